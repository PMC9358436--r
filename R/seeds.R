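#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic operation in the package takes an explicit integer seed.
#' Multi-stage procedures (pipelines, replicate ensembles, null chains) derive
#' one sub-seed per stage/replicate from a single master seed with this
#' function, so a run is fully determined by one integer.
#'
#' @param seed master seed (single finite number).
#' @param stream non-negative integer identifying the consumer stream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' sub_seed(1, 0)
#' sub_seed(1, 1)
#' @export
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  s <- abs(as.numeric(seed)) %% 2147483647
  # Lehmer-style mix; all arithmetic stays below 2^53 so doubles are exact.
  as.integer((s * 48271 + 12345 + as.numeric(stream) * 7919) %% 2147483647)
}
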