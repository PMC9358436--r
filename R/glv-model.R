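#' Construct a generalized Lotka-Volterra community model
#'
#' A gLV model describes community dynamics as `dx/dt = D(x) (r + A x)`,
#' where `x(t)` is the vector of species abundances, `r` the intrinsic
#' (monoculture) growth rates, `A` the n-by-n community matrix of per-capita
#' interaction coefficients and `D(x)` the diagonal matrix of abundances.
#'
#' The matrix convention follows the ODE: `A[i, k]` is the per-capita effect
#' of species `k` on the growth of species `i` (row = affected species).
#' Sign statements phrased in the "effect of i on j" direction are translated
#' through [classify_interaction()].
#'
#' @param species_ids character vector of unique taxon identifiers.
#' @param kingdoms per-species kingdom label, `"bacteria"` or `"fungi"`.
#' @param r numeric vector of intrinsic growth rates (1/time).
#' @param A numeric n-by-n interaction matrix (1/(abundance * time)).
#' @return an object of class `glv_model` with fields `species_ids`,
#'   `kingdoms`, `r`, `A`, `n`.
#' @examples
#' glv_model("sp1", "bacteria", r = 1, A = matrix(-1, 1, 1))
#' @seealso [sample_glv_model()] for random communities.
#' @export
glv_model <- function(species_ids, kingdoms, r, A) {
  species_ids <- as.character(species_ids)
  kingdoms <- as.character(kingdoms)
  n <- length(species_ids)
  A <- as.matrix(A)
  if (anyDuplicated(species_ids))
    stop("duplicate species ids")
  if (length(kingdoms) != n || length(r) != n)
    stop("kingdoms and r must have one entry per species")
  if (!all(kingdoms %in% c("bacteria", "fungi")))
    stop("kingdom labels must be 'bacteria' or 'fungi'")
  if (!all(dim(A) == c(n, n)))
    stop("A must be ", n, "x", n)
  if (!all(is.finite(r)) || !all(is.finite(A)))
    stop("r and A must be finite")
  dimnames(A) <- list(species_ids, species_ids)
  structure(
    list(species_ids = species_ids, kingdoms = kingdoms,
         r = stats::setNames(as.numeric(r), species_ids), A = A, n = n),
    class = "glv_model")
}

#' @export
print.glv_model <- function(x, ...) {
  interacting <- sum(x$A[upper.tri(x$A)] != 0 | t(x$A)[upper.tri(x$A)] != 0)
  cat("gLV model:", x$n, "species (",
      sum(x$kingdoms == "bacteria"), "bacteria,",
      sum(x$kingdoms == "fungi"), "fungi ),",
      interacting, "interacting pairs\n")
  invisible(x)
}

#' Sample a random cross-kingdom gLV community
#'
#' Draws a community matrix with a target connectance (fraction of unordered
#' species pairs that interact), a controllable share of cross-kingdom
#' (bacteria-fungi) interacting pairs, and an ecological mix of pairwise
#' interaction types. Each interacting pair is assigned a type from
#' `sign_mix` and half-normal interaction magnitudes with scale
#' `strength_scale`; the diagonal is uniform self-limitation `-self_limit`.
#'
#' Interaction types map to sign patterns of the two cross effects
#' (effect of i on j, effect of j on i): competition (-,-), predation
#' (-,+ in a random direction), mutualism (+,+), commensalism (+,0),
#' amensalism (-,0).
#'
#' @param n_bacteria,n_fungi species counts per kingdom (sum >= 2).
#' @param connectance_target fraction in `[0,1]` of unordered pairs that
#'   interact.
#' @param frac_cross_kingdom fraction of interacting pairs drawn from the
#'   bacteria-fungi pool (capped by pool sizes; ignored when one kingdom is
#'   absent).
#' @param sign_mix named probabilities over
#'   `c("competition","predation","mutualism","commensalism","amensalism")`;
#'   must sum to 1.
#' @param strength_scale scale (SD of the underlying normal) of off-diagonal
#'   interaction magnitudes; positive.
#' @param self_limit magnitude of diagonal self-limitation; positive.
#' @param r_range range of uniform intrinsic growth rates.
#' @param seed integer seed; identical arguments and seed give an identical
#'   model.
#' @return a [glv_model()] with bacteria labelled first (`B001`, ...) then
#'   fungi (`F001`, ...).
#' @examples
#' m <- sample_glv_model(3, 2, connectance_target = 0.3, seed = 1)
#' m$kingdoms
#' @export
sample_glv_model <- function(n_bacteria, n_fungi,
                             connectance_target = 0.1,
                             frac_cross_kingdom = 0.5,
                             sign_mix = c(competition = 0.35,
                                          predation = 0.35,
                                          mutualism = 0.10,
                                          commensalism = 0.10,
                                          amensalism = 0.10),
                             strength_scale = 0.3,
                             self_limit = 1,
                             r_range = c(0.5, 1.5),
                             seed = 1) {
  n_bacteria <- as.integer(n_bacteria); n_fungi <- as.integer(n_fungi)
  n <- n_bacteria + n_fungi
  if (n < 2) stop("need at least 2 species in total")
  if (!is.finite(connectance_target) || connectance_target < 0 ||
      connectance_target > 1)
    stop("connectance_target must be in [0, 1]")
  if (!is.finite(frac_cross_kingdom) || frac_cross_kingdom < 0 ||
      frac_cross_kingdom > 1)
    stop("frac_cross_kingdom must be in [0, 1]")
  if (!is.finite(strength_scale) || strength_scale <= 0 ||
      !is.finite(self_limit) || self_limit <= 0)
    stop("strength_scale and self_limit must be positive and finite")
  types <- c("competition", "predation", "mutualism", "commensalism",
             "amensalism")
  if (!all(names(sign_mix) %in% types) || any(sign_mix < 0) ||
      any(sign_mix > 1) || abs(sum(sign_mix) - 1) > 1e-8)
    stop("sign_mix must be named probabilities over the interaction types, summing to 1")

  set.seed(sub_seed(seed, 0L))
  species_ids <- c(if (n_bacteria > 0) sprintf("B%03d", seq_len(n_bacteria)),
                   if (n_fungi > 0) sprintf("F%03d", seq_len(n_fungi)))
  kingdoms <- c(rep("bacteria", n_bacteria), rep("fungi", n_fungi))

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cross <- kingdoms[pairs[, 1]] != kingdoms[pairs[, 2]]
  m_target <- round(connectance_target * nrow(pairs))
  n_cross <- min(round(frac_cross_kingdom * m_target), sum(cross))
  n_within <- min(m_target - n_cross, sum(!cross))
  # if one pool is exhausted, spill the remainder into the other
  n_cross <- min(n_cross + (m_target - n_cross - n_within), sum(cross))
  draw <- function(pool, k) pool[sample.int(length(pool), k)]
  pick <- c(if (n_cross > 0) draw(which(cross), n_cross),
            if (n_within > 0) draw(which(!cross), n_within))

  A <- matrix(0, n, n)
  if (length(pick) > 0) {
    type <- sample(types, length(pick), replace = TRUE,
                   prob = sign_mix[types])
    for (k in seq_along(pick)) {
      i <- pairs[pick[k], 1]; j <- pairs[pick[k], 2]
      m1 <- abs(stats::rnorm(1, 0, strength_scale))
      m2 <- abs(stats::rnorm(1, 0, strength_scale))
      flip <- stats::runif(1) < 0.5  # direction for asymmetric types
      # e_ij = effect of i on j (stored at A[j, i]); e_ji at A[i, j]
      e <- switch(type[k],
        competition  = c(-m1, -m2),
        mutualism    = c(m1, m2),
        predation    = if (flip) c(-m1, m2) else c(m2, -m1),
        commensalism = if (flip) c(m1, 0) else c(0, m1),
        amensalism   = if (flip) c(-m1, 0) else c(0, -m1))
      A[j, i] <- e[1]
      A[i, j] <- e[2]
    }
  }
  diag(A) <- -self_limit
  r <- stats::runif(n, r_range[1], r_range[2])
  glv_model(species_ids, kingdoms, r, A)
}

#' Evaluate the gLV time derivative
#'
#' Computes `dx/dt = D(x)(r + A x)`, i.e. componentwise
#' `x_i * (r_i + sum_k A[i,k] x_k)`.
#'
#' @param model a [glv_model()].
#' @param x abundance vector of length `model$n`, finite.
#' @return numeric rate vector of length `model$n`.
#' @examples
#' m <- glv_model("s", "bacteria", r = 1, A = matrix(-1, 1, 1))
#' glv_derivative(m, 0.5)  # logistic: 0.5 * (1 - 0.5) = 0.25
#' @export
glv_derivative <- function(model, x) {
  stopifnot(inherits(model, "glv_model"))
  if (length(x) != model$n) stop("x must have length ", model$n)
  if (!all(is.finite(x))) stop("x must be finite")
  as.numeric(x * (model$r + model$A %*% x))
}
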