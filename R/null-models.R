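#' Degree-preserving randomization of an undirected graph
#'
#' Configuration-style null: attempts `swap_factor * m` double-edge swaps
#' (two edges a-b, c-d are rewired to a-d, c-b), rejecting swaps that would
#' create self-loops or multi-edges, so the degree sequence — and with it
#' node count, edge count and connectance — is conserved exactly. Vertex
#' attributes (kingdom labels) are preserved; edge attributes of the
#' original (rho, q, sign) are dropped, as they are meaningless after
#' rewiring.
#'
#' @param net an \pkg{igraph} undirected graph with >= 2 edges.
#' @param swap_factor multiplier on the edge count giving the number of
#'   attempted swaps.
#' @param seed integer seed.
#' @return a randomized \pkg{igraph} graph with the same degree sequence.
#'   Graphs admitting no valid swap are returned unchanged with a warning.
#' @export
degree_preserving_randomize <- function(net, swap_factor = 10, seed = 1) {
  m <- igraph::ecount(net)
  if (m < 2) {
    warning("graph has fewer than 2 edges; no swap possible, returned unchanged")
    return(net)
  }
  set.seed(sub_seed(seed, 0L))
  g <- igraph::rewire(net, igraph::keeping_degseq(loops = FALSE,
                                                  niter = swap_factor * m))
  for (a in igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, a)
  same <- igraph::identical_graphs(igraph::simplify(g), igraph::simplify(net)) ||
    all(igraph::as_edgelist(g) == igraph::as_edgelist(net))
  if (same && m >= 2 && swap_factor * m >= 10)
    warning("no valid double-edge swap was applied; graph returned unchanged")
  g
}

# one curveball trade sequence on a row-wise list of column holdings;
# uses the current RNG stream (callers seed).
curveball_trades <- function(holdings, n_trades) {
  nr <- length(holdings)
  for (t in seq_len(n_trades)) {
    pair <- sample.int(nr, 2)
    s1 <- holdings[[pair[1]]]; s2 <- holdings[[pair[2]]]
    a <- setdiff(s1, s2); b <- setdiff(s2, s1)
    if (length(a) == 0 && length(b) == 0) next
    pool <- c(a, b)
    pool <- pool[sample.int(length(pool))]  # length-1 safe
    keep1 <- pool[seq_len(length(a))]
    holdings[[pair[1]]] <- c(setdiff(s1, a), keep1)
    holdings[[pair[2]]] <- c(setdiff(s2, b), setdiff(pool, keep1))
  }
  holdings
}

holdings_to_matrix <- function(holdings, template) {
  mat <- template
  mat[] <- 0L
  for (i in seq_along(holdings)) mat[i, holdings[[i]]] <- 1L
  mat
}

#' Curveball randomization of a binary matrix
#'
#' Fixed-fixed null model for binary (incidence) matrices: each trade picks
#' two rows and randomly re-allocates the columns held by exactly one of
#' them, keeping each row's total. Row sums and column sums are preserved
#' exactly by every trade.
#'
#' @param mat binary matrix with >= 2 rows.
#' @param n_trades number of trades.
#' @param seed integer seed.
#' @return a randomized binary matrix with identical margins and dimnames.
#' @export
curveball_randomize <- function(mat, n_trades, seed = 1) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("curveball needs at least 2 rows")
  if (!all(mat %in% c(0, 1))) stop("matrix must be binary")
  set.seed(sub_seed(seed, 0L))
  holdings <- apply(mat, 1, function(r) which(r == 1), simplify = FALSE)
  holdings <- curveball_trades(holdings, n_trades)
  holdings_to_matrix(holdings, mat)
}

#' Z-score normalization against a null ensemble
#'
#' Standard rule: `(observed - mean(null)) / sd(null)` (sample SD). When
#' the null ensemble has zero variance — as connectance does under any
#' degree-preserving null — the statistic is instead normalized by dividing
#' by the null mean (`rule = "ratio"`). An SD below 1e-12 is treated as
#' exactly 0.
#'
#' @param observed observed metric value.
#' @param null_values numeric vector of >= 2 null metric values.
#' @return list of class `zscore_report`: `observed`, `null_mean`,
#'   `null_sd`, `normalized`, `rule` (`"zscore"` or `"ratio"`), `n_null`.
#' @examples
#' zscore_normalize(5, c(2, 3, 4))        # z = 2
#' zscore_normalize(5, c(2.5, 2.5, 2.5))  # ratio rule: 2
#' @export
zscore_normalize <- function(observed, null_values) {
  if (length(null_values) < 2)
    stop("need at least 2 null values")
  if (!is.finite(observed) || any(!is.finite(null_values)))
    stop("observed and null values must be finite")
  m <- mean(null_values)
  s <- stats::sd(null_values)
  if (s < 1e-12) s <- 0
  if (s == 0) {
    if (abs(m) < 1e-12)
      stop("degenerate null ensemble: SD and mean are both 0")
    rule <- "ratio"; z <- observed / m
  } else {
    rule <- "zscore"; z <- (observed - m) / s
  }
  structure(list(observed = observed, null_mean = m, null_sd = s,
                 normalized = z, rule = rule, n_null = length(null_values)),
            class = "zscore_report")
}

#' @export
print.zscore_report <- function(x, ...) {
  cat(sprintf("observed %.4g | null mean %.4g sd %.4g | %s = %.4g (n_null %d)\n",
              x$observed, x$null_mean, x$null_sd, x$rule, x$normalized,
              x$n_null))
  invisible(x)
}

#' Z-score-normalized network summary statistics
#'
#' Generates `n_null` degree-preserving randomizations of the network
#' (independent sub-seeds), evaluates connectance, transitivity and
#' modularity on each, and normalizes the observed values with
#' [zscore_normalize()]. Because degree-preserving swaps conserve node and
#' edge counts, the connectance null ensemble always has SD 0 and the
#' ratio rule yields exactly 1. Modularity uses the same greedy algorithm
#' and seed policy on every replicate.
#'
#' @param net an \pkg{igraph} undirected graph with >= 1 edge.
#' @param n_null number of null replicates (>= 2).
#' @param seed master seed.
#' @param swap_factor passed to [degree_preserving_randomize()].
#' @return named list of `zscore_report`s for `connectance`,
#'   `transitivity`, `modularity`.
#' @export
summary_zscores <- function(net, n_null = 200, seed = 1, swap_factor = 10) {
  if (igraph::ecount(net) < 1) stop("network has no edges")
  if (n_null < 2) stop("n_null must be >= 2")
  obs <- c(connectance = connectance(net),
           transitivity = transitivity_global(net),
           modularity = modularity_partition(net, seed = 1)$modularity)
  nulls <- matrix(NA_real_, n_null, 3,
                  dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_null)) {
    g <- suppressWarnings(
      degree_preserving_randomize(net, swap_factor, seed = sub_seed(seed, b)))
    nulls[b, ] <- c(connectance(g), transitivity_global(g),
                    modularity_partition(g, seed = 1)$modularity)
  }
  stats::setNames(lapply(names(obs), function(met) {
    tryCatch(zscore_normalize(obs[[met]], nulls[, met]),
             error = function(e) {
               warning("degenerate null ensemble for ", met,
                       " (mean and SD both 0); normalized value is NA")
               structure(list(observed = obs[[met]], null_mean = 0,
                              null_sd = 0, normalized = NA_real_,
                              rule = "degenerate", n_null = n_null),
                         class = "zscore_report")
             })
  }), names(obs))
}

#' Tabulate z-score reports
#'
#' @param reports named list of `zscore_report`s (e.g. from
#'   [summary_zscores()]).
#' @return data frame with one row per metric.
#' @export
zscore_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(met) {
    r <- reports[[met]]
    data.frame(metric = met, observed = r$observed, null_mean = r$null_mean,
               null_sd = r$null_sd, normalized = r$normalized, rule = r$rule,
               n_null = r$n_null, stringsAsFactors = FALSE)
  }))
}
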