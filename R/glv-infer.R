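#' Infer gLV parameters from a time series by ridge regression
#'
#' Under gLV dynamics, `d log x_i / dt = r_i + sum_k A[i,k] x_k`, so for each
#' species the discrete log-derivative
#' `(log x_i(t+dt) - log x_i(t)) / dt` is regressed on the midpoint
#' abundances `(x(t) + x(t+dt))/2` of all species plus an intercept. The
#' intercept estimates `r_i` and is unpenalized; the interaction
#' coefficients carry an L2 (ridge) penalty `ridge_lambda`, solved in closed
#' form. Increments are usable for species `i` only when `x_i` exceeds
#' `min_abundance` at both endpoints (logs of near-zero abundances are
#' unstable). Species never exceeding `min_abundance` are excluded with a
#' warning (their rows and columns of `A_hat` are 0, `r_hat` is `NA`).
#'
#' @param series a `glv_trajectory` from [simulate_time_series()] (or a
#'   list with `times` and `abundances`), or an unnamed list of several
#'   such trajectories — e.g. replicate growth curves from different
#'   inocula — whose regression increments are pooled, the standard way to
#'   make the inference identifiable for larger communities.
#' @param ridge_lambda non-negative ridge penalty on interaction
#'   coefficients.
#' @param min_abundance threshold below which abundances are not used in
#'   log-space.
#' @return object of class `glv_fit`: list with `r_hat`, `A_hat` (ODE
#'   convention, row = affected species), `ridge_lambda`, `residual_ss`
#'   (per-species residual sum of squares), `excluded` (character).
#' @examples
#' m <- glv_model("s", "bacteria", r = 1, A = matrix(-1, 1, 1))
#' tr <- simulate_time_series(m, 0.05, seq(0, 8, by = 0.05))
#' fit <- infer_glv(tr, ridge_lambda = 1e-6)
#' fit$r_hat  # close to 1
#' @export
infer_glv <- function(series, ridge_lambda = 1e-3, min_abundance = 1e-6) {
  if (!is.list(series)) stop("series must have times and abundances")
  series_list <- if (!is.null(series$times)) list(series) else series
  if (!is.finite(ridge_lambda) || ridge_lambda < 0)
    stop("ridge_lambda must be >= 0")

  lo_list <- list(); hi_list <- list(); dt_list <- list(); mid_list <- list()
  ids <- NULL
  for (sr in series_list) {
    if (is.null(sr$times) || is.null(sr$abundances))
      stop("series must have times and abundances")
    x <- as.matrix(sr$abundances)
    if (nrow(x) < 3) stop("need at least 3 time points")
    if (is.null(ids)) {
      ids <- colnames(x)
      if (is.null(ids)) ids <- paste0("sp", seq_len(ncol(x)))
    } else if (ncol(x) != length(ids)) {
      stop("all series must cover the same species")
    }
    lo_list[[length(lo_list) + 1]] <- x[-nrow(x), , drop = FALSE]
    hi_list[[length(hi_list) + 1]] <- x[-1, , drop = FALSE]
    dt_list[[length(dt_list) + 1]] <- diff(as.numeric(sr$times))
  }
  lo <- do.call(rbind, lo_list)   # left endpoints of increments
  hi <- do.call(rbind, hi_list)   # right endpoints
  dt <- unlist(dt_list)
  mid <- (lo + hi) / 2
  n <- length(ids)

  present <- pmax(apply(lo, 2, max), apply(hi, 2, max)) > min_abundance
  if (!any(present)) stop("no species exceeds min_abundance")
  if (any(!present))
    warning("excluding all-zero/absent species: ",
            paste(ids[!present], collapse = ", "))
  keep <- which(present)

  r_hat <- stats::setNames(rep(NA_real_, n), ids)
  A_hat <- matrix(0, n, n, dimnames = list(ids, ids))
  rss <- stats::setNames(rep(NA_real_, n), ids)

  for (i in keep) {
    usable <- lo[, i] > min_abundance & hi[, i] > min_abundance
    if (sum(usable) < 2)
      stop("species ", ids[i], " has fewer than 2 usable increments")
    y <- (log(hi[usable, i]) - log(lo[usable, i])) / dt[usable]
    X <- cbind(1, mid[usable, keep, drop = FALSE])
    p <- ncol(X)
    pen <- diag(c(0, rep(ridge_lambda, p - 1)), p)
    beta <- solve(crossprod(X) + pen, crossprod(X, y))
    r_hat[i] <- beta[1]
    A_hat[i, keep] <- beta[-1]
    rss[i] <- sum((y - X %*% beta)^2)
  }
  structure(list(r_hat = r_hat, A_hat = A_hat, ridge_lambda = ridge_lambda,
                 residual_ss = rss, excluded = ids[!present]),
            class = "glv_fit")
}

#' Classify a pairwise interaction from the community matrix sign pattern
#'
#' Reads the two cross effects for an ordered species pair from the
#' ODE-convention community matrix (`A[i, k]` = effect of k on i, so the
#' effect of `i` on `j` is `A[j, i]`) and labels the relationship:
#' if i harms j while j benefits i, i preys on j; two negative cross effects
#' are competition; two positive, mutualism; one positive (negative) effect
#' with the reverse effect absent is commensalism (amensalism); both absent
#' is neutral. Effects with magnitude at most `tol` count as absent.
#'
#' @param A community matrix (ODE convention).
#' @param i,j distinct species indices (or names matching `dimnames(A)`).
#' @param tol magnitude threshold treated as zero; default
#'   `1e-6 * max(abs(A))`.
#' @return a single label among `"mutualism"`, `"competition"`,
#'   `"predation_i_on_j"`, `"predation_j_on_i"`, `"commensalism"`,
#'   `"amensalism"`, `"neutral"`, with attributes `effect_i_on_j` and
#'   `effect_j_on_i`.
#' @examples
#' A <- rbind(c(-1, 0.5), c(-0.4, -1))
#' classify_interaction(A, 1, 2)  # species 1 preys on species 2
#' @export
classify_interaction <- function(A, i, j, tol = NULL) {
  A <- as.matrix(A)
  if (is.character(i)) i <- match(i, rownames(A))
  if (is.character(j)) j <- match(j, colnames(A))
  n <- nrow(A)
  if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > n || j > n)
    stop("species index out of range")
  if (i == j) stop("i and j must differ")
  if (is.null(tol)) tol <- 1e-6 * max(abs(A))
  if (!is.finite(tol) || tol < 0) stop("tol must be >= 0")

  e_ij <- A[j, i]  # effect of i on j
  e_ji <- A[i, j]  # effect of j on i
  s_ij <- if (abs(e_ij) <= tol) 0 else sign(e_ij)
  s_ji <- if (abs(e_ji) <= tol) 0 else sign(e_ji)

  label <-
    if (s_ij == 0 && s_ji == 0) "neutral"
    else if (s_ij > 0 && s_ji > 0) "mutualism"
    else if (s_ij < 0 && s_ji < 0) "competition"
    else if (s_ij < 0 && s_ji > 0) "predation_i_on_j"
    else if (s_ij > 0 && s_ji < 0) "predation_j_on_i"
    else if (s_ij > 0 || s_ji > 0) "commensalism"
    else "amensalism"
  structure(label, effect_i_on_j = e_ij, effect_j_on_i = e_ji)
}

#' Classify all pairwise interactions of a community matrix
#'
#' @inheritParams classify_interaction
#' @return data frame with columns `i`, `j` (ids when `A` has dimnames) and
#'   `label`, one row per unordered pair.
#' @export
classify_interactions <- function(A, tol = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  labels <- vapply(seq_len(nrow(pairs)), function(k) {
    as.character(classify_interaction(A, pairs[k, 1], pairs[k, 2], tol))
  }, character(1))
  data.frame(i = ids[pairs[, 1]], j = ids[pairs[, 2]], label = labels,
             stringsAsFactors = FALSE)
}
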