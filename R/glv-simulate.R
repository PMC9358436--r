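#' Integrate a gLV community to steady state
#'
#' Numerically integrates `dx/dt = D(x)(r + A x)` (adaptive solver from
#' \pkg{deSolve}) in probe windows of `window` time units until the relative
#' change of every surviving species over a window drops below `rel_tol`, or
#' `t_max` is reached. Species falling below `extinct_eps` are clamped to
#' exactly 0 at window boundaries, and tiny negative round-off is clamped to
#' 0, so extinct species stay extinct. On convergence the surviving
#' subcommunity is polished by solving `A[S,S] x_S = -r[S]` exactly; the
#' linear solution replaces the integrated state when it is positive and
#' within 10% of it, so interior fixed points satisfy `r + A x* = 0` to
#' machine precision.
#'
#' @param model a [glv_model()].
#' @param x0 non-negative initial abundances (length `model$n`).
#' @param t_max maximum integration time.
#' @param rel_tol steady-state declaration threshold on the relative change
#'   per probe window.
#' @param extinct_eps abundances below this are treated as extinct (set to 0).
#' @param window probe-window length (time units) for the convergence check.
#' @return named non-negative numeric vector `x*` with attributes
#'   `converged` (logical) and `t_end` (time reached).
#' @examples
#' m <- glv_model("s", "bacteria", r = 1, A = matrix(-1, 1, 1))
#' integrate_to_steady_state(m, 0.1)  # carrying capacity 1
#' @export
integrate_to_steady_state <- function(model, x0, t_max = 1000,
                                      rel_tol = 1e-6, extinct_eps = 1e-8,
                                      window = 5) {
  stopifnot(inherits(model, "glv_model"))
  if (length(x0) != model$n) stop("x0 must have length ", model$n)
  if (any(!is.finite(x0)) || any(x0 < 0)) stop("x0 must be finite and >= 0")
  r <- as.numeric(model$r); A <- model$A
  rhs <- function(t, x, parms) list(x * (r + as.numeric(A %*% x)))

  x <- as.numeric(x0)
  x[x < extinct_eps] <- 0
  t_now <- 0
  converged <- all(x == 0)
  chunk <- 10L  # probe windows per solver call
  while (!converged && t_now < t_max) {
    t_seq <- seq(t_now, min(t_now + chunk * window, t_max), by = window)
    if (length(t_seq) < 2) break
    out <- tryCatch(
      suppressWarnings(
        deSolve::lsoda(y = x, times = t_seq, func = rhs,
                       rtol = 1e-8, atol = 1e-10, maxsteps = 1e5)),
      error = function(e)
        stop("gLV integration blew up (solver failure: ",
             conditionMessage(e), ")", call. = FALSE))
    states <- out[, -1, drop = FALSE]
    if (any(!is.finite(states)) || max(states) > 1e10 || nrow(states) < 2)
      stop("gLV integration blew up (non-finite or diverging abundances)")
    for (row in 2:nrow(states)) {
      xn <- pmax(states[row, ], 0)
      xn[xn < extinct_eps] <- 0
      rel <- abs(xn - x) / pmax(pmax(xn, x), extinct_eps)
      x <- xn
      t_now <- t_seq[row]
      if (max(rel) < rel_tol) { converged <- TRUE; break }
    }
  }

  if (converged && any(x > 0)) {
    s <- which(x > 0)
    xs <- tryCatch(solve(A[s, s, drop = FALSE], -r[s]),
                   error = function(e) NULL)
    if (!is.null(xs) && all(is.finite(xs)) && all(xs > 0) &&
        max(abs(xs - x[s]) / pmax(x[s], extinct_eps)) < 0.1)
      x[s] <- xs
  }
  structure(stats::setNames(x, model$species_ids),
            converged = converged, t_end = t_now)
}

#' Simulate steady-state profiles of random species subsets
#'
#' Repeatedly draws a random subset of species (independent Bernoulli
#' inclusion), integrates the gLV dynamics of the subsetted community to
#' steady state, and records the resulting abundance profile. The collection
#' of profiles plays the role of a set of community "samples" from which
#' co-occurrence can be computed. Subsets with fewer than 2 species are
#' resampled. Excluded species are exactly 0 in the corresponding profile
#' (absent species cannot appear under gLV dynamics).
#'
#' @param model a [glv_model()].
#' @param n_subsets number of subsets/profiles (>= 1).
#' @param inclusion_prob per-species Bernoulli inclusion probability in
#'   `(0, 1]`.
#' @param seed integer seed.
#' @param x0_abundance initial abundance given to each included species.
#' @param ... passed to [integrate_to_steady_state()] (`t_max`, `rel_tol`,
#'   `extinct_eps`, `window`).
#' @return object of class `steady_state_profiles`: list with
#'   `subset_masks` (n_subsets x n, 0/1), `profiles` (n_subsets x n),
#'   `converged` (logical per subset), `blew_up` (logical per subset;
#'   diverging subsets are reported with a warning, flagged non-converged
#'   and get `NA` profiles), `model_seed`.
#' @export
simulate_subset_profiles <- function(model, n_subsets, inclusion_prob = 0.5,
                                     seed = 1, x0_abundance = 0.1, ...) {
  stopifnot(inherits(model, "glv_model"))
  n_subsets <- as.integer(n_subsets)
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  if (!is.finite(inclusion_prob) || inclusion_prob <= 0 || inclusion_prob > 1)
    stop("inclusion_prob must be in (0, 1]")
  n <- model$n
  if (n < 2) stop("model has no feasible subsets (fewer than 2 species)")

  set.seed(sub_seed(seed, 0L))
  masks <- matrix(0L, n_subsets, n,
                  dimnames = list(sprintf("S%03d", seq_len(n_subsets)),
                                  model$species_ids))
  for (s in seq_len(n_subsets)) {
    for (try in 1:1000) {
      m <- stats::rbinom(n, 1L, inclusion_prob)
      if (sum(m) >= 2) break
    }
    if (sum(m) < 2) stop("model has no feasible subsets (could not draw >= 2 species)")
    masks[s, ] <- m
  }

  profiles <- matrix(0, n_subsets, n, dimnames = dimnames(masks))
  converged <- logical(n_subsets)
  blew_up <- logical(n_subsets)
  for (s in seq_len(n_subsets)) {
    x0 <- x0_abundance * masks[s, ]
    xs <- tryCatch(integrate_to_steady_state(model, x0, ...),
                   error = function(e) {
                     if (!grepl("blew up", conditionMessage(e))) stop(e)
                     blew_up[s] <<- TRUE
                     structure(rep(NA_real_, n), converged = FALSE)
                   })
    profiles[s, ] <- as.numeric(xs)
    converged[s] <- isTRUE(attr(xs, "converged"))
  }
  if (any(blew_up))
    warning(sum(blew_up), " of ", n_subsets,
            " subsets diverged (gLV blow-up); flagged non-converged")
  structure(list(subset_masks = masks, profiles = profiles,
                 converged = converged, blew_up = blew_up,
                 model_seed = seed),
            class = "steady_state_profiles")
}

#' Construct a samples-by-taxa abundance table
#'
#' @param mat non-negative numeric matrix, rows = samples, columns = taxa,
#'   with dimnames.
#' @param kind `"counts"` or `"relative"`; relative rows must sum to 1.
#' @return object of class `abundance_table`: list with `sample_ids`,
#'   `taxon_ids`, `values` (matrix), `kind`.
#' @export
abundance_table <- function(mat, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("abundance matrix needs sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(mat))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate taxon ids")
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("abundances must be finite and non-negative")
  if (kind == "relative" && any(abs(rowSums(mat) - 1) > 1e-6))
    stop("relative-abundance rows must sum to 1")
  structure(list(sample_ids = rownames(mat), taxon_ids = colnames(mat),
                 values = mat, kind = kind),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance table (", x$kind, "): ", length(x$sample_ids), " samples x ",
      length(x$taxon_ids), " taxa\n", sep = "")
  invisible(x)
}

#' Convert an abundance table to relative abundances
#'
#' @param table an [abundance_table()]; all-zero samples are an error.
#' @return an [abundance_table()] with `kind = "relative"`.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  rs <- rowSums(table$values)
  if (any(rs == 0)) stop("cannot normalize all-zero samples: ",
                         paste(table$sample_ids[rs == 0], collapse = ", "))
  abundance_table(sweep(table$values, 1, rs, "/"), kind = "relative")
}

#' Sample sequencing reads from steady-state profiles
#'
#' Emulates amplicon sequencing of the simulated community: each profile is
#' normalized to relative abundances and a multinomial of size `depth` is
#' drawn, so every sample row sums exactly to `depth` and species absent at
#' steady state receive 0 reads.
#'
#' @param profiles a [simulate_subset_profiles()] result.
#' @param depth reads per sample (>= 1).
#' @param seed integer seed.
#' @param converged_only drop profiles flagged non-converged (default TRUE).
#' @return an [abundance_table()] of counts.
#' @export
sample_reads <- function(profiles, depth, seed = 1, converged_only = TRUE) {
  stopifnot(inherits(profiles, "steady_state_profiles"))
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  prof <- profiles$profiles
  if (converged_only) prof <- prof[profiles$converged, , drop = FALSE]
  if (nrow(prof) == 0) stop("no (converged) profiles to sample from")
  if (any(rowSums(prof) == 0))
    stop("all-zero steady-state profile cannot be normalized: ",
         paste(rownames(prof)[rowSums(prof) == 0], collapse = ", "))
  set.seed(sub_seed(seed, 0L))
  counts <- t(apply(prof, 1, function(p) {
    as.numeric(stats::rmultinom(1, depth, p / sum(p)))
  }))
  dimnames(counts) <- dimnames(prof)
  abundance_table(counts, kind = "counts")
}

#' Simulate a gLV abundance time series
#'
#' Deterministic gLV integration between consecutive grid points, with an
#' optional multiplicative log-normal perturbation `x * exp(N(0, sd))`
#' applied at each grid point after the first. With
#' `process_noise_sd = 0` the trajectory is the deterministic solution.
#'
#' @param model a [glv_model()].
#' @param x0 non-negative initial abundances.
#' @param times strictly increasing time grid (first entry is the initial
#'   time; first row of the result equals `x0`).
#' @param process_noise_sd SD of the log-normal perturbation (0 = none).
#' @param seed integer seed (used only when `process_noise_sd > 0`).
#' @return object of class `glv_trajectory`: list with `times` and
#'   `abundances` (length(times) x n matrix, non-negative).
#' @export
simulate_time_series <- function(model, x0, times, process_noise_sd = 0,
                                 seed = 1) {
  stopifnot(inherits(model, "glv_model"))
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least 2 points")
  if (length(x0) != model$n) stop("x0 must have length ", model$n)
  if (any(!is.finite(x0)) || any(x0 < 0)) stop("x0 must be finite and >= 0")
  if (!is.finite(process_noise_sd) || process_noise_sd < 0)
    stop("process_noise_sd must be >= 0")
  r <- as.numeric(model$r); A <- model$A
  rhs <- function(t, x, parms) list(x * (r + as.numeric(A %*% x)))
  if (process_noise_sd > 0) set.seed(sub_seed(seed, 0L))

  n <- model$n
  traj <- matrix(0, length(times), n,
                 dimnames = list(NULL, model$species_ids))
  x <- as.numeric(x0)
  traj[1, ] <- x
  for (k in 2:length(times)) {
    out <- deSolve::lsoda(y = x, times = times[(k - 1):k], func = rhs,
                          rtol = 1e-8, atol = 1e-10)
    x <- pmax(out[2, -1], 0)
    if (any(!is.finite(x))) stop("gLV integration blew up in time series")
    if (process_noise_sd > 0)
      x <- x * exp(stats::rnorm(n, 0, process_noise_sd))
    traj[k, ] <- x
  }
  structure(list(times = times, abundances = traj), class = "glv_trajectory")
}
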