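#' Attack order for an in-silico extinction experiment
#'
#' Centrality-based orders are computed once on the intact network (static
#' order), sorted from highest to lowest, ties broken lexicographically by
#' node id; the random strategy is a seeded shuffle of all nodes.
#'
#' @param net an \pkg{igraph} undirected graph.
#' @param strategy `"degree"`, `"betweenness"`, `"eigenvector"` or
#'   `"random"`.
#' @param seed integer seed (random strategy only).
#' @param recompute if `TRUE`, the order is re-derived from the named
#'   centrality after every removal during [simulate_extinction()]
#'   (sensitivity mode); the returned object only records the flag.
#' @return list of class `attack_order`: `strategy`, `order` (character
#'   permutation of the node ids), `seed`, `recompute`.
#' @export
attack_order <- function(net, strategy = c("degree", "betweenness",
                                           "eigenvector", "random"),
                         seed = 1, recompute = FALSE) {
  strategy <- match.arg(strategy)
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(net)))
  if (strategy == "random") {
    set.seed(sub_seed(seed, 0L))
    ord <- sample(nm)
  } else {
    ct <- suppressWarnings(centralities(net))
    val <- stats::setNames(ct[[strategy]], ct$taxon)[nm]
    ord <- nm[order(-val, nm)]
  }
  structure(list(strategy = strategy, order = ord, seed = seed,
                 recompute = recompute), class = "attack_order")
}

#' Simulate sequential extinctions with secondary extinctions
#'
#' Nodes are removed one primary extinction at a time following the attack
#' order (skipping nodes that already went secondarily extinct). A
#' secondary extinction is the removal of a node that has lost all of its
#' edges: after each primary removal, every surviving node whose degree has
#' dropped to 0 is removed as well (one sweep suffices, since removing
#' degree-0 nodes deletes no further edges). After each extinction event
#' the curve records x = fraction of nodes extinct (primary + secondary)
#' and y = current largest component size divided by the initial largest
#' component size.
#'
#' @param net an \pkg{igraph} undirected graph.
#' @param order an [attack_order()] covering exactly the network's nodes.
#' @return list of class `robustness_curve`: `x`, `y` (step-curve points
#'   starting at (0, 1) and ending at (1, 0)), `strategy`, `n_nodes`.
#' @export
simulate_extinction <- function(net, order) {
  stopifnot(inherits(order, "attack_order"))
  nm <- igraph::V(net)$name
  if (is.null(nm)) stop("network nodes must be named")
  if (!setequal(order$order, nm) || length(order$order) != length(nm))
    stop("attack order is not a permutation of the network's nodes")
  n0 <- length(nm)
  comp0 <- igraph::components(net)
  lcc0 <- max(comp0$csize)

  g <- net
  x <- 0; y <- 1
  queue <- order$order
  while (igraph::vcount(g) > 0) {
    alive <- igraph::V(g)$name
    if (order$recompute && order$strategy != "random") {
      ct <- suppressWarnings(centralities(g))
      val <- stats::setNames(ct[[order$strategy]], ct$taxon)
      target <- alive[order(-val[alive], alive)][1]
    } else {
      queue <- queue[queue %in% alive]
      target <- queue[1]
    }
    g <- igraph::delete_vertices(g, target)
    if (igraph::vcount(g) > 0) {
      iso <- which(igraph::degree(g) == 0)
      if (length(iso) > 0) g <- igraph::delete_vertices(g, iso)
    }
    x <- c(x, (n0 - igraph::vcount(g)) / n0)
    y <- c(y, if (igraph::vcount(g) == 0) 0
              else max(igraph::components(g)$csize) / lcc0)
  }
  structure(list(x = x, y = y, strategy = order$strategy, n_nodes = n0),
            class = "robustness_curve")
}

#' Area under a robustness curve
#'
#' Trapezoidal integration of the (fraction extinct, largest-component
#' fraction) curve, linearly interpolating between recorded events.
#'
#' @param curve a [simulate_extinction()] result.
#' @return area in `[0, 1]`.
#' @export
robustness_auc <- function(curve) {
  stopifnot(inherits(curve, "robustness_curve"))
  if (length(curve$x) < 2) stop("curve needs at least 2 points")
  sum(diff(curve$x) * (utils::head(curve$y, -1) + utils::tail(curve$y, -1)) / 2)
}

#' Random-attack ensemble
#'
#' Runs `n_replicates` random-order extinction simulations with independent
#' sub-seeds, interpolates every curve onto a common x grid, and summarizes
#' the per-replicate AUCs.
#'
#' @param net an \pkg{igraph} undirected graph.
#' @param n_replicates number of random orders (>= 1).
#' @param seed master seed; replicate b uses `sub_seed(seed, b)`.
#' @param grid common x grid; default `seq(0, 1, length.out = n + 1)`.
#' @return list of class `robustness_ensemble`: `grid`, `mean_y`,
#'   `auc` (vector per replicate), `auc_mean`, `auc_sd`, `n_replicates`.
#' @export
random_attack_ensemble <- function(net, n_replicates = 100, seed = 1,
                                   grid = NULL) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  n0 <- igraph::vcount(net)
  if (is.null(grid)) grid <- seq(0, 1, length.out = n0 + 1)
  ys <- matrix(0, n_replicates, length(grid))
  auc <- numeric(n_replicates)
  for (b in seq_len(n_replicates)) {
    ord <- attack_order(net, "random", seed = sub_seed(seed, b))
    cv <- simulate_extinction(net, ord)
    ys[b, ] <- stats::approx(cv$x, cv$y, xout = grid, rule = 2, ties = "ordered")$y
    auc[b] <- robustness_auc(cv)
  }
  structure(list(grid = grid, mean_y = colMeans(ys), auc = auc,
                 auc_mean = mean(auc),
                 auc_sd = if (n_replicates > 1) stats::sd(auc) else 0,
                 n_replicates = n_replicates),
            class = "robustness_ensemble")
}

#' Robustness curves and AUCs for all attack strategies
#'
#' @param net an \pkg{igraph} undirected graph.
#' @param n_random random-attack replicates.
#' @param seed master seed.
#' @return list with `curves` (long-format data frame: strategy, event,
#'   x, y), `auc` (named vector: degree, betweenness, eigenvector,
#'   random_mean), `random_auc_sd`.
#' @export
robustness_analysis <- function(net, n_random = 100, seed = 1) {
  strategies <- c("degree", "betweenness", "eigenvector")
  curves <- list()
  auc <- c()
  for (s in strategies) {
    cv <- simulate_extinction(net, attack_order(net, s))
    curves[[s]] <- data.frame(strategy = s, event = seq_along(cv$x) - 1,
                              x = cv$x, y = cv$y, stringsAsFactors = FALSE)
    auc[s] <- robustness_auc(cv)
  }
  ens <- random_attack_ensemble(net, n_replicates = n_random, seed = seed)
  curves$random <- data.frame(strategy = "random",
                              event = seq_along(ens$grid) - 1,
                              x = ens$grid, y = ens$mean_y,
                              stringsAsFactors = FALSE)
  auc["random_mean"] <- ens$auc_mean
  list(curves = do.call(rbind, curves), auc = auc,
       random_auc_sd = ens$auc_sd)
}
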