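# Graph fixtures and independent oracles used across the suite.

library(igraph)

graph_from_pairs <- function(pairs, kingdoms = NULL) {
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  if (!is.null(kingdoms))
    igraph::V(g)$kingdom <- unname(kingdoms[igraph::V(g)$name])
  g
}

path3 <- function() graph_from_pairs(rbind(c("a", "b"), c("b", "c")))
triangle <- function() graph_from_pairs(rbind(c("a", "b"), c("b", "c"),
                                              c("a", "c")))
star4 <- function() graph_from_pairs(cbind("hub", paste0("leaf", 1:4)))
two_edges <- function() graph_from_pairs(rbind(c("a", "b"), c("c", "d")))
two_triangles <- function() graph_from_pairs(rbind(
  c("a", "b"), c("b", "c"), c("a", "c"),
  c("d", "e"), c("e", "f"), c("d", "f")))

# preferential-attachment fixture for hub-dominated attack experiments
pa_fixture <- function(n = 60, seed = 7) {
  set.seed(seed)
  g <- igraph::sample_pa(n, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

random_small_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- letters[seq_len(n)]
  # keep only nodes with degree >= 1, matching the build convention
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

# Oracle: betweenness by literal enumeration of all simple paths per pair.
oracle_betweenness <- function(g, normalized = TRUE) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  btw <- setNames(rep(0, n), nm)
  for (si in seq_len(n - 1)) {
    for (ti in (si + 1):n) {
      paths <- suppressWarnings(
        igraph::all_simple_paths(g, from = nm[si], to = nm[ti]))
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        inner <- setdiff(igraph::as_ids(p), c(nm[si], nm[ti]))
        for (v in inner) btw[v] <- btw[v] + 1 / length(shortest)
      }
    }
  }
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

# Oracle: extinction simulation on the adjacency matrix, recomputing
# components from scratch (BFS) after every event.
oracle_extinction <- function(g, order) {
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  adj[adj > 0] <- 1
  nm <- rownames(adj)
  comp_sizes <- function(a) {
    alive <- rownames(a)
    if (length(alive) == 0) return(integer(0))
    seen <- character(0); sizes <- integer(0)
    for (v in alive) {
      if (v %in% seen) next
      frontier <- v; comp <- character(0)
      while (length(frontier) > 0) {
        comp <- union(comp, frontier)
        nxt <- unique(unlist(lapply(frontier, function(u)
          colnames(a)[a[u, ] == 1])))
        frontier <- setdiff(nxt, comp)
      }
      seen <- union(seen, comp)
      sizes <- c(sizes, length(comp))
    }
    sizes
  }
  n0 <- length(nm)
  lcc0 <- max(comp_sizes(adj))
  x <- 0; y <- 1
  removed <- character(0)
  for (v in order) {
    if (v %in% removed) next
    removed <- union(removed, v)
    keep <- setdiff(nm, removed)
    a <- adj[keep, keep, drop = FALSE]
    iso <- rownames(a)[rowSums(a) == 0]
    removed <- union(removed, iso)
    keep <- setdiff(nm, removed)
    a <- adj[keep, keep, drop = FALSE]
    x <- c(x, length(removed) / n0)
    y <- c(y, if (length(keep) == 0) 0 else max(comp_sizes(a)) / lcc0)
  }
  list(x = x, y = y)
}

# Oracle: NODF by literal enumeration over every ordered line pair.
oracle_nodf <- function(mat) {
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  line_terms <- function(lines) {
    k <- nrow(lines)
    total <- 0; npairs <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i >= j) next
      npairs <- npairs + 1
      fi <- sum(lines[i, ]); fj <- sum(lines[j, ])
      if (fi == fj) next
      hi <- if (fi > fj) i else j
      lo <- if (fi > fj) j else i
      shared <- sum(lines[hi, ] == 1 & lines[lo, ] == 1)
      total <- total + 100 * shared / sum(lines[lo, ])
    }
    c(total, npairs)
  }
  r <- line_terms(mat)
  co <- line_terms(t(mat))
  (r[1] + co[1]) / (r[2] + co[2])
}

random_binary_matrix <- function(nr, nc, p, seed) {
  set.seed(seed)
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}

# small stable competitive community used in several tests
competitive_model <- function(n_b = 4, n_f = 2, seed = 5) {
  sample_glv_model(n_b, n_f, connectance_target = 0.4,
                   frac_cross_kingdom = 0.5,
                   sign_mix = c(competition = 1, predation = 0,
                                mutualism = 0, commensalism = 0,
                                amensalism = 0),
                   strength_scale = 0.3, seed = seed)
}
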