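#' Node centralities of a co-occurrence network
#'
#' Degree, betweenness (exact shortest-path counting; both raw and
#' normalized by `(n-1)(n-2)/2`) and eigenvector centrality for every node.
#' All metrics treat the graph as simple and unweighted; edge signs are
#' ignored. Eigenvector centrality on a disconnected graph is computed on
#' the largest connected component (dominant eigenvector of its adjacency
#' matrix, scaled to unit Euclidean norm) and set to 0 elsewhere, with a
#' warning.
#'
#' @param net an \pkg{igraph} undirected graph (e.g. from
#'   [build_network()]).
#' @return data frame with columns `taxon`, `kingdom` (NA when the graph
#'   carries no kingdom attribute), `degree`, `betweenness` (normalized),
#'   `betweenness_raw`, `eigenvector`.
#' @export
centralities <- function(net) {
  n <- igraph::vcount(net)
  if (n < 1) stop("network has no nodes")
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  kingdom <- if ("kingdom" %in% igraph::vertex_attr_names(net))
    igraph::V(net)$kingdom else rep(NA_character_, n)

  deg <- igraph::degree(net)
  btw_raw <- igraph::betweenness(net, directed = FALSE, weights = NA)
  norm_const <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  btw <- btw_raw / norm_const

  comp <- igraph::components(net)
  ev <- stats::setNames(rep(0, n), nm)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  if (comp$no > 1)
    warning("disconnected graph: eigenvector centrality computed on the ",
            "largest component (", comp$csize[big], " nodes), 0 elsewhere")
  if (length(members) == 1) {
    ev[members] <- 1
  } else {
    sub <- igraph::induced_subgraph(net, members)
    Adj <- as.matrix(igraph::as_adjacency_matrix(sub))
    Adj[Adj > 0] <- 1
    es <- eigen(Adj, symmetric = TRUE)
    v <- es$vectors[, 1]
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0  # Perron vector round-off
    v <- v / sqrt(sum(v^2))
    ev[igraph::V(sub)$name] <- v
  }
  data.frame(taxon = nm, kingdom = kingdom, degree = as.numeric(deg),
             betweenness = as.numeric(btw),
             betweenness_raw = as.numeric(btw_raw),
             eigenvector = as.numeric(ev[nm]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Connectance of an undirected simple graph
#'
#' Realized fraction of possible edges, `2m / (n (n - 1))`.
#'
#' @param net an \pkg{igraph} undirected graph with at least 2 nodes.
#' @return fraction in `[0, 1]`.
#' @export
connectance <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("connectance is undefined for fewer than 2 nodes")
  2 * igraph::ecount(net) / (n * (n - 1))
}

#' Global transitivity (clustering coefficient)
#'
#' `3 * triangles / connected triples`; defined as 0 for a graph with no
#' connected triple.
#'
#' @param net an \pkg{igraph} undirected graph.
#' @return fraction in `[0, 1]`.
#' @export
transitivity_global <- function(net) {
  tr <- igraph::transitivity(net, type = "global")
  if (is.nan(tr) || is.na(tr)) 0 else tr
}

#' Greedy modularity partition and Newman-Girvan Q
#'
#' Community detection by greedy agglomerative modularity maximization
#' (Clauset-Newman-Moore, via \pkg{igraph}); deterministic for a given
#' graph and seed.
#'
#' @param net an \pkg{igraph} undirected graph with at least 1 edge.
#' @param seed integer seed (the greedy algorithm is deterministic; the
#'   seed is fixed for a uniform seeding policy across null replicates).
#' @return list of class `modularity_partition`: `membership` (named
#'   integer vector) and `modularity` (Q for that partition).
#' @seealso [modularity_q()] to evaluate Q for a user-supplied partition.
#' @export
modularity_partition <- function(net, seed = 1) {
  if (igraph::ecount(net) < 1) stop("modularity needs at least 1 edge")
  set.seed(sub_seed(seed, 0L))
  cl <- igraph::cluster_fast_greedy(igraph::simplify(net))
  # cut the merge tree at the step maximizing Q ourselves: membership()
  # can return a sub-optimal cut on very small graphs
  memb <- igraph::cut_at(cl, steps = which.max(cl$modularity) - 1)
  q_cut <- igraph::modularity(net, memb)
  if (q_cut < igraph::modularity(net, igraph::membership(cl))) {
    memb <- igraph::membership(cl)
  }
  structure(list(membership = stats::setNames(as.integer(memb),
                                              igraph::V(net)$name),
                 modularity = igraph::modularity(net, memb)),
            class = "modularity_partition")
}

#' Newman-Girvan modularity of a given partition
#'
#' @param net an \pkg{igraph} undirected graph.
#' @param membership integer community labels, one per node.
#' @return modularity Q.
#' @export
modularity_q <- function(net, membership) {
  igraph::modularity(net, membership)
}

#' Paired centrality shift between two networks
#'
#' For nodes shared by both networks (matched by taxon id) the chosen
#' centrality is evaluated in each network and the per-node delta
#' (network 2 minus network 1) is reported, together with counts of nodes
#' above/below the y = x line — the comparison used to ask how adding a
#' second kingdom changes the importance of nodes from a single-kingdom
#' network.
#'
#' @param net_single,net_cross the two networks (e.g. bacteria-only and
#'   cross-kingdom); must share at least one node id.
#' @param metric `"degree"`, `"betweenness"` or `"eigenvector"`.
#' @return list of class `centrality_shift`: `paired` (data frame `taxon`,
#'   `value_single`, `value_cross`, `delta`), `only_single`, `only_cross`
#'   (ids absent from the other network), `summary` (list with
#'   `n_shared`, `n_increased`, `n_decreased`, `mean_delta`), `metric`.
#' @export
compare_centrality <- function(net_single, net_cross,
                               metric = c("degree", "betweenness",
                                          "eigenvector")) {
  metric <- match.arg(metric)
  if (length(intersect(igraph::V(net_single)$name,
                       igraph::V(net_cross)$name)) == 0)
    stop("networks share no nodes")
  c1 <- centralities(net_single)
  c2 <- centralities(net_cross)
  shared <- intersect(c1$taxon, c2$taxon)
  v1 <- stats::setNames(c1[[metric]], c1$taxon)[shared]
  v2 <- stats::setNames(c2[[metric]], c2$taxon)[shared]
  delta <- v2 - v1
  paired <- data.frame(taxon = shared, value_single = as.numeric(v1),
                       value_cross = as.numeric(v2),
                       delta = as.numeric(delta),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    paired = paired,
    only_single = setdiff(c1$taxon, shared),
    only_cross = setdiff(c2$taxon, shared),
    summary = list(n_shared = length(shared),
                   n_increased = sum(delta > 0),
                   n_decreased = sum(delta < 0),
                   mean_delta = mean(delta)),
    metric = metric), class = "centrality_shift")
}

#' Network summary statistics
#'
#' @param net an \pkg{igraph} undirected graph.
#' @param seed seed passed to [modularity_partition()].
#' @return list with `n_nodes`, `n_edges`, `connectance`, `transitivity`,
#'   `modularity` (NA for an edgeless graph).
#' @export
network_summary <- function(net, seed = 1) {
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       connectance = if (igraph::vcount(net) >= 2) connectance(net)
                     else NA_real_,
       transitivity = transitivity_global(net),
       modularity = if (igraph::ecount(net) >= 1)
         modularity_partition(net, seed)$modularity else NA_real_)
}
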