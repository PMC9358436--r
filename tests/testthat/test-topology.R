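test_that("centralities on canonical small graphs", {
  ct <- centralities(path3())
  expect_equal(ct$betweenness[ct$taxon == "b"], 1)
  expect_equal(ct$betweenness[ct$taxon %in% c("a", "c")], c(0, 0))

  ct3 <- centralities(triangle())
  expect_equal(ct3$eigenvector, rep(1 / sqrt(3), 3), tolerance = 1e-10)

  cts <- centralities(star4())
  expect_equal(ct_star <- cts$degree[cts$taxon == "hub"], 4)
  expect_true(all(cts$degree[cts$taxon != "hub"] == 1))
})

test_that("betweenness matches the path-enumeration oracle on small graphs", {
  for (seed in 1:8) {
    g <- random_small_graph(sample(4:8, 1), 0.45, seed = seed)
    if (igraph::vcount(g) < 3) next
    ct <- suppressWarnings(centralities(g))
    oracle <- oracle_betweenness(g)
    expect_equal(setNames(ct$betweenness, ct$taxon), oracle,
                 tolerance = 1e-10)
  }
})

test_that("eigenvector centrality is the dominant eigenvector of the LCC", {
  g <- two_triangles()  # disconnected
  expect_warning(ct <- centralities(g), "largest component")
  v <- setNames(ct$eigenvector, ct$taxon)
  on_lcc <- v > 0
  expect_equal(sum(on_lcc), 3)
  sub <- igraph::induced_subgraph(g, names(v)[on_lcc])
  Adj <- as.matrix(igraph::as_adjacency_matrix(sub))
  lam <- max(eigen(Adj, symmetric = TRUE)$values)
  resid <- Adj %*% v[rownames(Adj)] - lam * v[rownames(Adj)]
  expect_lt(max(abs(resid)), 1e-8)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
})

test_that("connectance and transitivity match closed forms", {
  expect_equal(connectance(triangle()), 1)
  expect_equal(connectance(path3()), 2 / 3)
  expect_error(connectance(igraph::make_empty_graph(1, directed = FALSE)),
               "fewer than 2")
  expect_equal(transitivity_global(triangle()), 1)
  expect_equal(transitivity_global(star4()), 0)
  expect_equal(transitivity_global(path3()), 0)
})

test_that("modularity of known partitions and the greedy optimizer", {
  g <- two_triangles()
  comp_part <- igraph::components(g)$membership
  expect_equal(modularity_q(g, comp_part), 0.5)
  expect_equal(modularity_q(triangle(), rep(1, 3)), 0)

  mp1 <- modularity_partition(g, seed = 3)
  mp2 <- modularity_partition(g, seed = 3)
  expect_identical(mp1, mp2)
  expect_equal(mp1$modularity, 0.5)  # greedy finds the component split
  expect_error(modularity_partition(
    igraph::make_empty_graph(3, directed = FALSE)), "at least 1 edge")
})

test_that("greedy partition beats all-singletons on random graphs", {
  for (seed in 1:5) {
    g <- random_small_graph(10, 0.3, seed = seed + 50)
    if (igraph::ecount(g) < 1) next
    mp <- modularity_partition(g)
    singletons <- seq_len(igraph::vcount(g))
    expect_gte(mp$modularity, modularity_q(g, singletons))
  }
})

test_that("comparing a network with itself gives zero shifts", {
  g <- triangle()
  cs <- compare_centrality(g, g, "betweenness")
  expect_true(all(cs$paired$delta == 0))
  expect_equal(cs$summary$n_increased, 0)
  expect_equal(cs$summary$n_decreased, 0)
  expect_lte(cs$summary$n_shared, igraph::vcount(g))
})

test_that("a fungal bridge raises betweenness of bacterial connector nodes", {
  # two bacterial triangles joined only through one fungal node
  km <- c(a = "bacteria", b = "bacteria", c = "bacteria",
          d = "bacteria", e = "bacteria", f = "bacteria", fun = "fungi")
  bacteria_only <- graph_from_pairs(rbind(
    c("a", "b"), c("b", "c"), c("a", "c"),
    c("d", "e"), c("e", "f"), c("d", "f")), km)
  cross <- igraph::add_edges(
    igraph::add_vertices(bacteria_only, 1, name = "fun", kingdom = "fungi"),
    c("c", "fun", "fun", "d"))
  cs <- suppressWarnings(
    compare_centrality(bacteria_only, cross, "betweenness"))
  connectors <- cs$paired[cs$paired$taxon %in% c("c", "d"), ]
  expect_gt(mean(connectors$delta), 0)
  # oracle check on the cross network
  oracle <- oracle_betweenness(cross)
  ct <- suppressWarnings(centralities(cross))
  expect_equal(setNames(ct$betweenness, ct$taxon), oracle,
               tolerance = 1e-10)
  disjoint <- graph_from_pairs(rbind(c("x1", "x2")))
  expect_error(compare_centrality(bacteria_only, disjoint),
               "share no nodes")
})

test_that("network_summary collects the comparison metrics", {
  s <- network_summary(triangle())
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_equal(s$connectance, 1)
  expect_equal(s$transitivity, 1)
  expect_equal(s$modularity, 0)
})
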