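make_table <- function(mat) {
  rownames(mat) <- sprintf("S%02d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("t%02d", seq_len(ncol(mat)))
  abundance_table(mat, kind = "counts")
}

test_that("pairwise correlations detect perfect monotone association", {
  mat <- cbind(1:8, (1:8)^2, 9:2, rep(5, 8))  # t4 constant
  tab <- make_table(mat)
  res <- suppressMessages(
    pairwise_correlation(tab, method = "spearman", min_prevalence = 0))
  expect_equal(res$rho["t01", "t02"], 1)
  expect_equal(res$rho["t01", "t03"], -1)
  expect_false("t04" %in% colnames(res$rho))
  expect_equal(res$p["t01", "t02"], 0)
  expect_equal(diag(res$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(res$rho, t(res$rho))
})

test_that("prevalence filtering and sample-count preconditions hold", {
  mat <- cbind(c(1, 0, 0, 0, 0, 0), 1:6, 6:1)
  tab <- make_table(mat)
  expect_message(res <- pairwise_correlation(tab, min_prevalence = 0.5),
                 "t01")
  expect_false("t01" %in% colnames(res$rho))
  expect_error(pairwise_correlation(make_table(matrix(1:6, 3, 2))),
               "at least 4 samples")
  expect_error(suppressMessages(
    pairwise_correlation(make_table(cbind(rep(1, 5), rep(2, 5))),
                         min_prevalence = 0)),
    "fewer than 2 taxa")
})

test_that("permutation p-values are usable for small sample sizes", {
  mat <- cbind(1:6, c(2, 1, 4, 3, 6, 5), c(3, 1, 4, 6, 2, 5))
  res <- suppressMessages(
    pairwise_correlation(make_table(mat), min_prevalence = 0,
                         n_perm = 200, seed = 4))
  expect_true(all(res$p[upper.tri(res$p)] >= 1 / 201))
  expect_true(all(res$p[upper.tri(res$p)] <= 1))
  res2 <- suppressMessages(
    pairwise_correlation(make_table(mat), min_prevalence = 0,
                         n_perm = 200, seed = 4))
  expect_identical(res$p, res2$p)
})

test_that("clr transform centers log-abundances per sample", {
  mat <- matrix(c(10, 0, 30, 5, 15, 20), 2, 3,
                dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  z <- clr_transform(abundance_table(mat, "counts"), pseudocount = 0.5)
  expect_equal(unname(rowSums(z)), c(0, 0))
  expect_equal(z[1, 1], log(10.5) - mean(log(c(10.5, 30.5, 15.5))))
  expect_error(clr_transform(mat, pseudocount = 0), "positive")
})

test_that("bh_adjust applies the step-up rule in input order", {
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(rep(0.3, 4)), rep(0.3, 4))
  p <- c(0.04, 0.001, 0.7, 0.01)
  q <- bh_adjust(p)
  expect_equal(q, stats::p.adjust(p, "BH"))  # order preserved
  expect_true(all(q >= p) && all(q <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("build_network filters edges by q and rho and drops isolated taxa", {
  taxa <- c("b1", "b2", "f1")
  rho <- matrix(c(1, 0.9, 0.1, 0.9, 1, -0.8, 0.1, -0.8, 1), 3, 3,
                dimnames = list(taxa, taxa))
  km <- c(b1 = "bacteria", b2 = "bacteria", f1 = "fungi")
  q1 <- matrix(1, 3, 3, dimnames = dimnames(rho))
  g_empty <- build_network(rho, q1, km)
  expect_equal(igraph::vcount(g_empty), 0)

  q <- matrix(0.01, 3, 3, dimnames = dimnames(rho))
  g <- build_network(rho, q, km, q_max = 0.05, rho_min = 0.6)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::vcount(g), 3)
  el <- igraph::as_edgelist(g)
  sgn <- igraph::E(g)$sign
  expect_equal(sgn[el[, 1] == "b2" & el[, 2] == "f1" |
                   el[, 1] == "f1" & el[, 2] == "b2"], "-")

  # monotone in q_max
  g_strict <- build_network(rho, q, km, q_max = 0.001, rho_min = 0.6)
  expect_lte(igraph::ecount(g_strict), igraph::ecount(g))

  expect_error(build_network(rho, q, km[1:2]), "missing from kingdom map")
})

test_that("kingdom subsetting partitions taxa and preserves samples", {
  mat <- matrix(rpois(24, 10) + 1, 4, 6)
  tab <- make_table(mat)
  km <- setNames(rep(c("bacteria", "fungi"), each = 3), tab$taxon_ids)
  tb <- kingdom_subset_table(tab, km, "bacteria")
  tf <- kingdom_subset_table(tab, km, "fungi")
  expect_length(intersect(tb$taxon_ids, tf$taxon_ids), 0)
  expect_setequal(c(tb$taxon_ids, tf$taxon_ids), tab$taxon_ids)
  expect_identical(tb$sample_ids, tab$sample_ids)
  expect_error(kingdom_subset_table(tab, km, "archaea"), "no taxa")
})

test_that("relative tables are renormalized within the kingdom", {
  mat <- matrix(c(10, 10, 20, 60, 5, 5, 45, 45, 25, 25, 25, 25), 3, 4,
                byrow = TRUE)
  tab <- relative_abundance(make_table(mat))
  km <- setNames(rep(c("bacteria", "fungi"), each = 2), tab$taxon_ids)
  tb <- kingdom_subset_table(tab, km, "bacteria")
  expect_equal(unname(rowSums(tb$values)), rep(1, 3))
  expect_equal(unname(tb$values[1, ]), c(0.5, 0.5))
})

test_that("bipartite extraction keeps exactly the cross-kingdom edges", {
  km <- c(b1 = "bacteria", b2 = "bacteria", b3 = "bacteria",
          f1 = "fungi", f2 = "fungi")
  g <- graph_from_pairs(rbind(c("b1", "b2"), c("b1", "f1"), c("b2", "f1"),
                              c("b3", "f2")), km)
  igraph::E(g)$sign <- c("+", "-", "+", "+")
  mat <- extract_bipartite(g)
  expect_equal(sum(mat), 3)  # one 1 per cross-kingdom edge, sign ignored
  expect_equal(rownames(mat), c("b1", "b2", "b3"))
  expect_equal(colnames(mat), c("f1", "f2"))
  expect_equal(unname(mat["b1", "f1"]), 1L)
  expect_equal(unname(mat["b3", "f1"]), 0L)

  g_bb <- graph_from_pairs(rbind(c("b1", "b2")), km)
  expect_message(empty <- extract_bipartite(g_bb), "empty")
  expect_equal(dim(empty), c(0, 0))

  one <- graph_from_pairs(rbind(c("b1", "f1")), km)
  expect_equal(unname(extract_bipartite(one)), matrix(1L, 1, 1))
})

test_that("edge composition counts sum to the edge total", {
  km <- c(b1 = "bacteria", b2 = "bacteria", f1 = "fungi", f2 = "fungi")
  g <- graph_from_pairs(rbind(c("b1", "b2"), c("b1", "f1"), c("f1", "f2")),
                        km)
  igraph::E(g)$sign <- c("+", "-", "+")
  comp <- edge_composition(g)
  expect_equal(sum(comp), 3)
  expect_equal(unname(comp["pos_bb"]), 1L)
  expect_equal(unname(comp["neg_bf"]), 1L)
  expect_equal(unname(comp["pos_ff"]), 1L)

  empty <- igraph::make_empty_graph(directed = FALSE)
  expect_equal(sum(edge_composition(empty)), 0)

  gb <- graph_from_pairs(rbind(c("b1", "b2")), km)
  igraph::E(gb)$sign <- "+"
  expect_equal(unname(edge_composition(gb)[c("pos_bf", "neg_bf")]),
               c(0L, 0L))
})

test_that("shuffling taxa destroys most edges of a structured dataset", {
  m <- competitive_model(8, 4, seed = 2)
  prof <- simulate_subset_profiles(m, 60, seed = 3)
  tab <- relative_abundance(sample_reads(prof, 20000, seed = 4))
  km <- kingdom_map_of(m)
  n_edges <- function(values) {
    res <- suppressMessages(pairwise_correlation(
      abundance_table(values, "relative"), min_prevalence = 0.1))
    q <- bh_adjust_matrix(res$p)
    igraph::ecount(build_network(res$rho, q, km, q_max = 0.05,
                                 rho_min = 0.35))
  }
  m_obs <- n_edges(tab$values)
  expect_gt(m_obs, 0)
  set.seed(99)
  worse <- replicate(20, {
    shuf <- apply(tab$values, 2, sample)
    dimnames(shuf) <- dimnames(tab$values)
    shuf <- shuf[rowSums(shuf) > 0, , drop = FALSE]
    shuf <- sweep(shuf, 1, rowSums(shuf), "/")
    n_edges(shuf) <= m_obs
  })
  expect_gte(mean(worse), 0.95)
})
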