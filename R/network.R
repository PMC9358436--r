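#' Coerce a taxon-to-kingdom mapping
#'
#' Accepts a named character vector (`taxon -> kingdom`) or a two-column
#' data frame (`taxon_id`, `kingdom`).
#'
#' @param x mapping as described.
#' @param allowed permitted kingdom labels.
#' @return named character vector.
#' @export
as_kingdom_map <- function(x, allowed = c("bacteria", "fungi")) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop("kingdom map data frame needs two columns")
    x <- stats::setNames(as.character(x[[2]]), as.character(x[[1]]))
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("kingdom map must be named by taxon id")
  if (anyDuplicated(names(x)))
    stop("duplicate taxon ids in kingdom map: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0)
    stop("unknown kingdom labels: ", paste(bad, collapse = ", "))
  as.character(x) -> k
  stats::setNames(k, names(x))
}

#' Kingdom map of a simulated gLV community
#'
#' @param model a [glv_model()].
#' @return named character vector, taxon id -> kingdom.
#' @export
kingdom_map_of <- function(model) {
  stopifnot(inherits(model, "glv_model"))
  stats::setNames(model$kingdoms, model$species_ids)
}

#' Centered log-ratio transform of an abundance table
#'
#' Optional guard against compositional artifacts: per sample,
#' `clr(x) = log(x + pseudocount) - mean(log(x + pseudocount))`. Off by
#' default throughout the pipeline, which correlates raw relative
#' abundances; pass a CLR-transformed matrix to [pairwise_correlation()]
#' to use it.
#'
#' @param table an [abundance_table()] or samples-by-taxa matrix.
#' @param pseudocount added to every entry before taking logs.
#' @return samples-by-taxa matrix of CLR values (may be negative, so it is
#'   returned as a plain matrix, not an [abundance_table()]).
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  mat <- if (inherits(table, "abundance_table")) table$values
         else as.matrix(table)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  lg <- log(mat + pseudocount)
  sweep(lg, 1, rowMeans(lg), "-")
}

#' Pairwise taxon-taxon correlations with prevalence filtering
#'
#' Computes Spearman (default) or Pearson correlations between all retained
#' taxa across samples, with two-sided p-values from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`. Taxa present (nonzero) in fewer than
#' `min_prevalence` of samples, and constant taxa (zero variance, undefined
#' correlation), are excluded before computation and reported in the
#' `dropped` attribute and a message. Optionally, permutation p-values
#' (independently permuting sample order) replace the t approximation, for
#' small sample sizes.
#'
#' @param table an [abundance_table()] or a samples-by-taxa matrix.
#' @param method `"spearman"` or `"pearson"`.
#' @param min_prevalence minimum fraction of samples in which a taxon must
#'   be nonzero.
#' @param n_perm if > 0, number of permutations for permutation p-values.
#' @param seed seed for the permutation null (used when `n_perm > 0`).
#' @return list of class `pairwise_correlation`: `rho` (symmetric, unit
#'   diagonal), `p` (two-sided), `n_samples`, `method`,
#'   `dropped` (character vector of excluded taxa).
#' @export
pairwise_correlation <- function(table, method = c("spearman", "pearson"),
                                 min_prevalence = 0.2, n_perm = 0,
                                 seed = 1) {
  method <- match.arg(method)
  mat <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  n <- nrow(mat)
  if (n < 4) stop("need at least 4 samples")
  prev_ok <- colMeans(mat > 0) >= min_prevalence
  const <- apply(mat, 2, function(v) stats::var(v) == 0)
  keep <- prev_ok & !const
  dropped <- colnames(mat)[!keep]
  if (length(dropped) > 0)
    message("dropping ", length(dropped),
            " low-prevalence/constant taxa: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) < 2) stop("fewer than 2 taxa left after prevalence filter")

  rho <- stats::cor(mat, method = method)
  if (n_perm > 0) {
    set.seed(sub_seed(seed, 0L))
    exceed <- matrix(0, ncol(mat), ncol(mat))
    for (b in seq_len(n_perm)) {
      perm <- apply(mat, 2, sample)
      exceed <- exceed + (abs(stats::cor(perm, method = method)) >=
                            abs(rho) - 1e-12)
    }
    p <- (1 + exceed) / (1 + n_perm)
  } else {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(rho) >= 1 - 1e-12] <- 0
  }
  diag(rho) <- 1
  diag(p) <- NA_real_
  structure(list(rho = rho, p = p, n_samples = n, method = method,
                 dropped = dropped),
            class = "pairwise_correlation")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH values in the input order (no silent sorting); each adjusted
#' value is at least its p-value and at most 1.
#'
#' @param p vector of p-values in `[0, 1]` (NAs propagated).
#' @return vector of BH-adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' BH-adjust a symmetric p-value matrix over its upper triangle
#'
#' @param p symmetric p-value matrix (diagonal ignored).
#' @return symmetric matrix of adjusted values, `NA` diagonal.
#' @export
bh_adjust_matrix <- function(p) {
  p <- as.matrix(p)
  ut <- upper.tri(p)
  q <- p
  q[ut] <- bh_adjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- NA_real_
  q
}

#' Build a signed co-occurrence network from correlation and q matrices
#'
#' An undirected edge joins every unordered taxon pair with `q <= q_max`
#' and `|rho| >= rho_min`; its sign is the sign of the correlation. Taxa
#' with no surviving edge are omitted, so every node of the returned graph
#' has degree >= 1 (the convention under which published co-occurrence
#' node counts are reported).
#'
#' @param rho symmetric correlation matrix with taxon dimnames.
#' @param q symmetric matrix of BH-adjusted p-values (same dimnames).
#' @param kingdom_map taxon -> kingdom mapping (see [as_kingdom_map()]);
#'   every taxon of `rho` must be present.
#' @param q_max significance threshold in `[0, 1]`.
#' @param rho_min minimum absolute correlation in `[0, 1]`.
#' @return an \pkg{igraph} undirected graph with vertex attributes `name`,
#'   `kingdom` and edge attributes `rho`, `q`, `sign` (`"+"`/`"-"`), plus
#'   graph attributes recording the thresholds.
#' @export
build_network <- function(rho, q, kingdom_map, q_max = 0.05, rho_min = 0.6) {
  rho <- as.matrix(rho); q <- as.matrix(q)
  if (!all(dim(rho) == dim(q))) stop("rho and q must have the same shape")
  if (any(c(q_max, rho_min) < 0) || any(c(q_max, rho_min) > 1))
    stop("thresholds must be in [0, 1]")
  taxa <- colnames(rho)
  if (is.null(taxa)) stop("rho must have taxon dimnames")
  km <- as_kingdom_map(kingdom_map)
  missing <- setdiff(taxa, names(km))
  if (length(missing) > 0)
    stop("taxa missing from kingdom map: ", paste(missing, collapse = ", "))

  idx <- which(upper.tri(rho), arr.ind = TRUE)
  ok <- !is.na(q[idx]) & q[idx] <= q_max & abs(rho[idx]) >= rho_min
  edges <- data.frame(from = taxa[idx[ok, 1]], to = taxa[idx[ok, 2]],
                      rho = rho[idx][ok], q = q[idx][ok],
                      sign = ifelse(rho[idx][ok] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, kingdom = unname(km[nodes]),
                          stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "q_max", q_max)
  g <- igraph::set_graph_attr(g, "rho_min", rho_min)
  g
}

#' Restrict an abundance table to one kingdom
#'
#' Single-kingdom networks are rebuilt from the kingdom-restricted table
#' (not by deleting nodes from the joint network), so correlations and BH
#' adjustment are recomputed within the kingdom.
#'
#' @param table an [abundance_table()].
#' @param kingdom_map taxon -> kingdom mapping covering the table's taxa.
#' @param kingdom kingdom label to keep.
#' @return an [abundance_table()] with columns restricted to that kingdom;
#'   samples (ids and order) unchanged. Relative tables are renormalized
#'   within the kingdom, i.e. relative abundances are recomputed from the
#'   kingdom-restricted data; samples with no reads of that kingdom are an
#'   error.
#' @export
kingdom_subset_table <- function(table, kingdom_map, kingdom) {
  stopifnot(inherits(table, "abundance_table"))
  km <- as_kingdom_map(kingdom_map)
  missing <- setdiff(table$taxon_ids, names(km))
  if (length(missing) > 0)
    stop("taxa missing from kingdom map: ", paste(missing, collapse = ", "))
  if (!kingdom %in% km) stop("no taxa of kingdom '", kingdom, "' in the map")
  keep <- table$taxon_ids[km[table$taxon_ids] == kingdom]
  if (length(keep) == 0)
    stop("no taxa of kingdom '", kingdom, "' in the table")
  vals <- table$values[, keep, drop = FALSE]
  if (table$kind == "relative") {
    rs <- rowSums(vals)
    if (any(rs == 0))
      stop("samples with no ", kingdom, " reads cannot be renormalized: ",
           paste(rownames(vals)[rs == 0], collapse = ", "))
    vals <- sweep(vals, 1, rs, "/")
  }
  abundance_table(vals, kind = table$kind)
}

#' Extract the bacteria-by-fungi bipartite incidence matrix
#'
#' Only edges connecting a bacterial and a fungal node are used: each such
#' edge (regardless of sign) becomes a 1 in a binary matrix with bacterial
#' rows and fungal columns. All-zero rows and columns are dropped.
#'
#' @param net a network from [build_network()] (vertex attribute `kingdom`).
#' @return binary incidence matrix with bacterial row names and fungal
#'   column names; possibly 0-by-0 (a message flags an empty result).
#' @export
extract_bipartite <- function(net) {
  if (!"kingdom" %in% igraph::vertex_attr_names(net))
    stop("network has no kingdom labels")
  if (igraph::ecount(net) == 0) {
    message("no cross-kingdom edges; bipartite matrix is empty")
    return(matrix(0L, 0, 0))
  }
  el <- igraph::as_edgelist(net)
  kv <- stats::setNames(igraph::V(net)$kingdom, igraph::V(net)$name)
  cross <- kv[el[, 1]] != kv[el[, 2]]
  if (!any(cross)) {
    message("no cross-kingdom edges; bipartite matrix is empty")
    return(matrix(0L, 0, 0))
  }
  el <- el[cross, , drop = FALSE]
  b <- ifelse(kv[el[, 1]] == "bacteria", el[, 1], el[, 2])
  f <- ifelse(kv[el[, 1]] == "fungi", el[, 1], el[, 2])
  rows <- sort(unique(b)); cols <- sort(unique(f))
  mat <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  mat[cbind(b, f)] <- 1L
  mat
}

#' Edge composition of a signed cross-kingdom network
#'
#' Counts edges by sign and kingdom category.
#'
#' @param net a network from [build_network()].
#' @return named integer vector with entries `pos_bb`, `pos_ff`, `pos_bf`,
#'   `neg_bb`, `neg_ff`, `neg_bf`, summing to the edge count.
#' @export
edge_composition <- function(net) {
  out <- c(pos_bb = 0L, pos_ff = 0L, pos_bf = 0L,
           neg_bb = 0L, neg_ff = 0L, neg_bf = 0L)
  if (igraph::ecount(net) == 0) return(out)
  el <- igraph::as_edgelist(net)
  kv <- stats::setNames(igraph::V(net)$kingdom, igraph::V(net)$name)
  k1 <- kv[el[, 1]]; k2 <- kv[el[, 2]]
  cat3 <- ifelse(k1 != k2, "bf", ifelse(k1 == "bacteria", "bb", "ff"))
  sgn <- ifelse(igraph::E(net)$sign == "+", "pos", "neg")
  tab <- table(paste(sgn, cat3, sep = "_"))
  out[names(tab)] <- as.integer(tab)
  out
}
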