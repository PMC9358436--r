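#' Read a samples-by-taxa abundance TSV
#'
#' First column = sample id, header row = taxon ids.
#'
#' @param path TSV file.
#' @param kind `"auto"` (counts if all integer, relative if rows sum to 1),
#'   `"counts"` or `"relative"`.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, kind = "auto") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed abundance TSV: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("malformed abundance TSV (non-numeric values)")
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (kind == "auto")
    kind <- if (max(abs(rowSums(mat) - 1)) < 1e-6) "relative" else "counts"
  abundance_table(mat, kind = kind)
}

#' Write an abundance table as TSV
#'
#' @param table an [abundance_table()].
#' @param path output file; first column `sample_id`.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(sample_id = table$sample_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxon-to-kingdom map TSV
#'
#' Two columns: `taxon_id`, `kingdom`.
#'
#' @param path TSV file.
#' @param allowed permitted kingdom labels.
#' @return named character vector (taxon -> kingdom).
#' @export
read_kingdom_map <- function(path, allowed = c("bacteria", "fungi")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed kingdom map TSV: ", path)
  as_kingdom_map(df[, 1:2], allowed = allowed)
}

#' Write a kingdom map as TSV
#'
#' @param kingdom_map named character vector or 2-column data frame.
#' @param path output file.
#' @export
write_kingdom_map <- function(kingdom_map, path) {
  km <- as_kingdom_map(kingdom_map)
  utils::write.table(
    data.frame(taxon_id = names(km), kingdom = unname(km)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load and validate an abundance table plus its kingdom map
#'
#' @param abundance_path abundance TSV (see [read_abundance_table()]).
#' @param kingdom_path kingdom map TSV (see [read_kingdom_map()]).
#' @return list with `table` and `kingdom_map`; taxa missing from the map
#'   are an error naming the offenders.
#' @export
load_inputs <- function(abundance_path, kingdom_path) {
  table <- read_abundance_table(abundance_path)
  km <- read_kingdom_map(kingdom_path)
  missing <- setdiff(table$taxon_ids, names(km))
  if (length(missing) > 0)
    stop("taxa missing from kingdom map: ", paste(missing, collapse = ", "))
  list(table = table, kingdom_map = km)
}

#' Export a co-occurrence network
#'
#' @param net an \pkg{igraph} graph from [build_network()].
#' @param path output file.
#' @param format `"graphml"` (full attributed graph) or `"edgelist"` (TSV
#'   `u, v, rho, q, sign`).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    if (igraph::ecount(net) > 0) {
      el <- igraph::as_edgelist(net)
      df <- data.frame(u = el[, 1], v = el[, 2],
                       rho = igraph::E(net)$rho, q = igraph::E(net)$q,
                       sign = igraph::E(net)$sign, stringsAsFactors = FALSE)
    } else {
      df <- data.frame(u = character(0), v = character(0),
                       rho = numeric(0), q = numeric(0),
                       sign = character(0))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Import a co-occurrence network
#'
#' @param path file written by [export_network()].
#' @param format `"graphml"` or `"edgelist"`.
#' @param kingdom_map required for `"edgelist"` (edge lists do not carry
#'   node attributes).
#' @return an \pkg{igraph} undirected graph.
#' @export
import_network <- function(path, format = c("graphml", "edgelist"),
                           kingdom_map = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g)
    return(g)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(u = "character", v = "character"))
  nodes <- sort(unique(c(df$u, df$v)))
  vert <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(kingdom_map)) {
    km <- as_kingdom_map(kingdom_map)
    vert$kingdom <- unname(km[nodes])
  }
  igraph::graph_from_data_frame(df, directed = FALSE, vertices = vert)
}

#' Serialize a gLV model to JSON
#'
#' Fields: `species_ids`, `kingdoms`, `r`, `A` (row-major).
#'
#' @param model a [glv_model()].
#' @param path output JSON file.
#' @export
write_glv_model <- function(model, path) {
  stopifnot(inherits(model, "glv_model"))
  jsonlite::write_json(
    list(species_ids = model$species_ids, kingdoms = model$kingdoms,
         r = unname(model$r), A = as.numeric(t(model$A)), n = model$n),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a gLV model from JSON
#'
#' @param path file written by [write_glv_model()].
#' @return a [glv_model()].
#' @export
read_glv_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(j$n)
  glv_model(j$species_ids, j$kingdoms, j$r,
            matrix(j$A, n, n, byrow = TRUE))
}
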