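#' Configuration for the full cross-kingdom comparison pipeline
#'
#' A condition is either a simulated community (simulation parameters) or a
#' pair of input files (`abundance_path`, `kingdom_path`). Defaults follow
#' the package's simulated study design: 40 bacteria + 15 fungi, 150
#' subset-samples per condition, multinomial sequencing at 50,000 reads.
#'
#' @param conditions named list of condition specs; each element is a list
#'   either with file paths (`abundance_path`, `kingdom_path`) or with
#'   simulation parameters understood by [sample_glv_model()] /
#'   [simulate_subset_profiles()] / [sample_reads()] (`n_bacteria`,
#'   `n_fungi`, `connectance_target`, `frac_cross_kingdom`, `sign_mix`,
#'   `strength_scale`, `n_subsets`, `inclusion_prob`, `depth`).
#' @param method,min_prevalence,q_max,rho_min correlation network settings
#'   (see [pairwise_correlation()] and [build_network()]).
#' @param n_random random-attack replicates per network.
#' @param n_null_unipartite degree-preserving null replicates for
#'   [summary_zscores()].
#' @param n_null_bipartite curveball null samples for [nodf_pvalue()].
#' @param seed master seed; every stochastic stage derives its sub-seed
#'   from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(conditions = list(
                         wild = list(n_bacteria = 40, n_fungi = 15,
                                     frac_cross_kingdom = 0.6),
                         domesticated = list(n_bacteria = 40, n_fungi = 15,
                                             frac_cross_kingdom = 0.15)),
                       method = "spearman", min_prevalence = 0.2,
                       q_max = 0.05, rho_min = 0.35,
                       n_random = 100, n_null_unipartite = 200,
                       n_null_bipartite = 1000, seed = 1) {
  defaults <- list(n_bacteria = 40, n_fungi = 15, connectance_target = 0.12,
                   frac_cross_kingdom = 0.5,
                   strength_scale = 0.3, n_subsets = 150,
                   inclusion_prob = 0.5, depth = 50000)
  conditions <- lapply(conditions, function(cd) {
    if (!is.null(cd$abundance_path)) return(cd)
    utils::modifyList(defaults, cd)
  })
  structure(list(conditions = conditions, method = method,
                 min_prevalence = min_prevalence, q_max = q_max,
                 rho_min = rho_min, n_random = n_random,
                 n_null_unipartite = n_null_unipartite,
                 n_null_bipartite = n_null_bipartite, seed = seed),
            class = "run_config")
}

# FNV-1a over the deparsed config; provenance fingerprint only.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

collect_condition_table <- function(cd, seed) {
  if (!is.null(cd$abundance_path)) {
    inp <- load_inputs(cd$abundance_path, cd$kingdom_path)
    return(list(table = relative_abundance(inp$table),
                kingdom_map = inp$kingdom_map))
  }
  model <- sample_glv_model(cd$n_bacteria, cd$n_fungi,
                            connectance_target = cd$connectance_target,
                            frac_cross_kingdom = cd$frac_cross_kingdom,
                            strength_scale = cd$strength_scale,
                            seed = sub_seed(seed, 1L))
  prof <- simulate_subset_profiles(model, n_subsets = cd$n_subsets,
                                   inclusion_prob = cd$inclusion_prob,
                                   seed = sub_seed(seed, 2L))
  reads <- sample_reads(prof, depth = cd$depth, seed = sub_seed(seed, 3L))
  list(table = relative_abundance(reads),
       kingdom_map = kingdom_map_of(model), model = model)
}

analyze_network <- function(net, config, seed) {
  res <- list(summary = network_summary(net, seed = 1))
  if (igraph::vcount(net) < 3 || igraph::ecount(net) < 2) {
    res$skipped <- "network too small for robustness/null analysis"
    return(res)
  }
  rb <- robustness_analysis(net, n_random = config$n_random,
                            seed = sub_seed(seed, 11L))
  res$robustness_auc <- as.list(rb$auc)
  res$random_auc_sd <- rb$random_auc_sd
  zs <- summary_zscores(net, n_null = config$n_null_unipartite,
                        seed = sub_seed(seed, 12L))
  res$zscores <- lapply(zs, function(r) r[c("observed", "null_mean",
                                            "null_sd", "normalized",
                                            "rule", "n_null")])
  res
}

build_condition_networks <- function(table, km, config) {
  corr <- suppressMessages(
    pairwise_correlation(table, method = config$method,
                         min_prevalence = config$min_prevalence))
  q <- bh_adjust_matrix(corr$p)
  cross <- build_network(corr$rho, q, km, q_max = config$q_max,
                         rho_min = config$rho_min)
  tb <- kingdom_subset_table(table, km, "bacteria")
  corr_b <- suppressMessages(
    pairwise_correlation(tb, method = config$method,
                         min_prevalence = config$min_prevalence))
  qb <- bh_adjust_matrix(corr_b$p)
  bacteria <- build_network(corr_b$rho, qb, km, q_max = config$q_max,
                            rho_min = config$rho_min)
  list(cross = cross, bacteria_only = bacteria)
}

#' Run the full cross-kingdom comparison pipeline
#'
#' For each condition: obtain the abundance table (simulated gLV community
#' or input files), build the cross-kingdom network from the full table and
#' the bacteria-only network from the kingdom-restricted table, then run
#' topology summaries, paired centrality shifts (bacteria-only vs
#' cross-kingdom), extinction robustness under all four attack strategies,
#' degree-preserving null Z-scores, and bipartite NODF nestedness with a
#' curveball permutation test. All randomness derives from the master seed,
#' so a report is byte-for-byte reproducible from config + seed.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory; when given, the report JSON,
#'   network GraphML/edge-list files and TSV tables are written there.
#' @return nested list (class `analysis_report`) with per-condition
#'   sections (`networks`, `centrality_shift`, `nestedness`) plus
#'   `provenance` and machine-readable `warnings`.
#' @export
run_full_comparison <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  warn <- list()
  note <- function(stage, msg)
    warn[[length(warn) + 1]] <<- list(stage = stage, message = msg)

  report <- list(
    provenance = list(package_version = as.character(
                        utils::packageVersion("xknet")),
                      config_hash = config_hash(unclass(config)),
                      seed = config$seed),
    conditions = list())

  for (ci in seq_along(config$conditions)) {
    cname <- names(config$conditions)[ci]
    # same stream for every condition: identical condition specs yield
    # identical sections, and conditions differ only through their parameters
    cseed <- sub_seed(config$seed, 100L)
    dat <- withCallingHandlers(
      collect_condition_table(config$conditions[[ci]], cseed),
      warning = function(w) {
        note(paste0(cname, "/simulate"), conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    nets <- withCallingHandlers(
      build_condition_networks(dat$table, dat$kingdom_map, config),
      warning = function(w) {
        note(paste0(cname, "/network"), conditionMessage(w))
        invokeRestart("muffleWarning")
      })

    sec <- list(networks = list())
    for (nn in names(nets)) {
      sec$networks[[nn]] <- withCallingHandlers(
        analyze_network(nets[[nn]], config, sub_seed(cseed, match(nn, names(nets)))),
        warning = function(w) {
          note(paste(cname, nn, sep = "/"), conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }

    shared <- intersect(igraph::V(nets$bacteria_only)$name,
                        igraph::V(nets$cross)$name)
    if (length(shared) > 0) {
      sec$centrality_shift <- lapply(
        c(betweenness = "betweenness", eigenvector = "eigenvector"),
        function(met) {
          cs <- suppressWarnings(
            compare_centrality(nets$bacteria_only, nets$cross, met))
          cs$summary
        })
    } else {
      note(paste0(cname, "/centrality_shift"), "no shared nodes")
    }

    bip <- withCallingHandlers(suppressMessages(extract_bipartite(nets$cross)),
      warning = function(w) {
        note(paste0(cname, "/bipartite"), conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (nrow(bip) >= 2 && ncol(bip) >= 2) {
      nr <- withCallingHandlers(
        nodf_pvalue(bip, n_null = config$n_null_bipartite,
                    seed = sub_seed(cseed, 40L)),
        warning = function(w) {
          note(paste0(cname, "/nestedness"), conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      sec$nestedness <- nr[c("nodf", "row_component", "col_component",
                             "n_rows", "n_cols", "p_value", "n_null")]
    } else {
      note(paste0(cname, "/nestedness"),
           "bipartite matrix too small; nestedness skipped")
    }

    report$conditions[[cname]] <- sec

    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      for (nn in names(nets)) {
        export_network(nets[[nn]],
                       file.path(outdir, paste0(cname, "_", nn, ".graphml")),
                       "graphml")
        export_network(nets[[nn]],
                       file.path(outdir, paste0(cname, "_", nn, "_edges.tsv")),
                       "edgelist")
      }
      write_abundance_table(dat$table,
                            file.path(outdir, paste0(cname, "_abundance.tsv")))
      write_kingdom_map(dat$kingdom_map,
                        file.path(outdir, paste0(cname, "_kingdoms.tsv")))
    }
  }

  report$warnings <- warn
  class(report) <- "analysis_report"
  if (!is.null(outdir))
    write_report(report, file.path(outdir, "report.json"))
  report
}

#' Write an analysis report as JSON
#'
#' @param report an `analysis_report` from [run_full_comparison()].
#' @param path output JSON file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Validate an analysis report against the bundled JSON schema
#'
#' Light structural validation: checks the `required` properties listed in
#' `inst/schema/analysis_report.schema.json` at the top level and per
#' condition.
#'
#' @param report an `analysis_report` or a path to a report JSON file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  schema <- jsonlite::read_json(
    system.file("schema", "analysis_report.schema.json", package = "xknet"),
    simplifyVector = TRUE)
  for (f in schema$required)
    if (is.null(report[[f]])) stop("report missing required field: ", f)
  for (f in schema$properties$provenance$required)
    if (is.null(report$provenance[[f]]))
      stop("provenance missing required field: ", f)
  creq <- schema$definitions$condition$required
  for (cn in names(report$conditions))
    for (f in creq)
      if (is.null(report$conditions[[cn]][[f]]))
        stop("condition '", cn, "' missing required field: ", f)
  invisible(TRUE)
}
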