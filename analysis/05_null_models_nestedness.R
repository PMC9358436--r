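#!/usr/bin/env Rscript
# Null-model analysis of the four networks: connectance, transitivity and
# modularity Z-score-normalized against 200 degree-preserving (double-edge
# swap) configuration nulls — connectance has zero spread under such nulls,
# so it falls back to the divide-by-mean rule. For each cross-kingdom
# network, the bacteria x fungi incidence matrix is tested for NODF
# nestedness against 1000 curveball (fixed-margins) nulls.
#
# Reads:  results/<condition>_{cross,bacteria_only}.graphml   (02)
# Writes: results/summary_zscores.tsv, results/nestedness.tsv

suppressPackageStartupMessages({library(xknet); library(igraph)})

seed <- 20260927
ztabs <- list(); nest <- list()
for (cn in c("wild", "domesticated")) {
  for (nn in c("cross", "bacteria_only")) {
    net <- import_network(file.path("results",
                                    paste0(cn, "_", nn, ".graphml")))
    if (ecount(net) < 2) { cat(cn, nn, "too few edges; skipped\n"); next }
    zs <- suppressWarnings(summary_zscores(net, n_null = 200,
                                           seed = sub_seed(seed, 70)))
    ztabs[[paste(cn, nn)]] <- cbind(condition = cn, network = nn,
                                    zscore_table(zs))
  }
  cross <- import_network(file.path("results", paste0(cn, "_cross.graphml")))
  bip <- suppressMessages(extract_bipartite(cross))
  if (nrow(bip) >= 2 && ncol(bip) >= 2) {
    res <- nodf_pvalue(bip, n_null = 1000, seed = sub_seed(seed, 71))
    nest[[cn]] <- data.frame(condition = cn, nodf = res$nodf,
                             n_bacteria = res$n_rows, n_fungi = res$n_cols,
                             p_value = res$p_value, n_null = res$n_null)
    cat(sprintf("%s: NODF = %.4f (%d x %d incidence), curveball p = %.3f\n",
                cn, res$nodf, res$n_rows, res$n_cols, res$p_value))
  } else {
    cat(cn, ": bipartite incidence too small for nestedness\n")
  }
}
write.table(do.call(rbind, ztabs), "results/summary_zscores.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
if (length(nest) > 0)
  write.table(do.call(rbind, nest), "results/nestedness.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
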