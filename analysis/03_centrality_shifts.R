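#!/usr/bin/env Rscript
# How does adding fungi change the importance of bacterial nodes?
# For each condition, pair the bacterial nodes shared by the bacteria-only
# and the cross-kingdom network and compare their betweenness and
# eigenvector centrality (the y = x comparison of the four-network figure).
#
# Reads:  results/<condition>_{cross,bacteria_only}.graphml   (02)
# Writes: results/centrality_<condition>_<network>.tsv,
#         results/centrality_shifts.tsv

suppressPackageStartupMessages({library(xknet); library(igraph)})

rows <- list()
for (cn in c("wild", "domesticated")) {
  cross <- import_network(file.path("results", paste0(cn, "_cross.graphml")))
  bact <- import_network(file.path("results",
                                   paste0(cn, "_bacteria_only.graphml")))
  for (nn in c("cross", "bacteria_only")) {
    net <- if (nn == "cross") cross else bact
    ct <- suppressWarnings(centralities(net))
    write.table(ct, file.path("results",
                              paste0("centrality_", cn, "_", nn, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (met in c("betweenness", "eigenvector")) {
    cs <- suppressWarnings(compare_centrality(bact, cross, met))
    rows[[paste(cn, met)]] <- data.frame(
      condition = cn, metric = met, n_shared = cs$summary$n_shared,
      n_increased = cs$summary$n_increased,
      n_decreased = cs$summary$n_decreased,
      mean_delta = cs$summary$mean_delta)
    cat(sprintf(
      "%s / %s: %d shared bacterial nodes, %d gained, %d lost, mean delta %+.4f\n",
      cn, met, cs$summary$n_shared, cs$summary$n_increased,
      cs$summary$n_decreased, cs$summary$mean_delta))
  }
}
write.table(do.call(rbind, rows), "results/centrality_shifts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
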