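#!/usr/bin/env Rscript
# Step 4: gene-gene epistasis networks.
#
# Builds one gene network per stratum and trait from the significant
# inter-genic pairs (max-edge curation), merges them across strata, computes
# the six centrality indices on the merged network, and subtracts the
# whole-cohort ("core") network to expose interactions only visible after
# the partition.

library(mixepinet)

out_dir <- "results"
scans <- readRDS("scratch/scans.rds")
alpha_star <- scans[[1]]$alpha_star
gene_universe <- unique(read.delim("scratch/analysis_data/panel.tsv")$gene)

is_stratum <- !grepl("^all\\.", names(scans))
nets <- lapply(scans[is_stratum], build_gene_network, alpha_star = alpha_star,
               gene_universe = gene_universe)
core <- merge_networks(lapply(scans[!is_stratum], build_gene_network,
                              alpha_star = alpha_star,
                              gene_universe = gene_universe))
merged <- merge_networks(nets)
residual <- subtract_network(merged, core)

cat(sprintf("merged network: %d of %d possible links (%.1f%%)\n",
            nrow(merged$edges), choose(length(gene_universe), 2),
            100 * nrow(merged$edges) / choose(length(gene_universe), 2)))
cat(sprintf("core (whole-cohort) network: %d links\n", nrow(core$edges)))
cat(sprintf("residual after core subtraction: %d links\n",
            nrow(residual$edges)))

write_network(merged, file.path(out_dir, "merged.net"))
write_network(merged, file.path(out_dir, "merged.graphml"))
write_network(merged, file.path(out_dir, "merged.tsv"))
write_network(core, file.path(out_dir, "core.tsv"))
write_network(residual, file.path(out_dir, "residual.tsv"))

if (nrow(merged$edges)) {
  cent <- centrality_indices(merged)
  write.table(cent, file.path(out_dir, "centrality.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("\ntop genes by betweenness:\n")
  print(head(cent[order(-cent$betweenness),
                  c("gene", "degree", "closeness", "betweenness", "stress",
                    "centroid", "katz")], 8), digits = 3)
}
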