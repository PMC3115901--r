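#!/usr/bin/env Rscript
# Step 3: per-subpopulation two-locus epistasis scans.
#
# Within each modal class of the partition, re-runs SNP QC (allele
# frequencies, monomorphism, HWE exact test) and decomposes every testable
# SNP pair into orthogonal variance components for both blood-pressure
# traits at the Bonferroni threshold derived from (0.05, candidate pairs,
# K, 2 traits). Also runs the whole-cohort scan (used as the "core" network
# source in step 4) and the case-control scan dichotomized at 90/140 mmHg.

library(mixepinet)

data_dir <- "scratch/analysis_data"
out_dir <- "results"

G <- read_genotypes(file.path(data_dir, "genotypes.tsv"),
                    file.path(data_dir, "panel.tsv"))
pheno <- read_phenotypes(file.path(data_dir, "phenotypes.tsv"),
                         indicators = c("diastolic", "systolic"),
                         covariates = sprintf("z%02d", 1:10))
part <- read.delim(file.path(out_dir, "partition.tsv"))
stopifnot(identical(part$subject_id, pheno$data$subject_id))
K <- max(part$modal)

qc <- allele_stats(G)
m <- sum(qc$informative)
alpha_star <- bonferroni_threshold(0.05, n_pairs = m * (m - 1) / 2,
                                   n_subpops = K, n_traits = 2)
cat(sprintf("%d informative SNPs, %d candidate pairs, alpha* = %.3g\n",
            m, m * (m - 1) / 2, alpha_star))

scans <- list()
for (k in seq_len(K)) {
  for (tr in c("diastolic", "systolic")) {
    scans[[sprintf("%d.%s", k, tr)]] <- scan_subpopulation(
      pheno$data[[tr]], G, which(part$modal == k), alpha_star,
      trait_name = tr, subpop = k)
  }
}
# whole-cohort scan per trait: the population-level "core" signal
for (tr in c("diastolic", "systolic")) {
  scans[[sprintf("all.%s", tr)]] <- scan_subpopulation(
    pheno$data[[tr]], G, seq_len(nrow(part)), alpha_star,
    trait_name = tr, subpop = "all")
}

summary_tab <- summarize_scan(scans)
write.table(summary_tab, file.path(out_dir, "scan_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

all_pairs <- do.call(rbind, lapply(scans, function(s) s$pairs))
sig <- all_pairs[all_pairs$significant, , drop = FALSE]
write.table(sig, file.path(out_dir, "significant_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(scans, "scratch/scans.rds")

cat("\nper-stratum interaction counts:\n")
print(summary_tab[, c("subpop", "trait", "n_subjects", "n_testable_pairs",
                      "n_significant", "fraction_significant")], digits = 3)

cc <- dichotomized_scan(pheno$data$diastolic, pheno$data$systolic, G = G,
                        alpha_star = alpha_star)
h2max <- max(cc$heritability$h2, na.rm = TRUE)
cat(sprintf("\ncase-control (90/140 rule): %d cases / %d controls\n",
            cc$n_cases, cc$n_controls))
cat(sprintf("maximal single-SNP case-control heritability: %.4f\n", h2max))
cat(sprintf("case-control significant pairs: %d\n", cc$scan$n_significant))
write.table(cc$heritability, file.path(out_dir, "casecontrol_h2.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
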