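#!/usr/bin/env Rscript
# Step 1: simulate the cohort-scale study data.
#
# Generates the default cohort: n = 2,523 subjects, 45 SNPs in 23 genes,
# two blood-pressure indicators, ten covariates, four latent classes with a
# strong additive-by-additive SPTLC3 x CERK effect planted in the top
# (hypertensive-like) class. Raw data land in scratch/ (they are large and
# fully regenerable); downstream steps read them from there.

library(mixepinet)

data_dir <- "scratch/analysis_data"
scn <- monica_like_scenario(K_true = 4, n_subjects = 2523, seed = 20090301)
paths <- simulate_to_files(scn, data_dir)
saveRDS(scn, file.path(data_dir, "scenario.rds"))

sim <- paths$sim
cat(sprintf("simulated %d subjects x %d SNPs (%d genes)\n",
            length(sim$genotypes$subject_id), ncol(sim$genotypes$dosage),
            length(unique(sim$genotypes$panel$gene))))
cat(sprintf("true class sizes: %s\n",
            paste(tabulate(sim$truth$labels, scn$K_true), collapse = ", ")))
ef <- sim$truth$effects[[1]]
cat(sprintf("planted %s effect %s x %s, beta = %g, class %s, expected V = %.2f\n",
            ef$component, ef$snp_a, ef$snp_b, ef$beta, ef$target_class,
            ef$expected_variance))
cat(sprintf("expected relative epistatic variance in the target class: %.3f\n",
            ef$expected_variance / (ef$expected_variance + scn$class_sds[4, 1]^2)))
cat(sprintf("files under %s\n", data_dir))
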