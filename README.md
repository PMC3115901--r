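# mixepinet

Mixture-resolved two-locus epistasis networks for quantitative traits.

## The problem

Population cohorts are physiologically heterogeneous: a blood-pressure
cohort mixes subgroups whose genetics act differently, and pooling them
dilutes genetic — especially epistatic — signals. `mixepinet` implements a
two-step analysis for this setting, aimed at statistical geneticists
working with candidate SNP panels and correlated quantitative indicators:

1. **Resolve heterogeneity.** Fit the covariate-gated finite mixture

   *f*(**y** | **z**) = Σ<sub>x</sub> π(x | **z**) *f*(**y** | x, **z**)

   over the indicator traits **y** (diastolic/systolic blood pressure) with
   multinomial-logit gating π(x | **z**) on the covariates **z**, by EM with
   restarts. Select the class count K by the sample-size-adjusted BIC,
   −2ℓ + d·ln((n+2)/24), with an entropy tie-break, and assign each subject
   to their modal class.

2. **Decompose and connect.** Within each subpopulation, regress the trait
   on the orthogonal Cockerham contrasts of every SNP pair —
   w<sub>A</sub>: {0,1,2} → {−2p, q−p, 2q}, w<sub>D</sub>: {0,1,2} →
   {−p², pq, −q²} — plus their four products, yielding variance components
   V<sub>A</sub>, V<sub>D</sub>, V<sub>AA</sub>, V<sub>AD</sub>,
   V<sub>DA</sub>, V<sub>DD</sub>. The relative epistatic variance
   (V<sub>AA</sub>+V<sub>AD</sub>+V<sub>DA</sub>+V<sub>DD</sub>)/V<sub>P</sub>
   of significant inter-genic pairs (joint 4-df F-test at the Bonferroni
   threshold α/(n<sub>pairs</sub>·n<sub>subpops</sub>·n<sub>traits</sub>))
   weights the edges of gene-gene networks, which support six centrality
   indices (degree, closeness, betweenness, stress, centroid, Katz,
   closeness vitality), merging across subpopulations, and core-network
   subtraction.

QC is built in: per-stratum allele frequencies, monomorphism, the
Hardy-Weinberg exact test (HWE failures are excluded from decomposition),
and two-locus EM linkage disequilibrium (D, D′, r²). A synthetic-cohort
generator with planted effects of known analytic variance provides ground
truth for every stage; the methods vignette
(`vignettes/mixture-epistasis-networks.Rmd`) documents the model,
conventions and limitations.

## Worked example

```r
library(mixepinet)

# a 2-class cohort of 1,000 subjects over the 45-SNP / 23-gene panel,
# with a strong additive-by-additive pair planted in the top class
scn <- monica_like_scenario(K_true = 2, n_subjects = 1000, seed = 11)
sim <- simulate_population(scn)

fit <- fit_mixture(sim$phenotypes, 2, mix_config(restarts = 3, seed = 5))
fit
#> mixture_model: K=2, n=1000, loglik=-7261.06, d=19, aBIC=14593.03
round(fit$means, 1)
#>      [,1]  [,2]
#> [1,] 72.9 116.1
#> [2,] 87.9 135.2
```

The two recovered classes sit at 73/116 and 88/135 mmHg (diastolic/
systolic), matching the planted class means; the gating coefficients on the
first three covariates come back as 0.85, −0.52, 0.31 against the true
0.8, −0.5, 0.3, and the modal assignment disagrees with the simulated
labels for only ~5% of subjects (entropy 0.85).

```r
dec <- decompose_pair(sim$phenotypes$data$diastolic,
                      sim$genotypes$dosage[, "rs01505"],
                      sim$genotypes$dosage[, "rs05141"])
```

Run on a 50,000-subject single-class cohort with a planted
additive-by-additive effect of analytic relative variance 0.5, this returns
`dec$rel_epistatic` = 0.498 with the AA component dominating every other
component by more than two orders of magnitude.

The full workflow — simulate, partition, scan, networks, report — is in
`analysis/01_simulate.R` … `analysis/05_report.R`; each script prints what
it found and writes its tables under `results/`. `run_pipeline()` chains
the same steps programmatically and writes a byte-reproducible report
bundle (partition, selection, scan, QC, summary tables, Pajek/GraphML/TSV
networks, structured exclusion log, manifest).

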