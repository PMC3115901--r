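test_that("allele statistics count, flag and book-keep correctly", {
  expect_true(allele_stats(matrix(c(0, 0, 0, 0), 4))$monomorphic)
  expect_equal(allele_stats(matrix(c(0, 0, 0, 0), 4))$p, 0)
  expect_equal(allele_stats(matrix(c(0, 1, 2, 1), 4))$p, 0.5)

  # 106-SNP panel: 5 all-missing, 56 monomorphic, 45 informative
  set.seed(1)
  n <- 40
  cols <- c(
    replicate(5, rep(NA_integer_, n), simplify = FALSE),
    replicate(56, rep(0L, n), simplify = FALSE),
    replicate(45, {
      g <- rbinom(n, 2, 0.4)
      g[1] <- 0L; g[2] <- 1L   # guarantee polymorphism
      g
    }, simplify = FALSE))
  G <- do.call(cbind, cols)
  colnames(G) <- sprintf("snp%03d", 1:106)
  st <- allele_stats(G)
  expect_equal(sum(st$all_missing), 5)
  expect_equal(sum(st$monomorphic), 56)
  expect_equal(sum(st$informative), 45)
})

test_that("the HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_test(c(0, 0, 50)), 1)
  expect_equal(hwe_exact_test(c(5, 0, 5)), hwe_oracle(5, 0, 5), tolerance = 1e-12)
  # exact-HWE counts at n = 10000 sit deep in the null
  g <- exact_hwe_genotypes(0.3, 10000)
  cnt <- tabulate(factor(g, 0:2), 3)
  expect_gt(hwe_exact_test(cnt), 0.5)
  expect_error(hwe_exact_test(c(0, 0, 0)), "zero")

  # property: all tables with up to 50 alleles
  set.seed(2)
  for (i in 1:60) {
    n <- sample(3:25, 1)
    n1 <- sample(0:n, 1); n2 <- sample(0:(n - n1), 1)
    n0 <- n - n1 - n2
    expect_equal(hwe_exact_test(c(n0, n1, n2)), hwe_oracle(n0, n1, n2),
                 tolerance = 1e-9)
  }
})

test_that("two-locus EM LD recovers phase and matches a grid-search oracle", {
  # perfect coupling, phase-unambiguous ({0,2} only)
  g <- rep(c(0L, 2L), c(30, 20))
  ld <- ld_pair(g, g)
  expect_equal(ld$Dprime, 1)
  expect_equal(ld$r2, 1)

  # independent SNPs: tiny r2, roughly uniform p over replicates
  pv <- vapply(1:50, function(i) {
    set.seed(400 + i)
    a <- rbinom(10000, 2, 0.3); b <- rbinom(10000, 2, 0.4)
    ld <- ld_pair(a, b)
    expect_lt(ld$r2, 0.01)
    ld$p
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)

  # EM log-likelihood equals a grid search over f_AB within 1e-6
  set.seed(9)
  pan <- panel_spec(c("a", "b"), "G", c(0.35, 0.45),
                    ld_block = c("B", "B"), ld_r2 = c(NA, 0.4))
  G <- simulate_genotypes(pan, 500, seed = 10)
  ga <- G$dosage[, 1]; gb <- G$dosage[, 2]
  ld <- ld_pair(ga, gb)
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  pa <- mean(ga) / 2; pb <- mean(gb) / 2
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  grid <- seq(lo + 1e-9, hi - 1e-9, length.out = 20001)
  lls <- vapply(grid, function(fab) {
    f <- c(AB = fab, Ab = pa - fab, aB = pb - fab, ab = 1 - pa - pb + fab)
    mixepinet:::ld_loglik(tab, f)
  }, numeric(1))
  expect_lt(abs(ld$loglik - max(lls)), 1e-6)

  expect_error(ld_pair(rep(1L, 50), rbinom(50, 2, 0.5)), "monomorphic")
})

test_that("Cockerham contrasts have the stated values and symmetries", {
  w <- contrast_scores(c(0, 1, 2), 0.5)
  expect_equal(w$w_a, c(-1, 0, 1))
  expect_equal(w$w_d, c(-0.25, 0.25, -0.25))

  g <- exact_hwe_genotypes(0.4, 1000)
  w <- contrast_scores(g, 0.4)
  expect_lt(abs(mean(w$w_a)), 1e-12)
  expect_lt(abs(mean(w$w_d)), 1e-12)
  expect_lt(abs(mean(w$w_a * w$w_d)), 1e-12)
  # population variances (denominator n) equal 2pq and (pq)^2
  expect_equal(mean(w$w_a^2), 2 * 0.4 * 0.6, tolerance = 1e-12)
  expect_equal(mean(w$w_d^2), (0.4 * 0.6)^2, tolerance = 1e-12)

  # swapping the counted allele negates w_A and leaves w_D unchanged
  ws <- contrast_scores(2L - g, 0.6)
  expect_equal(ws$w_a, -w$w_a, tolerance = 1e-12)
  expect_equal(ws$w_d, w$w_d, tolerance = 1e-12)

  expect_error(contrast_scores(c(0, 1), 1), "monomorphic")
})

test_that("the decomposition is orthogonal on exact-HWE designs", {
  d <- exact_hwe_pair(0.5, 0.4, 100)
  wa <- contrast_scores(d$g_a, 0.5); wb <- contrast_scores(d$g_b, 0.4)
  X <- cbind(wa$w_a, wa$w_d, wb$w_a, wb$w_d,
             wa$w_a * wb$w_a, wa$w_a * wb$w_d,
             wa$w_d * wb$w_a, wa$w_d * wb$w_d)
  XtX <- crossprod(X) / nrow(X)
  off <- XtX; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-10)
  expect_lt(max(abs(colMeans(X))), 1e-10)

  # components sum to the regression's explained variance
  set.seed(12)
  y <- 0.5 * X[, 1] + 1.2 * X[, 5] + rnorm(nrow(X))
  dec <- decompose_pair(y, d$g_a, d$g_b, p_a = 0.5, p_b = 0.4, min_n = 20)
  fit <- lm(y ~ X)
  explained <- var(fitted(fit))
  expect_lt(abs(sum(dec$components) - explained), 1e-10)
  # orthogonality shortcut equals the sequential-ANOVA route
  ss <- anova(lm(y ~ X[, 1] + X[, 2] + X[, 3] + X[, 4] + X[, 5] + X[, 6] +
                   X[, 7] + X[, 8]))[["Sum Sq"]]
  expect_equal(unname(dec$components),
               ss[1:8] / (nrow(X) - 1), tolerance = 1e-10)
})

test_that("planted epistasis is recovered and null pairs are calibrated", {
  pan <- two_snp_panel(0.5, 0.5)
  scn <- scenario(pan, 50000, K_true = 1,
                  planted_effects = list(
                    planted_effect("snpA", "snpB", component = "AA", beta = 2)),
                  noise_sd = 1, n_covariates = 1, seed = 31)
  sim <- simulate_population(scn)
  dec <- decompose_pair(sim$phenotypes$data$diastolic,
                        sim$genotypes$dosage[, 1], sim$genotypes$dosage[, 2])
  expect_lt(abs(dec$rel_epistatic - 0.5), 0.02)
  others <- dec$components[c("A1", "D1", "A2", "D2", "AD", "DA", "DD")]
  expect_true(all(dec$components["AA"] >= 10 * others))

  # null: p-values uniform, components small
  pv <- vapply(1:200, function(i) {
    set.seed(600 + i)
    ga <- rbinom(300, 2, 0.4); gb <- rbinom(300, 2, 0.3)
    y <- rnorm(300)
    decompose_pair(y, ga, gb)$p_value
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("allele-label swaps change nothing in the decomposition", {
  set.seed(14)
  ga <- rbinom(800, 2, 0.3); gb <- rbinom(800, 2, 0.45)
  y <- rnorm(800) + 0.3 * ga * gb
  d1 <- decompose_pair(y, ga, gb)
  d2 <- decompose_pair(y, 2L - ga, gb)
  d3 <- decompose_pair(y, ga, 2L - gb)
  for (d in list(d2, d3)) {
    expect_equal(unname(d$components), unname(d1$components), tolerance = 1e-10)
    expect_equal(d$p_value, d1$p_value, tolerance = 1e-10)
    expect_equal(d$h2_a, d1$h2_a, tolerance = 1e-10)
  }
})

test_that("single-SNP heritability behaves at its edges and recovers truth", {
  g <- exact_hwe_genotypes(0.5, 200)
  w <- contrast_scores(g, 0.5)
  expect_equal(single_snp_heritability(w$w_a + 0, g, 0.5), 1, tolerance = 1e-12)

  h2 <- vapply(1:100, function(i) {
    set.seed(700 + i)
    single_snp_heritability(rnorm(2000), rbinom(2000, 2, 0.3))
  }, numeric(1))
  expect_gte(mean(h2 < 0.01), 0.95)

  # planted additive effect with expected relative variance 0.2
  set.seed(41)
  n <- 20000; p <- 0.5
  g <- rbinom(n, 2, p)
  w <- contrast_scores(g, p)
  beta <- sqrt(0.25 / (2 * p * (1 - p)))  # V_A = 0.25, noise 1 -> rel 0.2
  y <- beta * w$w_a + rnorm(n)
  expect_lt(abs(single_snp_heritability(y, g) - 0.2), 0.02)
})

test_that("the Bonferroni threshold reproduces the stated cut-offs", {
  expect_equal(signif(bonferroni_threshold(0.05, 990, 14, 2), 1), 2e-6)
  expect_equal(bonferroni_threshold(0.05, 1, 1, 1), 0.05)
  a <- bonferroni_threshold(0.05, 10, 3, 2)
  expect_equal(bonferroni_threshold(0.05, 20, 3, 2), a / 2)
  expect_equal(bonferroni_threshold(0.05, 10, 6, 2), a / 2)
})

test_that("subpopulation scans count pairs, exclude and calibrate correctly", {
  # 45 informative SNPs -> 990 candidate pairs
  pan <- monica_like_panel()
  scn <- scenario(pan, 300, K_true = 1, noise_sd = 1, n_covariates = 1,
                  seed = 51)
  sim <- simulate_population(scn)
  sc <- scan_subpopulation(sim$phenotypes$data$diastolic, sim$genotypes,
                           seq_len(300), alpha_star = 1e-6)
  expect_equal(sc$n_candidate_pairs, 990)
  expect_equal(nrow(sc$pairs), choose(sum(sc$snp_qc$hwe_pass), 2))

  # null calibration at nominal alpha without Bonferroni
  sigfrac <- vapply(1:3, function(i) {
    scn_i <- scenario(pan, 400, K_true = 1, noise_sd = 1, n_covariates = 1,
                      seed = 60 + i)
    sim_i <- simulate_population(scn_i)
    sc_i <- scan_subpopulation(sim_i$phenotypes$data$diastolic,
                               sim_i$genotypes, seq_len(400),
                               alpha_star = 0.05)
    # use all testable pairs (intragenic included) for the calibration
    pp <- sc_i$pairs[sc_i$pairs$testable, ]
    mean(pp$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(sigfrac) - 0.05), 0.01)

  # a SNP monomorphic in the stratum drops out of the denominator
  G <- sim$genotypes
  G$dosage[, 3] <- 0L
  sc2 <- scan_subpopulation(sim$phenotypes$data$diastolic, G, seq_len(300),
                            alpha_star = 1e-6)
  expect_equal(sc2$n_candidate_pairs, choose(44, 2))
  expect_false(any(sc2$pairs$snp_a == colnames(G$dosage)[3] |
                     sc2$pairs$snp_b == colnames(G$dosage)[3]))

  # strata below the minimum size are flagged, not scanned
  sc3 <- scan_subpopulation(sim$phenotypes$data$diastolic, sim$genotypes,
                            1:7, alpha_star = 1e-6)
  expect_equal(sc3$flag, "insufficient-n")
  expect_equal(nrow(sc3$pairs), 0)
})

test_that("dichotomized scans honour thresholds and detect strong signals", {
  pan <- two_snp_panel(0.5, 0.4)
  G <- simulate_genotypes(pan, 2000, seed = 71)
  d <- rnorm(2000, 85, 10); s <- rnorm(2000, 130, 12)
  expect_error(
    dichotomized_scan(d, s, thresholds = c(diastolic = -Inf, systolic = -Inf),
                      G = G),
    "all subjects are cases")

  # binary trait equal to the additive-score indicator is highly heritable
  w <- contrast_scores(G$dosage[, 1], 0.5)
  case_trait <- ifelse(w$w_a > 0, 200, 60)   # diastolic above/below 90
  res <- dichotomized_scan(case_trait, rep(100, 2000), G = G,
                           thresholds = c(diastolic = 90, systolic = 1e9))
  expect_gt(res$heritability$h2[1], 0.5)
  expect_equal(res$n_cases + res$n_controls, 2000)
})
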