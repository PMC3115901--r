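make_pheno <- function(n = 600, sep = 8, gate = 2.0, seed = 1,
                       K = 2, sd_y = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  eta <- cbind(0, if (K == 2) cbind(0 + gate * z1 + 0 * z2) else NULL)
  if (K == 2) {
    pr <- 1 / (1 + exp(-(gate * z1)))
    lab <- 1L + (runif(n) < pr)
  } else {
    lab <- sample.int(K, n, replace = TRUE)
  }
  mu <- seq(0, sep * sd_y * (K - 1), length.out = K)
  y1 <- mu[lab] + rnorm(n, 0, sd_y)
  y2 <- mu[lab] * 1.2 + rnorm(n, 0, sd_y)
  list(
    pheno = phenotype_table(
      data.frame(subject_id = sprintf("s%d", 1:n), y1 = y1, y2 = y2,
                 z1 = z1, z2 = z2),
      indicators = c("y1", "y2"), covariates = c("z1", "z2")),
    labels = lab)
}

test_that("K = 1 reduces to the closed-form Gaussian MLE", {
  d <- make_pheno(n = 300, seed = 3)
  fit <- fit_mixture(d$pheno, 1, mix_config(seed = 1))
  y <- as.matrix(d$pheno$data[, c("y1", "y2")])
  ll <- sum(vapply(1:2, function(m) {
    mu <- mean(y[, m]); s <- sqrt(mean((y[, m] - mu)^2))
    sum(dnorm(y[, m], mu, s, log = TRUE))
  }, numeric(1)))
  expect_equal(fit$loglik, ll, tolerance = 1e-12)
  expect_true(all(fit$posterior == 1))
})

test_that("adjusted BIC follows the sample-size-adjusted penalty", {
  expect_equal(adjusted_bic(0, d = 5, n = 22), 0)
  expect_equal(adjusted_bic(-100, d = 10, n = 998), 200 + 10 * log(1000 / 24))
  # monotone in d at fixed loglik and n
  expect_gt(adjusted_bic(-50, d = 12, n = 500), adjusted_bic(-50, d = 9, n = 500))
})

test_that("entropy hits its endpoints and matches brute force", {
  crisp <- diag(4)[rep(1:4, 25), ]
  expect_equal(mixture_entropy(crisp), 1)
  unif <- matrix(1 / 3, 60, 3)
  expect_equal(mixture_entropy(unif), 0)
  set.seed(42)
  p <- matrix(rexp(50 * 4), 50, 4)
  p <- p / rowSums(p)
  brute <- 1 - sum(apply(p, 1, function(r) -sum(r * log(r)))) / (50 * log(4))
  expect_equal(mixture_entropy(p), brute, tolerance = 1e-12)
  expect_error(mixture_entropy(matrix(1, 10, 1)), "K = 1")
})

test_that("parameters and partition are recovered under strong separation", {
  d <- make_pheno(n = 2000, sep = 8, gate = 2.0, seed = 7)
  fit <- fit_mixture(d$pheno, 2, mix_config(restarts = 5, seed = 2))
  expect_true(all(abs(sort(fit$means[, 1]) - c(0, 8)) < 0.1))
  # gating coefficient on z1 for class 2 vs class 1
  expect_lt(abs(fit$gamma[1, 2] - 2.0), 0.3)
  expect_lt(abs(fit$gamma[1, 3] - 0.0), 0.3)
  modal <- max.col(fit$posterior)
  expect_gt(mclust::adjustedRandIndex(modal, d$labels), 0.95)
  # log-likelihood is monotone over EM iterations
  expect_true(all(diff(fit$trace) > -1e-6 * (abs(fit$loglik) + 1)))
  # posterior rows sum to one
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-9))
})

test_that("duplicating every row doubles the log-likelihood, not the fit", {
  d <- make_pheno(n = 250, seed = 9)
  dd <- d$pheno$data[rep(seq_len(nrow(d$pheno$data)), each = 2), ]
  dd$subject_id <- sprintf("s%d", seq_len(nrow(dd)))
  p2 <- phenotype_table(dd, d$pheno$indicators, d$pheno$covariates)
  f1 <- fit_mixture(d$pheno, 2, mix_config(restarts = 2, seed = 4))
  f2 <- fit_mixture(p2, 2, mix_config(restarts = 2, seed = 4))
  expect_equal(f2$means, f1$means, tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-5)
})

test_that("subject order does not affect the canonical fit", {
  d <- make_pheno(n = 400, seed = 13)
  f1 <- fit_mixture(d$pheno, 2, mix_config(restarts = 2, seed = 5))
  set.seed(77)
  perm <- sample(nrow(d$pheno$data))
  pp <- d$pheno
  pp$data <- pp$data[perm, ]
  f2 <- fit_mixture(pp, 2, mix_config(restarts = 2, seed = 5))
  expect_equal(f1$means, f2$means, tolerance = 1e-6)
  expect_equal(f1$sds, f2$sds, tolerance = 1e-6)
  expect_equal(f1$posterior[perm, ], f2$posterior, tolerance = 1e-6)
})

test_that("model selection picks by aBIC with the entropy tie-break", {
  tab <- data.frame(K = c(2, 3), loglik = c(-10, -11), d = c(5, 8),
                    abic = c(100.0, 100.5), entropy = c(0.6, 0.9),
                    converged = TRUE, error = "")
  expect_equal(mixepinet:::select_from_table(tab, margin = 2), 3)
  tab$entropy <- c(0.9, 0.6)
  expect_equal(mixepinet:::select_from_table(tab, margin = 2), 2)
  # outside the margin the minimum wins regardless of entropy
  tab$abic <- c(100, 110)
  expect_equal(mixepinet:::select_from_table(tab, margin = 2), 2)

  d <- make_pheno(n = 200, seed = 31)
  sel <- select_model(d$pheno, K_range = 1, mix_config(seed = 1))
  expect_equal(sel$K, 1)
  expect_equal(nrow(sel$table), 1)
})

test_that("per-K failures land in the selection table without aborting", {
  d <- make_pheno(n = 30, seed = 3)
  sel <- suppressWarnings(
    select_model(d$pheno, c(1, 29, 2000), mix_config(restarts = 1, seed = 1)))
  expect_equal(nrow(sel$table), 3)
  expect_true(nzchar(sel$table$error[sel$table$K == 2000]))
})

test_that("class diagnostics flag tiny classes and catch correlation", {
  d <- make_pheno(n = 500, sep = 10, seed = 17)
  fit <- fit_mixture(d$pheno, 2, mix_config(restarts = 2, seed = 6))
  diag <- class_diagnostics(fit, d$pheno)
  expect_equal(sum(diag$class_sizes), fit$n)
  expect_true(all(sort(unique(diag$modal)) %in% 1:2))
  # class-conditionally independent indicators: correlations should be small
  expect_true(all(abs(diag$class_table$cor) < 0.3, na.rm = TRUE))
  # normality p-values present for both indicators
  expect_true(all(!is.na(diag$class_table$shapiro_y1)))

  # tiny class: force via a posterior with a 2-member class
  fit2 <- fit_mixture(d$pheno, 2, mix_config(restarts = 2, seed = 6,
                                             min_diag_n = 10))
  fit2$posterior <- cbind(c(rep(1, 2), rep(0, fit2$n - 2)),
                          c(rep(0, 2), rep(1, fit2$n - 2)))
  d2 <- class_diagnostics(fit2, d$pheno)
  expect_equal(d2$class_table$flag[1], "insufficient")
  expect_true(is.na(d2$class_table$cor[1]))
})

test_that("identical indicators in a class give correlation 1", {
  set.seed(5)
  n <- 120
  y <- rnorm(n)
  ph <- phenotype_table(
    data.frame(subject_id = sprintf("s%d", 1:n), y1 = y, y2 = y,
               z1 = rnorm(n)),
    indicators = c("y1", "y2"), covariates = "z1")
  fit <- fit_mixture(ph, 1, mix_config(seed = 1))
  fit$K <- 1L
  dg <- class_diagnostics(fit, ph)
  expect_equal(dg$class_table$cor[1], 1)
  expect_lt(dg$class_table$cor_p[1], 1e-10)
})

test_that("type-I error of the class correlation test is nominal", {
  # single class, independent indicators: the correlation test should
  # reject at about its nominal level over replicates
  rej <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    n <- 80
    ph <- phenotype_table(
      data.frame(subject_id = sprintf("s%d", 1:n), y1 = rnorm(n),
                 y2 = rnorm(n), z1 = rnorm(n)),
      indicators = c("y1", "y2"), covariates = "z1")
    fit <- fit_mixture(ph, 1, mix_config(seed = 1))
    dg <- class_diagnostics(fit, ph)
    dg$class_table$cor_p[1] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("the gating refit agrees with an established multinomial fitter", {
  set.seed(8)
  n <- 500
  Z <- cbind(rnorm(n), rnorm(n))
  eta <- cbind(0, -0.3 + 1.2 * Z[, 1] - 0.7 * Z[, 2])
  pr <- exp(eta) / rowSums(exp(eta))
  lab <- 1L + (runif(n) < pr[, 2])
  resp <- cbind(lab == 1L, lab == 2L) * 1.0
  ours <- mixepinet:::fit_gating(resp, Z)
  ref <- nnet::multinom(factor(lab) ~ Z, trace = FALSE)
  expect_true(all(abs(ours[1, ] - coef(ref)) < 1e-3))
})

test_that("the one-factor variant runs with a monotone likelihood", {
  set.seed(23)
  n <- 400
  z <- rnorm(n)
  lab <- 1L + (runif(n) < plogis(1.5 * z))
  eta <- 0.8 * z + rnorm(n, 0, 0.6)
  mu <- c(0, 6)
  y1 <- mu[lab] + eta + rnorm(n, 0, 0.5)
  y2 <- mu[lab] * 1.1 + 0.7 * eta + rnorm(n, 0, 0.5)
  ph <- phenotype_table(
    data.frame(subject_id = sprintf("s%d", 1:n), y1 = y1, y2 = y2, z1 = z),
    indicators = c("y1", "y2"), covariates = "z1")
  fit <- fit_mixture(ph, 2, mix_config(restarts = 2, seed = 9,
                                       factor_model = TRUE, max_iter = 500))
  expect_true(all(diff(fit$trace) > -1e-6 * (abs(fit$loglik) + 1)))
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-9))
  # the factor should load positively on both indicators
  expect_true(all(fit$factor$lambda[, 1] == 1))
  # factor variant must beat the conditional-independence fit in likelihood
  fit0 <- fit_mixture(ph, 2, mix_config(restarts = 2, seed = 9))
  expect_gt(fit$loglik, fit0$loglik)
})
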