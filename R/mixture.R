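#' EM configuration for the covariate-gated mixture
#'
#' @param restarts number of random restarts (best log-likelihood wins).
#' @param max_iter EM iteration cap per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param var_floor_frac class residual variance floor, as a fraction of the
#'   total indicator variance (guards against degenerate spikes).
#' @param gating fit multinomial-logit gating on the covariates (`TRUE`) or a
#'   covariate-free mixing proportion (`FALSE`).
#' @param factor_model use the per-class one-factor variant (latent factor
#'   between covariates and indicators) instead of the conditional-
#'   independence latent-profile model.
#' @param seed integer seed controlling initialisation.
#' @param abic_margin adjusted-BIC margin within which [select_model()]
#'   treats fits as equivalent and falls back to entropy.
#' @param min_diag_n smallest class size given full diagnostics.
#' @return list of class `mix_config`.
#' @export
mix_config <- function(restarts = 20L, max_iter = 2000L, tol = 1e-8,
                       var_floor_frac = 1e-6, gating = TRUE,
                       factor_model = FALSE, seed = 1L, abic_margin = 2,
                       min_diag_n = 10L) {
  structure(list(restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 var_floor_frac = var_floor_frac, gating = isTRUE(gating),
                 factor_model = isTRUE(factor_model), seed = as.integer(seed),
                 abic_margin = abic_margin, min_diag_n = as.integer(min_diag_n)),
            class = "mix_config")
}

log_sum_exp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# Multinomial-logit fit of class responsibilities on covariates by Newton
# ascent with step halving (concave objective); warm-startable, which keeps
# the per-EM-iteration refit cheap. Gamma is (K-1) x (P+1), class 1 reference.
fit_gating <- function(resp, Z, gamma0 = NULL, max_iter = 25L, tol = 1e-10,
                       ridge = 1e-8) {
  n <- nrow(resp); K <- ncol(resp)
  X <- cbind(1, Z)
  P1 <- ncol(X)
  gamma <- if (is.null(gamma0)) matrix(0, K - 1, P1) else gamma0
  obj <- function(g) {
    eta <- cbind(0, X %*% t(g))
    sum(resp * (eta - log_sum_exp_rows(eta)))
  }
  f <- obj(gamma)
  for (it in seq_len(max_iter)) {
    eta <- cbind(0, X %*% t(gamma))
    pi_mat <- exp(eta - log_sum_exp_rows(eta))
    grad <- t(resp[, -1, drop = FALSE] - pi_mat[, -1, drop = FALSE]) %*% X
    gvec <- as.vector(t(grad))
    H <- matrix(0, (K - 1) * P1, (K - 1) * P1)
    for (a in seq_len(K - 1)) {
      for (b in seq_len(K - 1)) {
        w <- if (a == b) pi_mat[, a + 1] * (1 - pi_mat[, a + 1])
             else -pi_mat[, a + 1] * pi_mat[, b + 1]
        blk <- crossprod(X * w, X)
        ia <- (a - 1) * P1 + seq_len(P1)
        ib <- (b - 1) * P1 + seq_len(P1)
        H[ia, ib] <- blk
      }
    }
    step <- solve(H + ridge * diag(nrow(H)), gvec)
    sz <- 1
    repeat {
      cand <- gamma + sz * matrix(step, K - 1, P1, byrow = TRUE)
      fc <- obj(cand)
      if (is.finite(fc) && fc >= f - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-8) { cand <- gamma; fc <- f; break }
    }
    conv <- abs(fc - f) < tol * (abs(f) + 1)
    gamma <- cand; f <- fc
    if (conv) break
  }
  gamma
}

gating_probs <- function(gamma, Z) {
  if (is.null(gamma)) stop("gating_probs: no gating coefficients")
  eta <- cbind(0, cbind(1, Z) %*% t(gamma))
  p <- exp(eta - log_sum_exp_rows(eta))
  p
}

#' Fit the covariate-gated finite mixture f(y|z) = sum_x pi(x|z) f(y|x, z)
#'
#' EM for a K-class Gaussian mixture over the indicator traits, with class
#' membership probabilities gated by a multinomial-logit on the covariates.
#' The E-step computes Bayes responsibilities; the M-step performs
#' responsibility-weighted Gaussian updates and a responsibility-weighted
#' multinomial-logit refit of the gating. The default within-class density is
#' conditionally independent across indicators (latent-profile model); with
#' `factor_model = TRUE` a per-class single latent factor `eta = gamma' z +
#' zeta` carries the covariates into the indicators (`y = nu_k + lambda_k eta
#' + eps`, first loading fixed to 1, factor intercept 0). The best of
#' `restarts` random starts is returned; classes are canonicalized by
#' ascending first-indicator mean. The log-likelihood trace is retained so
#' monotonicity is checkable per iteration.
#'
#' @param pheno a [phenotype_table()].
#' @param K number of classes (>= 1).
#' @param config a [mix_config()].
#' @return A `mixture_model` list: `K`, `gamma` (gating), `means`, `sds`,
#'   per-class factor parameters when enabled, `loglik`, `trace`, `n_params`,
#'   `n`, `posterior`, `converged`, `n_empty_restarts`.
#' @export
fit_mixture <- function(pheno, K, config = mix_config()) {
  stopifnot(inherits(pheno, "phenotype_table"), K >= 1)
  cc <- stats::complete.cases(pheno$data[, c(pheno$indicators,
                                             pheno$covariates)])
  dat <- pheno$data[cc, , drop = FALSE]
  Y <- as.matrix(dat[, pheno$indicators, drop = FALSE])
  Z <- as.matrix(dat[, pheno$covariates, drop = FALSE])
  n <- nrow(Y); M <- ncol(Y); P <- ncol(Z)
  if (n < K) stop("fit_mixture: fewer subjects than classes")
  d <- n_mixture_params(K, M, P, config)
  if (n < 10 * d) {
    warning(sprintf("fit_mixture: n=%d below 10x parameter count (%d)", n, d))
  }
  var_floor <- config$var_floor_frac * mean(apply(Y, 2, stats::var))
  if (K == 1L) {
    mu <- colMeans(Y)
    sd1 <- sqrt(pmax(apply(Y, 2, function(y) mean((y - mean(y))^2)), var_floor))
    ll <- sum(vapply(seq_len(M), function(m)
      sum(stats::dnorm(Y[, m], mu[m], sd1[m], log = TRUE)), numeric(1)))
    model <- list(K = 1L, gamma = NULL, means = matrix(mu, 1, M),
                  sds = matrix(sd1, 1, M), factor = NULL, loglik = ll,
                  trace = ll, n_params = d, n = n,
                  posterior = matrix(1, n, 1), converged = TRUE,
                  n_empty_restarts = 0L, subject_id = dat$subject_id,
                  indicators = pheno$indicators, covariates = pheno$covariates,
                  config = config)
    class(model) <- "mixture_model"
    return(model)
  }
  set.seed(config$seed)
  best <- NULL
  n_empty <- 0L
  r <- 0L
  attempts <- 0L
  while (r < config$restarts && attempts < 4L * config$restarts) {
    attempts <- attempts + 1L
    run <- tryCatch(
      em_once(Y, Z, K, config, var_floor, jitter = attempts > 1L),
      empty_class = function(e) NULL
    )
    if (is.null(run)) { n_empty <- n_empty + 1L; next }
    r <- r + 1L
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best)) stop("fit_mixture: all restarts collapsed to empty classes")
  model <- c(best, list(n_params = d, n = n, subject_id = dat$subject_id,
                        indicators = pheno$indicators,
                        covariates = pheno$covariates,
                        n_empty_restarts = n_empty, config = config))
  class(model) <- "mixture_model"
  canonicalize_classes(model)
}

n_mixture_params <- function(K, M, P, config) {
  d <- 2L * K * M                       # class means + residual variances
  if (K > 1L) {
    d <- d + (if (config$gating) (K - 1L) * (P + 1L) else K - 1L)
  }
  if (config$factor_model) {
    d <- d + K * ((M - 1L) + P + 1L)    # loadings (first fixed), gamma, psi
  }
  d
}

em_once <- function(Y, Z, K, config, var_floor, jitter = FALSE) {
  n <- nrow(Y); M <- ncol(Y)
  Ys <- scale(Y)
  km <- stats::kmeans(Ys, centers = K, nstart = 5L)
  means <- matrix(NA_real_, K, M)
  sds <- matrix(NA_real_, K, M)
  for (k in seq_len(K)) {
    sel <- km$cluster == k
    means[k, ] <- colMeans(Y[sel, , drop = FALSE])
    s <- apply(Y[sel, , drop = FALSE], 2,
               function(y) stats::sd(y))
    s[is.na(s) | s < sqrt(var_floor)] <- sqrt(max(var_floor, stats::var(Y[, 1]) / K))
    sds[k, ] <- s
  }
  if (jitter) {
    means <- means + matrix(stats::rnorm(K * M, 0, 0.3), K, M) *
      rep(apply(Y, 2, stats::sd), each = K)
  }
  gamma <- NULL
  mix_w <- rep(1 / K, K)
  fac <- if (config$factor_model) init_factor(K, M, ncol(Z)) else NULL
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    # E-step
    if (config$gating && !is.null(gamma)) {
      log_pi <- log(pmax(gating_probs(gamma, Z), 1e-300))
    } else {
      log_pi <- matrix(log(mix_w), n, K, byrow = TRUE)
    }
    log_f <- class_log_density(Y, Z, means, sds, fac)
    log_post <- log_pi + log_f
    ll <- sum(log_sum_exp_rows(log_post))
    resp <- exp(log_post - log_sum_exp_rows(log_post))
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < config$tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    wk <- colSums(resp)
    if (any(wk < 1e-8 * n)) {
      cond <- structure(class = c("empty_class", "error", "condition"),
                        list(message = "empty class", call = NULL))
      stop(cond)
    }
    # M-step
    if (config$factor_model) {
      upd <- m_step_factor(Y, Z, resp, means, sds, fac, var_floor)
      means <- upd$means; sds <- upd$sds; fac <- upd$fac
    } else {
      for (k in seq_len(K)) {
        w <- resp[, k]
        means[k, ] <- colSums(w * Y) / wk[k]
        v <- colSums(w * (Y - matrix(means[k, ], n, M, byrow = TRUE))^2) / wk[k]
        sds[k, ] <- sqrt(pmax(v, var_floor))
      }
    }
    if (config$gating && ncol(Z) >= 0) {
      gamma <- fit_gating(resp, Z, gamma0 = gamma)
    } else {
      mix_w <- wk / n
    }
  }
  list(K = K, gamma = gamma, mix_w = if (config$gating) NULL else mix_w,
       means = means, sds = sds, factor = fac, loglik = ll,
       trace = trace, posterior = resp, converged = converged)
}

init_factor <- function(K, M, P) {
  list(lambda = matrix(c(1, rep(0.5, M - 1)), K, M, byrow = TRUE),
       gamma_f = matrix(0, K, P), psi = rep(1, K))
}

# Per-class log density of y given z. LPA: independent Gaussians. Factor
# variant: MVN with covariance psi * lambda lambda' + diag(sds^2) and mean
# nu_k + lambda_k * (gamma_k' z).
class_log_density <- function(Y, Z, means, sds, fac) {
  n <- nrow(Y); M <- ncol(Y); K <- nrow(means)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (is.null(fac)) {
      lk <- 0
      for (m in seq_len(M)) {
        lk <- lk + stats::dnorm(Y[, m], means[k, m], sds[k, m], log = TRUE)
      }
      out[, k] <- lk
    } else {
      lam <- fac$lambda[k, ]
      Sig <- fac$psi[k] * tcrossprod(lam) + diag(sds[k, ]^2, M)
      mu_f <- as.vector(Z %*% fac$gamma_f[k, ])
      ctr <- Y - matrix(means[k, ], n, M, byrow = TRUE) - outer(mu_f, lam)
      L <- chol(Sig)
      half <- forwardsolve(t(L), t(ctr))
      out[, k] <- -0.5 * (M * log(2 * pi) + 2 * sum(log(diag(L))) +
                            colSums(half^2))
    }
  }
  out
}

# M-step of the one-factor variant: E over the latent factor given class and
# data, then closed-form weighted regression updates per class.
m_step_factor <- function(Y, Z, resp, means, sds, fac, var_floor) {
  n <- nrow(Y); M <- ncol(Y); K <- nrow(means)
  for (k in seq_len(K)) {
    w <- resp[, k]; sw <- sum(w)
    lam <- fac$lambda[k, ]; psi <- fac$psi[k]
    sig2 <- sds[k, ]^2
    m0 <- as.vector(Z %*% fac$gamma_f[k, ])
    tau <- 1 / psi + sum(lam^2 / sig2)
    v <- 1 / tau
    resid <- Y - matrix(means[k, ], n, M, byrow = TRUE)
    h <- (m0 / psi + as.vector(resid %*% (lam / sig2))) * v
    # gamma_f: weighted LS of h on Z
    XtWX <- crossprod(Z * w, Z)
    gf <- solve(XtWX + 1e-8 * diag(ncol(Z)), crossprod(Z * w, h))
    fac$gamma_f[k, ] <- gf
    mz <- as.vector(Z %*% gf)
    fac$psi[k] <- max(sum(w * (v + (h - mz)^2)) / sw, var_floor)
    for (m in seq_len(M)) {
      if (m == 1L) {
        means[k, m] <- sum(w * (Y[, m] - h)) / sw
        lam_m <- 1
      } else {
        A <- rbind(c(sw, sum(w * h)),
                   c(sum(w * h), sum(w * (h^2 + v))))
        b <- c(sum(w * Y[, m]), sum(w * Y[, m] * h))
        sol <- solve(A + 1e-10 * diag(2), b)
        means[k, m] <- sol[1]; lam_m <- sol[2]
        fac$lambda[k, m] <- lam_m
      }
      res_m <- Y[, m] - means[k, m] - lam_m * h
      sds[k, m] <- sqrt(max(sum(w * (res_m^2 + lam_m^2 * v)) / sw, var_floor))
    }
  }
  list(means = means, sds = sds, fac = fac)
}

# Sort classes by ascending first-indicator mean; makes labels deterministic.
canonicalize_classes <- function(model) {
  ord <- order(model$means[, 1])
  if (all(ord == seq_along(ord))) return(model)
  inv <- order(ord)
  model$means <- model$means[ord, , drop = FALSE]
  model$sds <- model$sds[ord, , drop = FALSE]
  model$posterior <- model$posterior[, ord, drop = FALSE]
  if (!is.null(model$factor)) {
    model$factor$lambda <- model$factor$lambda[ord, , drop = FALSE]
    model$factor$gamma_f <- model$factor$gamma_f[ord, , drop = FALSE]
    model$factor$psi <- model$factor$psi[ord]
  }
  if (!is.null(model$gamma)) {
    # refit reference class: express gating relative to new class 1
    # log-odds eta_k in old labels; new eta'_k = eta_old(ord[k]) - eta_old(ord[1])
    full <- rbind(0, model$gamma)       # K x (P+1) in old labels
    full <- full[ord, , drop = FALSE]
    full <- sweep(full, 2, full[1, ])
    model$gamma <- full[-1, , drop = FALSE]
  }
  if (!is.null(model$mix_w)) model$mix_w <- model$mix_w[ord]
  model
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: K=%d, n=%d, loglik=%.2f, d=%d, aBIC=%.2f\n",
              x$K, x$n, x$loglik, x$n_params, adjusted_bic(x)))
  invisible(x)
}

#' Sample-size-adjusted BIC
#'
#' `-2 loglik + d * ln((n + 2) / 24)` with `d` the free-parameter count —
#' the conventional sample-size-adjusted BIC of mixture-model software.
#' Lower is better.
#'
#' @param model a fitted `mixture_model`, or a log-likelihood (with `d`,
#'   `n` supplied).
#' @param d,n parameter count and sample size when `model` is a bare
#'   log-likelihood.
#' @return the adjusted BIC value.
#' @export
adjusted_bic <- function(model, d = NULL, n = NULL) {
  if (inherits(model, "mixture_model")) {
    ll <- model$loglik; d <- model$n_params; n <- model$n
  } else {
    ll <- model
    stopifnot(!is.null(d), !is.null(n))
  }
  -2 * ll + d * log((n + 2) / 24)
}

#' Entropy of a mixture partition
#'
#' `1 - sum_i sum_k (-p_ik log p_ik) / (n log K)`: 1 for perfectly crisp
#' posteriors, 0 for uniform (uninformative) posteriors.
#'
#' @param posterior n x K posterior matrix (rows sum to 1), or an object
#'   with a `posterior` element.
#' @return entropy in `[0, 1]`; errors for K = 1 (undefined).
#' @export
mixture_entropy <- function(posterior) {
  if (!is.matrix(posterior)) posterior <- posterior$posterior
  K <- ncol(posterior); n <- nrow(posterior)
  if (K < 2) stop("mixture_entropy: undefined for K = 1")
  h <- -posterior * log(posterior)
  h[!is.finite(h)] <- 0        # 0 * log 0 = 0
  1 - sum(h) / (n * log(K))
}

#' Fit a range of class counts and select by adjusted BIC, entropy tie-break
#'
#' Fits every K in `K_range`, tabulates log-likelihood, parameter count,
#' adjusted BIC and entropy, and picks the minimum-aBIC model; when other
#' fits lie within `config$abic_margin` of the minimum, the highest-entropy
#' candidate among them wins. Per-K fit failures are recorded in the table,
#' never abort the sweep.
#'
#' @param pheno a [phenotype_table()].
#' @param K_range integer vector of candidate class counts.
#' @param config a [mix_config()].
#' @return list: `model` (the selected `mixture_model`), `K` (its class
#'   count), `table` (the selection table).
#' @export
select_model <- function(pheno, K_range, config = mix_config()) {
  stopifnot(length(K_range) >= 1)
  fits <- list()
  tab <- data.frame(K = integer(), loglik = numeric(), d = integer(),
                    abic = numeric(), entropy = numeric(),
                    converged = logical(), error = character(),
                    stringsAsFactors = FALSE)
  for (K in K_range) {
    res <- tryCatch(fit_mixture(pheno, K, config), error = identity)
    if (inherits(res, "error")) {
      tab <- rbind(tab, data.frame(K = K, loglik = NA, d = NA, abic = NA,
                                   entropy = NA, converged = FALSE,
                                   error = conditionMessage(res)))
      next
    }
    ent <- if (K >= 2) mixture_entropy(res$posterior) else NA_real_
    tab <- rbind(tab, data.frame(K = K, loglik = res$loglik,
                                 d = res$n_params, abic = adjusted_bic(res),
                                 entropy = ent, converged = res$converged,
                                 error = ""))
    fits[[as.character(K)]] <- res
  }
  pick <- select_from_table(tab, config$abic_margin)
  if (is.na(pick)) stop("select_model: no K could be fitted")
  list(model = fits[[as.character(pick)]], K = pick, table = tab)
}

# Selection rule: minimum aBIC; candidates within `margin` of the minimum
# are equivalent and the highest entropy wins (K = 1, entropy undefined,
# only wins when it is the unique candidate).
select_from_table <- function(tab, margin) {
  ok <- !is.na(tab$abic)
  if (!any(ok)) return(NA_integer_)
  mn <- min(tab$abic[ok])
  cand <- which(ok & tab$abic <= mn + margin)
  if (length(cand) == 1L) return(tab$K[cand])
  ent <- tab$entropy[cand]
  if (all(is.na(ent))) return(tab$K[cand[which.min(tab$abic[cand])]])
  tab$K[cand[which.max(ifelse(is.na(ent), -Inf, ent))]]
}

#' Partition diagnostics for a fitted mixture
#'
#' Modal class assignment, class sizes, adjusted BIC and entropy, plus the
#' classification checks: within each class, the Pearson correlation between
#' the first two indicators (which should vanish in a perfect partition of a
#' conditionally independent mixture) and per-indicator normality tests
#' (Shapiro-Wilk, Lilliefors, Anderson-Darling). Classes below
#' `config$min_diag_n` are flagged `insufficient` and their tests skipped.
#'
#' @param model a fitted `mixture_model`.
#' @param pheno the [phenotype_table()] it was fitted on.
#' @return A `partition_result` list: `posterior`, `modal`, `class_sizes`,
#'   `abic`, `entropy`, `class_table` (per-class diagnostics).
#' @export
class_diagnostics <- function(model, pheno) {
  stopifnot(inherits(model, "mixture_model"))
  cc <- stats::complete.cases(pheno$data[, c(pheno$indicators,
                                             pheno$covariates)])
  dat <- pheno$data[cc, , drop = FALSE]
  Y <- as.matrix(dat[, pheno$indicators, drop = FALSE])
  stopifnot(nrow(Y) == nrow(model$posterior))
  modal <- max.col(model$posterior, ties.method = "first")
  sizes <- tabulate(modal, nbins = model$K)
  min_n <- model$config$min_diag_n
  rows <- vector("list", model$K)
  for (k in seq_len(model$K)) {
    sel <- modal == k
    nk <- sum(sel)
    row <- data.frame(class = k, n = nk, flag = "",
                      cor = NA_real_, cor_p = NA_real_,
                      stringsAsFactors = FALSE)
    for (ind in model$indicators) {
      row[[paste0("shapiro_", ind)]] <- NA_real_
      row[[paste0("lilliefors_", ind)]] <- NA_real_
      row[[paste0("ad_", ind)]] <- NA_real_
    }
    if (nk < min_n) {
      row$flag <- "insufficient"
    } else {
      if (ncol(Y) >= 2) {
        if (stats::sd(Y[sel, 1]) > 0 && stats::sd(Y[sel, 2]) > 0) {
          ct <- stats::cor.test(Y[sel, 1], Y[sel, 2])
          row$cor <- unname(ct$estimate); row$cor_p <- ct$p.value
        } else {
          row$cor <- if (all(Y[sel, 1] == Y[sel, 2])) 1 else NA_real_
          row$cor_p <- 0
        }
      }
      for (m in seq_along(model$indicators)) {
        y <- Y[sel, m]
        ind <- model$indicators[m]
        if (stats::sd(y) == 0) next
        if (nk >= 3 && nk <= 5000) {
          row[[paste0("shapiro_", ind)]] <- stats::shapiro.test(y)$p.value
        }
        if (nk >= 5) {
          row[[paste0("lilliefors_", ind)]] <- nortest::lillie.test(y)$p.value
        }
        if (nk >= 8) {
          row[[paste0("ad_", ind)]] <- nortest::ad.test(y)$p.value
        }
      }
    }
    rows[[k]] <- row
  }
  structure(
    list(posterior = model$posterior, modal = modal, class_sizes = sizes,
         subject_id = model$subject_id,
         abic = adjusted_bic(model),
         entropy = if (model$K >= 2) mixture_entropy(model$posterior)
                   else NA_real_,
         class_table = do.call(rbind, rows)),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition_result: K=%d, sizes [%s], entropy=%.3f\n",
              length(x$class_sizes), paste(x$class_sizes, collapse = ", "),
              x$entropy))
  invisible(x)
}
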