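#' Per-SNP allele statistics
#'
#' Counted-allele frequency, genotype counts, and monomorphism flags.
#' Missing dosages are excluded from the counts; an all-missing SNP is
#' flagged (`all_missing`) rather than dropped silently. A SNP is
#' monomorphic when only one genotype class is present among the non-missing
#' calls; `informative` SNPs are the polymorphic, not-all-missing ones.
#'
#' @param G a `genotype_matrix` (or bare dosage matrix).
#' @return data.frame with one row per SNP: `snp_id`, `n0`, `n1`, `n2`,
#'   `n_missing`, `p`, `monomorphic`, `all_missing`, `informative`.
#' @export
allele_stats <- function(G) {
  dos <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  ids <- colnames(dos)
  if (is.null(ids)) ids <- sprintf("snp%d", seq_len(ncol(dos)))
  out <- data.frame(
    snp_id = ids,
    n0 = colSums(dos == 0L, na.rm = TRUE),
    n1 = colSums(dos == 1L, na.rm = TRUE),
    n2 = colSums(dos == 2L, na.rm = TRUE),
    n_missing = colSums(is.na(dos)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  n_called <- out$n0 + out$n1 + out$n2
  out$p <- ifelse(n_called > 0, (out$n1 + 2 * out$n2) / (2 * n_called), NA_real_)
  out$all_missing <- n_called == 0L
  out$monomorphic <- !out$all_missing &
    ((out$n0 == n_called) | (out$n1 == n_called) | (out$n2 == n_called))
  out$informative <- !out$all_missing & !out$monomorphic
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: conditioning on the observed allele counts, the
#' p-value is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table.
#'
#' @param counts genotype counts `c(n0, n1, n2)` = (hom other, het, hom
#'   counted); non-negative.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n0 <- counts[1]; n1 <- counts[2]; n2 <- counts[3]
  n <- n0 + n1 + n2
  if (n == 0) stop("hwe_exact_test: zero subjects")
  nA <- n1 + 2 * n2           # counted-allele count
  na_ <- n1 + 2 * n0
  if (nA == 0 || na_ == 0) return(1)  # monomorphic: single attainable table
  het <- seq.int(nA %% 2, min(nA, na_), by = 2)
  # log P(n_het | n, nA) up to the shared normaliser
  lp <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) -
    lgamma(het + 1) - lgamma((na_ - het) / 2 + 1) + het * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  obs <- pr[match(n1, het)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Orthogonal (Cockerham) contrast scores for one SNP
#'
#' Additive contrast `w_A`: dosage 2 -> `2q`, 1 -> `q - p`, 0 -> `-2p`;
#' dominance contrast `w_D`: 2 -> `-q^2`, 1 -> `pq`, 0 -> `-p^2`, with `p`
#' the counted-allele frequency and `q = 1 - p`. Under exact HWE both have
#' zero mean, zero covariance, and variances `2pq` and `(pq)^2` — the basis
#' of the orthogonal variance decomposition.
#'
#' @param g dosage vector in `{0, 1, 2, NA}`.
#' @param p counted-allele frequency strictly inside (0, 1).
#' @return list with numeric vectors `w_a` and `w_d` (NA where `g` is NA).
#' @export
contrast_scores <- function(g, p) {
  if (p <= 0 || p >= 1) stop("contrast_scores: monomorphic SNP (p is 0 or 1)")
  q <- 1 - p
  w_a <- g - 2 * p
  w_d <- rep(NA_real_, length(g))
  w_d[!is.na(g) & g == 0L] <- -p^2
  w_d[!is.na(g) & g == 1L] <- p * q
  w_d[!is.na(g) & g == 2L] <- -q^2
  list(w_a = as.numeric(w_a), w_d = w_d)
}

#' Two-locus linkage disequilibrium by EM over unphased genotypes
#'
#' Estimates the four haplotype frequencies by EM (double heterozygotes are
#' split between the coupling and repulsion phases in proportion to their
#' current likelihood), then reports `D = f_AB - pA pB`, the normalised `D'`,
#' `r^2`, and a 1-df likelihood-ratio p-value against independence.
#'
#' @param g_a,g_b dosage vectors (counted-allele, `{0,1,2,NA}`).
#' @param tol,max_iter EM convergence controls.
#' @return list: `haplotypes` (named AB/Ab/aB/ab), `D`, `Dprime`, `r2`, `p`,
#'   `loglik`, `n`.
#' @export
ld_pair <- function(g_a, g_b, tol = 1e-12, max_iter = 1000L) {
  keep <- !is.na(g_a) & !is.na(g_b)
  g_a <- g_a[keep]; g_b <- g_b[keep]
  n <- length(g_a)
  if (n == 0) stop("ld_pair: no shared complete cases")
  if (length(unique(g_a)) < 2 || length(unique(g_b)) < 2) {
    stop("ld_pair: LD undefined for a monomorphic SNP")
  }
  tab <- table(factor(g_a, 0:2), factor(g_b, 0:2))  # rows A dosage, cols B
  pa <- mean(g_a) / 2; pb <- mean(g_b) / 2
  f <- c(AB = pa * pb, Ab = pa * (1 - pb), aB = (1 - pa) * pb,
         ab = (1 - pa) * (1 - pb))
  n_dh <- tab["1", "1"]
  ll <- ld_loglik(tab, f)
  for (it in seq_len(max_iter)) {
    # E: split double heterozygotes between phases AB/ab vs Ab/aB
    cup <- f["AB"] * f["ab"]; rep_ <- f["Ab"] * f["aB"]
    w <- if (cup + rep_ > 0) cup / (cup + rep_) else 0.5
    cAB <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"] + n_dh * w
    cAb <- 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"] + n_dh * (1 - w)
    caB <- 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"] + n_dh * (1 - w)
    cab <- 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"] + n_dh * w
    f_new <- stats::setNames(c(cAB, cAb, caB, cab) / (2 * n),
                             c("AB", "Ab", "aB", "ab"))
    ll_new <- ld_loglik(tab, f_new)
    conv <- abs(ll_new - ll) < tol * (abs(ll) + 1)
    f <- f_new; ll <- ll_new
    if (conv) break
  }
  pa_h <- f["AB"] + f["Ab"]; pb_h <- f["AB"] + f["aB"]
  D <- unname(f["AB"] - pa_h * pb_h)
  d_max <- if (D >= 0) min(pa_h * (1 - pb_h), (1 - pa_h) * pb_h)
           else min(pa_h * pb_h, (1 - pa_h) * (1 - pb_h))
  dprime <- if (d_max > 0) abs(D) / d_max else 0
  denom <- pa_h * (1 - pa_h) * pb_h * (1 - pb_h)
  r2 <- if (denom > 0) D^2 / denom else 0
  f0 <- c(AB = pa * pb, Ab = pa * (1 - pb), aB = (1 - pa) * pb,
          ab = (1 - pa) * (1 - pb))
  lrt <- 2 * (ll - ld_loglik(tab, f0))
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  list(haplotypes = f, D = D, Dprime = unname(dprime), r2 = unname(r2),
       p = unname(p), loglik = unname(ll), n = n)
}

# Multinomial log-likelihood of a 3x3 genotype-pair table under haplotype
# frequencies f (haplotypes pair independently).
ld_loglik <- function(tab, f) {
  pr <- matrix(0, 3, 3)  # [A dosage + 1, B dosage + 1]
  pr[3, 3] <- f["AB"]^2
  pr[3, 2] <- 2 * f["AB"] * f["Ab"]
  pr[3, 1] <- f["Ab"]^2
  pr[2, 3] <- 2 * f["AB"] * f["aB"]
  pr[2, 2] <- 2 * f["AB"] * f["ab"] + 2 * f["Ab"] * f["aB"]
  pr[2, 1] <- 2 * f["Ab"] * f["ab"]
  pr[1, 3] <- f["aB"]^2
  pr[1, 2] <- 2 * f["aB"] * f["ab"]
  pr[1, 1] <- f["ab"]^2
  cnt <- tab  # rows A dosage 0..2, cols B dosage 0..2, matching pr
  use <- cnt > 0
  sum(cnt[use] * log(pmax(pr[use], 1e-300)))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha nominal family-wise level.
#' @param n_pairs number of SNP pairs tested.
#' @param n_subpops number of subpopulations scanned.
#' @param n_traits number of traits scanned.
#' @return `alpha / (n_pairs * n_subpops * n_traits)`.
#' @export
bonferroni_threshold <- function(alpha, n_pairs = 1L, n_subpops = 1L,
                                 n_traits = 1L) {
  stopifnot(alpha > 0, n_pairs >= 1, n_subpops >= 1, n_traits >= 1)
  alpha / (n_pairs * n_subpops * n_traits)
}

#' Two-locus orthogonal variance decomposition for one SNP pair
#'
#' Regresses the trait on the eight orthogonal predictors `w_A1, w_D1, w_A2,
#' w_D2` and their four products (`AA`, `AD`, `DA`, `DD`), on the pairwise
#' complete cases. Each variance component is the sample variance of the
#' fitted term `beta_j * x_j`; the total phenotypic variance `V_P` is the
#' sample trait variance in the stratum, and the relative epistatic variance
#' is `(V_AA + V_AD + V_DA + V_DD) / V_P`. Joint epistasis significance is
#' the F-test of the four interaction terms against the marginal model.
#' Predictors that are constant (or aliased) after complete-case filtering
#' are dropped with a named flag and their components set to 0.
#'
#' @param trait numeric trait vector.
#' @param g_a,g_b dosage vectors.
#' @param p_a,p_b counted-allele frequencies; estimated from the analyzed
#'   complete cases when `NULL` (the default, matching per-stratum usage).
#' @param min_n minimum complete-case count for a testable pair.
#' @param snp_a,snp_b labels carried into the result.
#' @return A `pair_decomposition` list; `testable = FALSE` results carry a
#'   `reason`.
#' @export
decompose_pair <- function(trait, g_a, g_b, p_a = NULL, p_b = NULL,
                           min_n = 20L, snp_a = "snp_a", snp_b = "snp_b") {
  keep <- !is.na(trait) & !is.na(g_a) & !is.na(g_b)
  trait <- trait[keep]; g_a <- g_a[keep]; g_b <- g_b[keep]
  n <- length(trait)
  base <- list(snp_a = snp_a, snp_b = snp_b, n_used = n, testable = FALSE,
               dropped = character())
  if (n < min_n) {
    base$reason <- sprintf("n=%d below minimum %d", n, min_n)
    return(structure(base, class = "pair_decomposition"))
  }
  if (is.null(p_a)) p_a <- mean(g_a) / 2
  if (is.null(p_b)) p_b <- mean(g_b) / 2
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    base$reason <- "monomorphic in stratum"
    return(structure(base, class = "pair_decomposition"))
  }
  wa <- contrast_scores(g_a, p_a); wb <- contrast_scores(g_b, p_b)
  X <- cbind(A1 = wa$w_a, D1 = wa$w_d, A2 = wb$w_a, D2 = wb$w_d,
             AA = wa$w_a * wb$w_a, AD = wa$w_a * wb$w_d,
             DA = wa$w_d * wb$w_a, DD = wa$w_d * wb$w_d)
  const <- apply(X, 2, function(x) stats::var(x) < 1e-14)
  dropped <- colnames(X)[const]
  Xu <- X[, !const, drop = FALSE]
  inter_names <- c("AA", "AD", "DA", "DD")
  if (!any(colnames(Xu) %in% inter_names)) {
    base$reason <- "no interaction predictor survives"
    base$dropped <- dropped
    return(structure(base, class = "pair_decomposition"))
  }
  fit8 <- stats::lm(trait ~ Xu)
  cf <- stats::coef(fit8)[-1]
  names(cf) <- colnames(Xu)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    dropped <- c(dropped, aliased)
    Xu <- Xu[, setdiff(colnames(Xu), aliased), drop = FALSE]
    if (!any(colnames(Xu) %in% inter_names)) {
      base$reason <- "interaction predictors aliased"
      base$dropped <- dropped
      return(structure(base, class = "pair_decomposition"))
    }
    fit8 <- stats::lm(trait ~ Xu)
    cf <- stats::coef(fit8)[-1]
    names(cf) <- colnames(Xu)
  }
  marg <- Xu[, intersect(colnames(Xu), c("A1", "D1", "A2", "D2")),
             drop = FALSE]
  fit4 <- if (ncol(marg) > 0) stats::lm(trait ~ marg) else stats::lm(trait ~ 1)
  av <- stats::anova(fit4, fit8)
  p_joint <- av[["Pr(>F)"]][2]
  if (is.na(p_joint)) p_joint <- 1  # interaction block adds no fit
  comp <- stats::setNames(numeric(8), colnames(X))
  for (j in names(cf)) comp[j] <- cf[j]^2 * stats::var(Xu[, j])
  v_p <- stats::var(trait)
  coefs <- stats::setNames(rep(NA_real_, 8), colnames(X))
  coefs[names(cf)] <- cf
  epi <- sum(comp[inter_names])
  out <- list(
    snp_a = snp_a, snp_b = snp_b, n_used = n, testable = TRUE,
    p_a = p_a, p_b = p_b, coefficients = coefs,
    components = comp, V_P = v_p,
    rel_epistatic = if (v_p > 0) epi / v_p else NA_real_,
    h2_a = if (v_p > 0) (comp["A1"] + comp["D1"]) / v_p else NA_real_,
    h2_b = if (v_p > 0) (comp["A2"] + comp["D2"]) / v_p else NA_real_,
    p_value = p_joint,
    t_tests = suppressWarnings(summary(fit8)$coefficients),
    dropped = dropped, reason = NA_character_
  )
  structure(out, class = "pair_decomposition")
}

#' Single-SNP heritability from the two-contrast regression
#'
#' `h^2 = (V_A + V_D) / V_P`, where `V_A` and `V_D` are the sample variances
#' of the fitted additive and dominance terms of the regression of the trait
#' on `w_A` and `w_D`, and `V_P` is the sample trait variance. A local,
#' single-locus quantity, not a genome-wide heritability.
#'
#' @inheritParams decompose_pair
#' @param g dosage vector.
#' @param p counted-allele frequency; estimated from complete cases if NULL.
#' @return h-squared in `[0, 1]` (NA if not testable).
#' @export
single_snp_heritability <- function(trait, g, p = NULL, min_n = 20L) {
  keep <- !is.na(trait) & !is.na(g)
  trait <- trait[keep]; g <- g[keep]
  if (length(g) < min_n) return(NA_real_)
  if (is.null(p)) p <- mean(g) / 2
  if (p <= 0 || p >= 1) return(NA_real_)
  w <- contrast_scores(g, p)
  X <- cbind(A = w$w_a, D = w$w_d)
  const <- apply(X, 2, function(x) stats::var(x) < 1e-14)
  X <- X[, !const, drop = FALSE]
  if (ncol(X) == 0) return(NA_real_)
  fit <- stats::lm(trait ~ X)
  cf <- stats::coef(fit)[-1]
  names(cf) <- colnames(X)
  v <- 0
  for (j in names(cf)) if (!is.na(cf[j])) v <- v + cf[j]^2 * stats::var(X[, j])
  v_p <- stats::var(trait)
  if (v_p > 0) unname(v / v_p) else NA_real_
}

#' Scan all SNP pairs of a subpopulation for epistasis
#'
#' Re-evaluates allele frequencies, monomorphism and the HWE exact test
#' within the stratum (SNPs failing HWE there are excluded from the
#' decomposition), then runs [decompose_pair()] on every pair of surviving
#' SNPs with stratum-estimated frequencies. Intragenic pairs are computed
#' but tagged, and excluded from the significance summaries. The fraction of
#' significant pairs uses the testable pairs as denominator.
#'
#' @param trait numeric trait vector aligned with `G` subjects.
#' @param G a `genotype_matrix`.
#' @param members logical/integer index of stratum members.
#' @param alpha_star per-test significance threshold (e.g. from
#'   [bonferroni_threshold()]).
#' @param trait_name,subpop labels carried into the result.
#' @param hwe_alpha per-SNP HWE exclusion threshold; default `0.05 / m` with
#'   `m` the informative SNP count in the stratum.
#' @param min_n minimum pairwise complete-case count.
#' @param min_stratum strata smaller than this are reported but not scanned.
#' @return A `scan_result`: list with the pair table (`pairs`), stratum QC
#'   (`snp_qc`), counts, and per-SNP significant-interaction degrees.
#' @export
scan_subpopulation <- function(trait, G, members, alpha_star,
                               trait_name = "trait", subpop = 1L,
                               hwe_alpha = NULL, min_n = 20L,
                               min_stratum = 20L) {
  stopifnot(inherits(G, "genotype_matrix"))
  idx <- if (is.logical(members)) which(members) else as.integer(members)
  dos <- G$dosage[idx, , drop = FALSE]
  y <- trait[idx]
  panel <- G$panel
  empty <- function(reason) {
    structure(list(subpop = subpop, trait = trait_name, n_subjects = length(idx),
                   pairs = empty_pair_table(), snp_qc = NULL,
                   n_candidate_pairs = 0L, n_testable_pairs = 0L,
                   n_significant = 0L, fraction_significant = NA_real_,
                   snp_degrees = integer(), alpha_star = alpha_star,
                   flag = reason),
              class = "scan_result")
  }
  if (length(idx) < min_stratum) return(empty("insufficient-n"))
  qc <- allele_stats(dos)
  qc$hwe_p <- NA_real_
  inf <- which(qc$informative)
  m <- length(inf)
  if (m < 2) return(empty("fewer than 2 informative SNPs"))
  if (is.null(hwe_alpha)) hwe_alpha <- 0.05 / m
  for (j in inf) {
    qc$hwe_p[j] <- hwe_exact_test(c(qc$n0[j], qc$n1[j], qc$n2[j]))
  }
  qc$hwe_pass <- qc$informative & !is.na(qc$hwe_p) & qc$hwe_p >= hwe_alpha
  testable_snps <- which(qc$hwe_pass)
  n_candidate <- m * (m - 1) / 2
  if (length(testable_snps) < 2) {
    res <- empty("fewer than 2 HWE-passing SNPs")
    res$snp_qc <- qc
    res$n_candidate_pairs <- as.integer(n_candidate)
    return(res)
  }
  prs <- utils::combn(testable_snps, 2)
  rows <- vector("list", ncol(prs))
  for (k in seq_len(ncol(prs))) {
    a <- prs[1, k]; b <- prs[2, k]
    dec <- decompose_pair(y, dos[, a], dos[, b], p_a = qc$p[a], p_b = qc$p[b],
                          min_n = min_n, snp_a = qc$snp_id[a],
                          snp_b = qc$snp_id[b])
    rows[[k]] <- pair_row(dec, panel)
  }
  pairs <- do.call(rbind, rows)
  pairs$subpop <- subpop
  pairs$trait <- trait_name
  pairs$significant <- pairs$testable & !pairs$intragenic &
    !is.na(pairs$p_value) & pairs$p_value <= alpha_star
  n_testable <- sum(pairs$testable)
  n_sig <- sum(pairs$significant)
  deg <- stats::setNames(integer(nrow(qc)), qc$snp_id)
  if (n_sig > 0) {
    t_sig <- table(c(pairs$snp_a[pairs$significant],
                     pairs$snp_b[pairs$significant]))
    deg[names(t_sig)] <- as.integer(t_sig)
  }
  structure(
    list(subpop = subpop, trait = trait_name, n_subjects = length(idx),
         pairs = pairs, snp_qc = qc,
         n_candidate_pairs = as.integer(n_candidate),
         n_testable_pairs = as.integer(n_testable),
         n_significant = as.integer(n_sig),
         fraction_significant = if (n_testable > 0) n_sig / n_testable
                                else NA_real_,
         snp_degrees = deg, alpha_star = alpha_star, flag = NA_character_),
    class = "scan_result"
  )
}

empty_pair_table <- function() {
  comp_cols <- c("V_A1", "V_D1", "V_A2", "V_D2", "V_AA", "V_AD", "V_DA", "V_DD")
  df <- data.frame(snp_a = character(), snp_b = character(),
                   gene_a = character(), gene_b = character(),
                   intragenic = logical(), n_used = integer(),
                   testable = logical(), stringsAsFactors = FALSE)
  for (cc in comp_cols) df[[cc]] <- numeric()
  df$V_P <- numeric(); df$rel_epistatic <- numeric()
  df$h2_a <- numeric(); df$h2_b <- numeric(); df$p_value <- numeric()
  df$dropped <- character(); df$reason <- character()
  df
}

pair_row <- function(dec, panel) {
  ga <- panel$gene[match(dec$snp_a, panel$snp_id)]
  gb <- panel$gene[match(dec$snp_b, panel$snp_id)]
  comp <- if (dec$testable) dec$components else stats::setNames(
    rep(NA_real_, 8), c("A1", "D1", "A2", "D2", "AA", "AD", "DA", "DD"))
  data.frame(
    snp_a = dec$snp_a, snp_b = dec$snp_b,
    gene_a = if (is.na(ga)) "" else ga, gene_b = if (is.na(gb)) "" else gb,
    intragenic = !is.na(ga) && !is.na(gb) && ga == gb,
    n_used = dec$n_used, testable = dec$testable,
    V_A1 = comp[["A1"]], V_D1 = comp[["D1"]],
    V_A2 = comp[["A2"]], V_D2 = comp[["D2"]],
    V_AA = comp[["AA"]], V_AD = comp[["AD"]],
    V_DA = comp[["DA"]], V_DD = comp[["DD"]],
    V_P = if (dec$testable) dec$V_P else NA_real_,
    rel_epistatic = if (dec$testable) dec$rel_epistatic else NA_real_,
    h2_a = if (dec$testable) dec$h2_a else NA_real_,
    h2_b = if (dec$testable) dec$h2_b else NA_real_,
    p_value = if (dec$testable) dec$p_value else NA_real_,
    dropped = paste(dec$dropped, collapse = ","),
    reason = if (dec$testable) "" else dec$reason,
    stringsAsFactors = FALSE
  )
}

#' Case-control (dichotomized) epistasis scan
#'
#' Builds a binary hypertension-style trait (1 when the first trait exceeds
#' its threshold or the second exceeds its threshold) and applies the same
#' orthogonal decomposition to the 0/1 trait across the whole sample, plus a
#' per-SNP heritability table.
#'
#' @param diastolic,systolic numeric trait vectors.
#' @param thresholds named numeric `c(diastolic=, systolic=)`, the
#'   case-defining cutoffs (defaults 90 and 140 mmHg).
#' @param G a `genotype_matrix`.
#' @param alpha_star per-test threshold.
#' @param ... passed to [scan_subpopulation()].
#' @return list: `scan` (a `scan_result` on the binary trait), `heritability`
#'   (per-SNP h^2 table), `n_cases`, `n_controls`.
#' @export
dichotomized_scan <- function(diastolic, systolic,
                              thresholds = c(diastolic = 90, systolic = 140),
                              G, alpha_star = 0.05, ...) {
  stopifnot(inherits(G, "genotype_matrix"))
  case <- as.numeric(diastolic > thresholds[["diastolic"]] |
                     systolic > thresholds[["systolic"]])
  ok <- !is.na(case)
  if (all(case[ok] == 1)) stop("dichotomized_scan: all subjects are cases")
  if (all(case[ok] == 0)) stop("dichotomized_scan: all subjects are controls")
  scn <- scan_subpopulation(case, G, seq_along(case), alpha_star,
                            trait_name = "hypertension", subpop = "all", ...)
  qc <- allele_stats(G)
  h2 <- vapply(seq_len(ncol(G$dosage)), function(j) {
    if (!qc$informative[j]) return(NA_real_)
    single_snp_heritability(case, G$dosage[, j])
  }, numeric(1))
  list(scan = scn,
       heritability = data.frame(snp_id = qc$snp_id, gene = G$panel$gene,
                                 h2 = h2, stringsAsFactors = FALSE),
       n_cases = sum(case[ok] == 1), n_controls = sum(case[ok] == 0))
}
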