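#' Simulate genotypes for a SNP panel
#'
#' SNPs outside LD blocks are drawn independently with Hardy-Weinberg
#' genotype probabilities `(q^2, 2pq, p^2)` for the counted allele at
#' frequency `p`. SNPs inside a block are generated haplotype-wise along the
#' block: each SNP's haplotype allele is drawn conditionally on the previous
#' block SNP from the 2x2 haplotype table solved from `(p_prev, p, r2)`, so
#' consecutive block SNPs reach the target r-squared while haplotypes pair
#' independently (HWE holds marginally at every SNP). Infeasible `(p, r2)`
#' combinations are rejected with an error naming the pair rather than
#' silently clipped.
#'
#' @param spec a [panel_spec()].
#' @param n number of subjects (>= 1).
#' @param seed integer seed; fixing it fixes every output bit.
#' @param missing_rate per-call probability a genotype is set missing.
#' @return A `genotype_matrix`: list with `subject_id`, `panel`, and an
#'   integer `dosage` matrix (subjects x SNPs, values 0/1/2 or `NA`).
#' @export
simulate_genotypes <- function(spec, n, seed = 1L, missing_rate = 0) {
  stopifnot(inherits(spec, "panel_spec"), n >= 1)
  set.seed(as.integer(seed))
  m <- nrow(spec)
  dos <- matrix(NA_integer_, nrow = n, ncol = m,
                dimnames = list(NULL, spec$snp_id))
  blocks <- split(seq_len(m), spec$ld_block)  # NA block labels dropped by split
  in_block <- unlist(blocks, use.names = FALSE)
  solo <- setdiff(seq_len(m), in_block)
  for (j in solo) {
    dos[, j] <- stats::rbinom(n, 2L, spec$p[j])
  }
  for (idx in blocks) {
    idx <- idx[order(idx)]
    # two haplotypes per subject, built SNP by SNP along the block
    h1 <- stats::rbinom(n, 1L, spec$p[idx[1]])
    h2 <- stats::rbinom(n, 1L, spec$p[idx[1]])
    dos[, idx[1]] <- h1 + h2
    for (k in seq_along(idx)[-1]) {
      ja <- idx[k - 1]; jb <- idx[k]
      tab <- haplotype_table(spec$p[ja], spec$p[jb], spec$ld_r2[jb],
                             spec$snp_id[ja], spec$snp_id[jb])
      # P(allele B = 1 | allele A)
      p_b_given_1 <- tab["AB"] / spec$p[ja]
      p_b_given_0 <- tab["aB"] / (1 - spec$p[ja])
      nh1 <- stats::rbinom(n, 1L, ifelse(h1 == 1L, p_b_given_1, p_b_given_0))
      nh2 <- stats::rbinom(n, 1L, ifelse(h2 == 1L, p_b_given_1, p_b_given_0))
      dos[, jb] <- nh1 + nh2
      h1 <- nh1; h2 <- nh2
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n * m) < missing_rate, n, m)
    dos[drop] <- NA_integer_
  }
  genotype_matrix(sprintf("S%04d", seq_len(n)), spec, dos)
}

# Solve the 2x2 haplotype frequency table from marginal frequencies and a
# target r^2 (positive-D root). Errors when the implied f_AB leaves [max(0,
# pA+pB-1), min(pA, pB)], i.e. the target is unattainable for these alleles.
haplotype_table <- function(pa, pb, r2, id_a = "A", id_b = "B") {
  if (is.na(r2)) r2 <- 0
  D <- sqrt(r2 * pa * (1 - pa) * pb * (1 - pb))
  f_ab <- pa * pb + D
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  if (f_ab < lo - 1e-12 || f_ab > hi + 1e-12) {
    stop(sprintf(
      "infeasible LD target r2=%.3f for pair %s (p=%.3f) / %s (p=%.3f)",
      r2, id_a, pa, id_b, pb))
  }
  c(AB = f_ab, Ab = pa - f_ab, aB = pb - f_ab, ab = 1 - pa - pb + f_ab)
}

#' Construct a genotype matrix
#'
#' @param subject_id character vector of unique subject ids.
#' @param panel a [panel_spec()] or data.frame with at least `snp_id`, `gene`.
#' @param dosage integer matrix subjects x SNPs with values in
#'   `{0, 1, 2, NA}`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(subject_id, panel, dosage) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (anyDuplicated(subject_id)) stop("genotype_matrix: duplicate subject ids")
  if (anyDuplicated(panel$snp_id)) stop("genotype_matrix: duplicate snp ids")
  stopifnot(nrow(dosage) == length(subject_id), ncol(dosage) == nrow(panel))
  ok <- dosage %in% c(0L, 1L, 2L, NA_integer_)
  if (!all(ok)) stop("genotype_matrix: dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(NULL, panel$snp_id)
  structure(list(subject_id = as.character(subject_id),
                 panel = as.data.frame(panel), dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%d genes)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$panel$gene))))
  invisible(x)
}

#' Phenotype table
#'
#' @param data data.frame with a `subject_id` column plus the named
#'   indicator and covariate columns.
#' @param indicators names of the indicator (trait) columns.
#' @param covariates names of the covariate columns (may be empty).
#' @return A `phenotype_table` object.
#' @export
phenotype_table <- function(data, indicators, covariates = character()) {
  stopifnot(is.data.frame(data), "subject_id" %in% names(data))
  if (anyDuplicated(data$subject_id)) {
    stop("phenotype_table: duplicate subject ids")
  }
  missing_cols <- setdiff(c(indicators, covariates), names(data))
  if (length(missing_cols)) {
    stop(sprintf("phenotype_table: missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  structure(list(data = data, indicators = indicators,
                 covariates = covariates),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d subjects, indicators [%s], %d covariates\n",
              nrow(x$data), paste(x$indicators, collapse = ", "),
              length(x$covariates)))
  invisible(x)
}

# Cockerham contrast scores for a planted effect, from panel frequencies.
effect_score <- function(effect, dosage, panel) {
  sc <- function(id, kind) {
    p <- panel$p[match(id, panel$snp_id)]
    g <- dosage[, id]
    w <- contrast_scores(g, p)
    if (kind == "A") w$w_a else w$w_d
  }
  comp <- effect$component
  if (comp %in% c("A", "D")) {
    sc(effect$snp_a, comp)
  } else {
    kinds <- strsplit(comp, "")[[1]]
    sc(effect$snp_a, kinds[1]) * sc(effect$snp_b, kinds[2])
  }
}

#' Simulate a cohort with latent class structure and planted genetic effects
#'
#' Draws covariates as independent standard Gaussians, class labels from a
#' multinomial-logit gating on the covariates, genotypes from the panel (HWE
#' and LD structure per [simulate_genotypes()]), and indicators as
#' class-specific Gaussians plus the planted genetic contributions (through
#' the orthogonal contrast scores of the planted SNPs, using panel
#' frequencies) plus residual noise. The truth record carries the class
#' labels, gating and mean parameters, the per-effect analytic expected
#' variance contributions, and the genetic contribution actually added per
#' subject.
#'
#' @param scn a [scenario()].
#' @return List with `genotypes` (a `genotype_matrix`), `phenotypes` (a
#'   [phenotype_table()]), and `truth` (a `truth_record` list).
#' @export
simulate_population <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(scn$seed)
  n <- scn$n_subjects; K <- scn$K_true
  P <- scn$n_covariates; M <- length(scn$indicators)
  Z <- matrix(stats::rnorm(n * P), n, P,
              dimnames = list(NULL, sprintf("z%02d", seq_len(P))))
  if (K > 1) {
    eta <- cbind(0, cbind(1, Z) %*% t(scn$gating))  # n x K log-odds
    pi_mat <- exp(eta - apply(eta, 1, max))
    pi_mat <- pi_mat / rowSums(pi_mat)
    labels <- apply(pi_mat, 1, function(pr) sample.int(K, 1L, prob = pr))
  } else {
    pi_mat <- matrix(1, n, 1)
    labels <- rep(1L, n)
  }
  geno_seed <- as.integer((as.numeric(scn$seed) * 7919 + 13) %% 2147483647)
  G <- simulate_genotypes(scn$panel, n, seed = geno_seed,
                          missing_rate = scn$missing_rate)
  # planted contributions use a missing-free draw path: scores from panel p,
  # missing dosages contribute 0 to the genetic value
  genetic <- matrix(0, n, M)
  for (ef in scn$planted_effects) {
    s <- effect_score(ef, G$dosage, scn$panel)
    s[is.na(s)] <- 0
    mask <- if (identical(ef$target_class, "all")) rep(TRUE, n)
            else labels == as.integer(ef$target_class)
    genetic <- genetic + ef$beta * s * mask
  }
  Y <- matrix(NA_real_, n, M, dimnames = list(NULL, scn$indicators))
  for (m in seq_len(M)) {
    Y[, m] <- scn$class_means[labels, m] + genetic[, m] +
      stats::rnorm(n, 0, scn$class_sds[labels, m])
  }
  dat <- data.frame(subject_id = G$subject_id, Y, Z, check.names = FALSE)
  pheno <- phenotype_table(dat, scn$indicators, colnames(Z))
  expected <- lapply(scn$planted_effects, function(ef) {
    list(snp_a = ef$snp_a, snp_b = ef$snp_b, component = ef$component,
         beta = ef$beta, target_class = ef$target_class,
         expected_variance = expected_components(ef, scn$panel))
  })
  truth <- structure(
    list(labels = labels, class_probs = pi_mat, gating = scn$gating,
         class_means = scn$class_means, class_sds = scn$class_sds,
         effects = expected, genetic_value = genetic[, 1],
         seed = scn$seed),
    class = "truth_record"
  )
  list(genotypes = G, phenotypes = pheno, truth = truth)
}
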