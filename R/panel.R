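#' SNP panel specification
#'
#' A panel spec declares, per SNP, its identifier, the gene it tags, the
#' chromosome, the population frequency `p` of the counted allele, and an
#' optional linkage-disequilibrium block: SNPs sharing an `ld_block` label are
#' simulated jointly so that consecutive SNPs in the block reach a target
#' haplotype correlation `ld_r2`.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param gene character vector of gene symbols (recycled if length 1).
#' @param p numeric vector of counted-allele frequencies in (0, 1].
#' @param chromosome optional chromosome labels; defaults to one chromosome
#'   per gene, assigned in order of first appearance.
#' @param ld_block optional character/NA vector of block labels.
#' @param ld_r2 optional numeric/NA vector; target r-squared with the previous
#'   SNP of the same block. Ignored for the first SNP of a block.
#' @return A `panel_spec`: a data.frame with columns `snp_id`, `gene`,
#'   `chromosome`, `p`, `ld_block`, `ld_r2`.
#' @export
panel_spec <- function(snp_id, gene, p, chromosome = NULL,
                       ld_block = NA_character_, ld_r2 = NA_real_) {
  m <- length(snp_id)
  if (anyDuplicated(snp_id)) stop("panel_spec: snp_id values must be unique")
  if (length(gene) == 1L) gene <- rep(gene, m)
  if (length(p) == 1L) p <- rep(p, m)
  stopifnot(length(gene) == m, length(p) == m)
  if (any(p <= 0 | p > 1)) stop("panel_spec: allele frequencies must lie in (0, 1]")
  if (is.null(chromosome)) {
    chromosome <- as.character(match(gene, unique(gene)))
  }
  ld_block <- rep_len(as.character(ld_block), m)
  ld_r2 <- rep_len(as.numeric(ld_r2), m)
  bad <- !is.na(ld_r2) & (ld_r2 < 0 | ld_r2 > 1)
  if (any(bad)) stop("panel_spec: ld_r2 must lie in [0, 1]")
  out <- data.frame(
    snp_id = as.character(snp_id), gene = as.character(gene),
    chromosome = as.character(chromosome), p = as.numeric(p),
    ld_block = ld_block, ld_r2 = ld_r2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("panel_spec", "data.frame")
  out
}

#' A planted genetic effect for the population simulator
#'
#' Effects act through the orthogonal Cockerham contrast scores of the named
#' SNPs: `A`/`D` are single-locus additive and dominance effects, and `AA`,
#' `AD`, `DA`, `DD` are the two-locus products. A coefficient `beta` in trait
#' units per contrast unit is applied either in every latent class
#' (`target_class = "all"`) or only within one class.
#'
#' @param snp_a,snp_b panel SNP ids; `snp_b` is required for the two-locus
#'   components and must be `NULL` for `A`/`D`.
#' @param component one of `"A"`, `"D"`, `"AA"`, `"AD"`, `"DA"`, `"DD"`.
#' @param beta finite effect size (trait units per contrast unit).
#' @param target_class `"all"` or an integer class id.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(snp_a, snp_b = NULL, component, beta,
                           target_class = "all") {
  component <- match.arg(component, c("A", "D", "AA", "AD", "DA", "DD"))
  two_locus <- component %in% c("AA", "AD", "DA", "DD")
  if (two_locus && is.null(snp_b)) {
    stop(sprintf("planted_effect: component %s requires snp_b", component))
  }
  if (!two_locus && !is.null(snp_b)) {
    stop(sprintf("planted_effect: component %s takes a single SNP", component))
  }
  if (!is.finite(beta)) stop("planted_effect: beta must be finite")
  structure(
    list(snp_a = snp_a, snp_b = snp_b, component = component,
         beta = as.numeric(beta), target_class = target_class),
    class = "planted_effect"
  )
}

#' Expected variance contributed by a planted effect
#'
#' Under Hardy-Weinberg equilibrium the additive contrast has variance
#' `2pq` and the dominance contrast `(pq)^2`; for two independent loci the
#' product contrasts are zero-mean with variance equal to the product of the
#' marginal contrast variances. The expected trait variance of a planted
#' effect is therefore `beta^2` times the relevant (product of) contrast
#' variance(s).
#'
#' @param effect a [planted_effect()].
#' @param spec the [panel_spec()] the effect refers to.
#' @return Expected variance contribution in squared trait units.
#' @export
expected_components <- function(effect, spec) {
  stopifnot(inherits(effect, "planted_effect"))
  freq <- function(id) {
    i <- match(id, spec$snp_id)
    if (is.na(i)) stop(sprintf("expected_components: SNP '%s' not in panel", id))
    spec$p[i]
  }
  cvar <- function(p, kind) {
    q <- 1 - p
    if (kind == "A") 2 * p * q else (p * q)^2
  }
  pa <- freq(effect$snp_a)
  comp <- effect$component
  v <- switch(comp,
    A = cvar(pa, "A"),
    D = cvar(pa, "D"),
    {
      pb <- freq(effect$snp_b)
      kinds <- strsplit(comp, "")[[1]]
      cvar(pa, kinds[1]) * cvar(pb, kinds[2])
    }
  )
  effect$beta^2 * v
}

#' Simulation scenario
#'
#' Bundles everything the population simulator needs: the SNP panel, the
#' latent-class structure (class count, multinomial-logit gating coefficients
#' on the covariates, class-specific indicator means and residual SDs), the
#' covariate count, the planted genetic effects, and the seed. Covariates are
#' drawn as independent standard Gaussians; their scale is immaterial to
#' recovery studies because the gating coefficients absorb it.
#'
#' @param panel a [panel_spec()].
#' @param n_subjects cohort size.
#' @param K_true number of latent classes.
#' @param gating numeric matrix `(K_true - 1) x (n_covariates + 1)` of
#'   log-odds coefficients (intercept first) for classes `2..K` against class
#'   1; `NULL` for equal class probabilities.
#' @param class_means `K_true x n_indicators` matrix of indicator means.
#' @param class_sds matrix of the same shape with positive residual SDs;
#'   defaults to `noise_sd` everywhere.
#' @param indicators names of the indicator traits.
#' @param n_covariates number of standard-Gaussian covariates.
#' @param planted_effects list of [planted_effect()].
#' @param noise_sd default residual SD used to fill `class_sds`.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed; all randomness in [simulate_population()] flows
#'   from it.
#' @return A `scenario` list.
#' @export
scenario <- function(panel, n_subjects, K_true = 1L, gating = NULL,
                     class_means = NULL, class_sds = NULL,
                     indicators = c("diastolic", "systolic"),
                     n_covariates = 10L, planted_effects = list(),
                     noise_sd = 1, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "panel_spec"), n_subjects >= 1, K_true >= 1)
  M <- length(indicators)
  if (is.null(class_means)) {
    class_means <- matrix(0, nrow = K_true, ncol = M)
  }
  class_means <- as.matrix(class_means)
  stopifnot(nrow(class_means) == K_true, ncol(class_means) == M)
  if (is.null(class_sds)) {
    class_sds <- matrix(noise_sd, nrow = K_true, ncol = M)
  }
  class_sds <- as.matrix(class_sds)
  stopifnot(nrow(class_sds) == K_true, ncol(class_sds) == M)
  if (any(class_sds <= 0)) stop("scenario: all SDs must be > 0")
  if (K_true > 1) {
    if (is.null(gating)) gating <- matrix(0, K_true - 1, n_covariates + 1)
    gating <- as.matrix(gating)
    stopifnot(nrow(gating) == K_true - 1, ncol(gating) == n_covariates + 1)
  } else {
    gating <- NULL
  }
  for (ef in planted_effects) {
    ids <- c(ef$snp_a, ef$snp_b)
    miss <- setdiff(ids, panel$snp_id)
    if (length(miss)) {
      stop(sprintf("scenario: planted SNP '%s' not in panel", miss[1]))
    }
  }
  structure(
    list(panel = panel, n_subjects = as.integer(n_subjects),
         K_true = as.integer(K_true), gating = gating,
         class_means = class_means, class_sds = class_sds,
         indicators = indicators, n_covariates = as.integer(n_covariates),
         planted_effects = planted_effects, noise_sd = noise_sd,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "scenario"
  )
}

#' The default cohort-scale panel: 45 informative SNPs in 23 genes
#'
#' Mirrors the scale of a sphingolipid-pathway candidate panel in a
#' population cohort: 23 genes on distinct chromosomes, most represented by
#' two SNPs, with a handful of modest intragenic LD blocks. Allele
#' frequencies span common to low-frequency variants.
#'
#' @return A [panel_spec()] of 45 SNPs.
#' @export
monica_like_panel <- function() {
  genes <- c("SPTLC1", "SPTLC2", "SPTLC3", "KDSR", "CERS1", "CERS2", "CERS3",
             "CERS4", "CERS5", "CERS6", "DEGS1", "SMPD1", "ASAH1", "ACER1",
             "ACER2", "ACER3", "SPHK1", "SPHK2", "SGPL1", "SGPP1", "CERK",
             "UGCG", "ELOVL1")
  # 22 genes x 2 SNPs + 1 gene x 1 SNP = 45
  gene_vec <- c(rep(genes[-23], each = 2L), genes[23])
  m <- length(gene_vec)
  snp_id <- sprintf("rs%05d", seq_len(m) * 101L + 1000L)
  # deterministic frequency ladder, 0.08..0.50
  p <- round(seq(0.08, 0.50, length.out = m), 3)
  ld_block <- rep(NA_character_, m)
  ld_r2 <- rep(NA_real_, m)
  # modest LD inside four two-SNP genes
  for (g in c("CERS2", "ACER2", "SPHK1", "UGCG")) {
    idx <- which(gene_vec == g)
    ld_block[idx] <- g
    ld_r2[idx[2]] <- 0.5
  }
  panel_spec(snp_id, gene_vec, p, ld_block = ld_block, ld_r2 = ld_r2)
}

#' The default cohort-scale scenario
#'
#' Emulates the structure of a mid-size population cohort: n = 2,523
#' subjects, the 45-SNP/23-gene panel of [monica_like_panel()], two
#' correlated blood-pressure-like indicators (diastolic around 80 mmHg,
#' systolic around 125 mmHg), ten standard-Gaussian covariates driving class
#' membership, and a configurable number of latent classes (2-14) whose
#' indicator means are spread over a physiologic range.
#'
#' @param K_true number of latent classes (default 4).
#' @param n_subjects cohort size (default 2523).
#' @param separation spacing of consecutive class means: each indicator's
#'   class means sit `separation / 2` residual SDs apart (default 5, a
#'   moderately separated mixture; 8 gives 4-SD-per-indicator separation).
#' @param planted_effects list of [planted_effect()] (default: one strong
#'   additive-by-additive pair between SPTLC3 and CERK in the top class).
#' @param seed integer seed.
#' @return A [scenario()].
#' @export
monica_like_scenario <- function(K_true = 4L, n_subjects = 2523L,
                                 separation = 5, planted_effects = NULL,
                                 seed = 20090301L) {
  panel <- monica_like_panel()
  K <- as.integer(K_true)
  stopifnot(K >= 1L, K <= 14L)
  sd_d <- 6; sd_s <- 8
  off <- seq_len(K) - (K + 1) / 2
  class_means <- cbind(80 + off * separation * sd_d / 2,
                       125 + off * separation * sd_s / 2)
  class_sds <- cbind(rep(sd_d, K), rep(sd_s, K))
  gating <- NULL
  if (K > 1) {
    gating <- matrix(0, K - 1, 11L)
    # first three covariates gate membership; higher classes lean on them more
    for (k in seq_len(K - 1)) {
      gating[k, 2:4] <- c(0.8, -0.5, 0.3) * k / (K - 1)
    }
  }
  if (is.null(planted_effects)) {
    snp_a <- panel$snp_id[match("SPTLC3", panel$gene)]
    snp_b <- panel$snp_id[match("CERK", panel$gene)]
    planted_effects <- list(
      planted_effect(snp_a, snp_b, component = "AA", beta = 12,
                     target_class = K)
    )
  }
  scenario(panel, n_subjects, K_true = K, gating = gating,
           class_means = class_means, class_sds = class_sds,
           n_covariates = 10L, planted_effects = planted_effects,
           noise_sd = sd_d, seed = seed)
}
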