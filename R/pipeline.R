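#' Run the full two-step analysis
#'
#' Chains the pipeline: read genotypes and phenotypes, select the mixture
#' model over `K_range` by adjusted BIC (entropy tie-break), compute
#' partition diagnostics, scan every sufficiently large stratum for
#' two-locus epistasis in every trait at the Bonferroni threshold derived
#' from `(alpha, candidate pairs, K, traits)`, build per-stratum gene
#' networks, merge them, optionally subtract a core network, and write the
#' summary tables (per-stratum interaction counts and fractions, per-stratum
#' trait summaries, hypertensive fractions by the 140/90 rule — descriptive
#' only, never entered in the partition). Every exclusion is appended to a
#' structured log. Deterministic given the seed; the report bundle is
#' byte-identical across runs with the same config.
#'
#' @param config a [run_config()].
#' @param core optional core [gene_network()] (or path readable by
#'   [read_network()]) subtracted from the merged network.
#' @return Invisibly, a list with the fitted selection, partition, scans,
#'   networks and summary tables; files are written under `config$out` when
#'   set.
#' @export
run_pipeline <- function(config, core = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_rec <- list()
  note <- function(stage, what, detail = "") {
    log_rec[[length(log_rec) + 1]] <<- data.frame(
      stage = stage, what = what, detail = detail, stringsAsFactors = FALSE)
  }
  stage <- "read"
  result <- tryCatch({
    G <- read_genotypes(config$geno, config$panel)
    pheno <- read_phenotypes(config$pheno, config$indicators,
                             config$covariates)
    if (!identical(sort(G$subject_id), sort(pheno$data$subject_id))) {
      stop("subject ids of genotypes and phenotypes do not match")
    }
    pheno$data <- pheno$data[match(G$subject_id, pheno$data$subject_id), ,
                             drop = FALSE]

    stage <- "partition"
    cfg <- mix_config(restarts = config$restarts, seed = config$seed,
                      factor_model = config$factor_model)
    sel <- select_model(pheno, config$K_range, cfg)
    part <- class_diagnostics(sel$model, pheno)
    K <- sel$K

    stage <- "scan"
    qc_all <- allele_stats(G)
    m_inf <- sum(qc_all$informative)
    n_pairs <- m_inf * (m_inf - 1) / 2
    alpha_star <- bonferroni_threshold(config$alpha, max(n_pairs, 1), K,
                                       length(config$traits))
    cc <- stats::complete.cases(pheno$data[, c(config$indicators,
                                               config$covariates)])
    cc_idx <- which(cc)
    scans <- list()
    for (k in seq_len(K)) {
      members <- cc_idx[part$modal == k]
      for (tr in config$traits) {
        trait_vec <- pheno$data[[tr]]
        sc <- scan_subpopulation(trait_vec, G, members, alpha_star,
                                 trait_name = tr, subpop = k,
                                 min_stratum = config$min_stratum)
        if (!is.na(sc$flag)) {
          note("scan", sprintf("stratum %d / %s skipped", k, tr), sc$flag)
        } else {
          excl <- sc$snp_qc$snp_id[!sc$snp_qc$informative]
          if (length(excl)) {
            note("scan", sprintf("stratum %d: non-informative SNPs", k),
                 paste(excl, collapse = ","))
          }
          hwe_fail <- sc$snp_qc$snp_id[sc$snp_qc$informative &
                                         !sc$snp_qc$hwe_pass]
          if (length(hwe_fail)) {
            note("scan", sprintf("stratum %d: HWE-excluded SNPs", k),
                 paste(hwe_fail, collapse = ","))
          }
        }
        scans[[sprintf("%d.%s", k, tr)]] <- sc
      }
    }

    stage <- "network"
    gene_universe <- unique(G$panel$gene)
    nets <- lapply(scans, function(sc) {
      build_gene_network(sc, alpha_star, curation = config$curation,
                         gene_universe = gene_universe)
    })
    merged <- merge_networks(nets)
    residual <- NULL
    if (!is.null(core)) {
      if (is.character(core)) core <- read_network(core)
      residual <- subtract_network(merged, core)
    }
    cent <- if (nrow(merged$edges)) centrality_indices(merged) else NULL

    stage <- "summary"
    summary_tab <- summarize_scan(scans)
    hyper <- hypertensive_fractions(pheno, part, cc_idx,
                                    config$hypertension_thresholds,
                                    config$indicators)

    stage <- "write"
    if (!is.null(out_dir)) {
      wt <- function(d, f) utils::write.table(
        d, file.path(out_dir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
      write_partition(part, file.path(out_dir, "partition.tsv"))
      wt(sel$table, "selection.tsv")
      all_pairs <- do.call(rbind, lapply(scans, function(s) s$pairs))
      wt(all_pairs, "scan.tsv")
      qc_frames <- lapply(names(scans), function(nm) {
        q <- scans[[nm]]$snp_qc
        if (is.null(q)) return(NULL)
        q$subpop <- scans[[nm]]$subpop; q$trait <- scans[[nm]]$trait
        q
      })
      wt(do.call(rbind, qc_frames), "qc.tsv")
      wt(summary_tab, "summary.tsv")
      wt(hyper, "hypertension.tsv")
      if (!is.null(cent)) wt(cent, "centrality.tsv")
      write_network(merged, file.path(out_dir, "merged.net"))
      write_network(merged, file.path(out_dir, "merged.graphml"))
      write_network(merged, file.path(out_dir, "merged.tsv"))
      if (!is.null(residual)) {
        write_network(residual, file.path(out_dir, "residual.tsv"))
      }
      log_df <- if (length(log_rec)) do.call(rbind, log_rec) else
        data.frame(stage = character(), what = character(),
                   detail = character())
      wt(log_df, "log.tsv")
      manifest <- c(
        sprintf("package: mixepinet %s",
                as.character(utils::packageVersion("mixepinet"))),
        sprintf("r_version: %s", paste(R.version$major, R.version$minor,
                                       sep = ".")),
        sprintf("seed: %d", config$seed),
        sprintf("alpha: %g", config$alpha),
        sprintf("alpha_star: %.17g", alpha_star),
        sprintf("K_selected: %d", K),
        sprintf("config_hash: %s", unname(tools::md5sum(config$pheno))))
      writeLines(manifest, file.path(out_dir, "manifest.txt"))
    }
    list(selection = sel, partition = part, alpha_star = alpha_star,
         scans = scans, networks = nets, merged = merged,
         residual = residual, centrality = cent, summary = summary_tab,
         hypertension = hyper,
         log = if (length(log_rec)) do.call(rbind, log_rec) else NULL)
  }, error = function(e) {
    stop(sprintf("run_pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Summarize scan results across strata and traits
#'
#' One row per stratum and trait: subjects, testable and significant
#' interaction counts, fraction of testable, and the spread
#' (min/max/mean/median) of the relative genetic (epistatic) values among
#' significant pairs; plus `union` rows counting distinct significant SNP
#' pairs per trait across strata.
#'
#' @param results list of `scan_result` objects.
#' @return data.frame summary table.
#' @export
summarize_scan <- function(results) {
  stopifnot(length(results) >= 1)
  rows <- lapply(results, function(sc) {
    sig <- if (nrow(sc$pairs)) sc$pairs[sc$pairs$significant, , drop = FALSE]
           else sc$pairs
    rv <- sig$rel_epistatic
    data.frame(
      subpop = as.character(sc$subpop), trait = sc$trait,
      n_subjects = sc$n_subjects,
      n_candidate_pairs = sc$n_candidate_pairs,
      n_testable_pairs = sc$n_testable_pairs,
      n_significant = sc$n_significant,
      fraction_significant = sc$fraction_significant,
      rel_var_min = if (length(rv)) min(rv) else NA_real_,
      rel_var_max = if (length(rv)) max(rv) else NA_real_,
      rel_var_mean = if (length(rv)) mean(rv) else NA_real_,
      rel_var_median = if (length(rv)) stats::median(rv) else NA_real_,
      flag = if (is.na(sc$flag)) "" else sc$flag,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  traits <- unique(tab$trait)
  for (tr in traits) {
    keys <- unlist(lapply(results, function(sc) {
      if (sc$trait != tr || !nrow(sc$pairs)) return(character())
      s <- sc$pairs[sc$pairs$significant, , drop = FALSE]
      paste(s$snp_a, s$snp_b, sep = "\r")
    }))
    per_stratum_max <- suppressWarnings(
      max(tab$n_significant[tab$trait == tr], na.rm = TRUE))
    tab <- rbind(tab, data.frame(
      subpop = "union", trait = tr, n_subjects = NA_integer_,
      n_candidate_pairs = NA_integer_, n_testable_pairs = NA_integer_,
      n_significant = length(unique(keys)),
      fraction_significant = NA_real_, rel_var_min = NA_real_,
      rel_var_max = NA_real_, rel_var_mean = NA_real_,
      rel_var_median = NA_real_, flag = "", stringsAsFactors = FALSE))
  }
  tab
}

# Descriptive hypertensive fractions per stratum (thresholds in trait units;
# first indicator vs first threshold, second vs second).
hypertensive_fractions <- function(pheno, part, cc_idx, thresholds,
                                   indicators) {
  d <- pheno$data[cc_idx, , drop = FALSE]
  y1 <- d[[indicators[1]]]
  y2 <- if (length(indicators) >= 2) d[[indicators[2]]] else rep(NA_real_,
                                                                 nrow(d))
  t1 <- thresholds[[1]]; t2 <- if (length(thresholds) >= 2) thresholds[[2]]
                               else Inf
  rows <- lapply(seq_along(part$class_sizes), function(k) {
    sel <- part$modal == k
    data.frame(subpop = k, n = sum(sel),
               frac_above_first = mean(y1[sel] > t1),
               frac_above_second = if (all(is.na(y2))) NA_real_
                                   else mean(y2[sel] > t2),
               frac_above_both = if (all(is.na(y2))) NA_real_
                                 else mean(y1[sel] > t1 & y2[sel] > t2),
               frac_hypertensive = if (all(is.na(y2))) mean(y1[sel] > t1)
                                   else mean(y1[sel] > t1 | y2[sel] > t2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(subpop = NA_integer_, n = nrow(d),
                        frac_above_first = mean(y1 > t1),
                        frac_above_second = if (all(is.na(y2))) NA_real_
                                            else mean(y2 > t2),
                        frac_above_both = if (all(is.na(y2))) NA_real_
                                          else mean(y1 > t1 & y2 > t2),
                        frac_hypertensive = if (all(is.na(y2)))
                          mean(y1 > t1) else mean(y1 > t1 | y2 > t2)))
}

#' Convenience: simulate a scenario and write its files
#'
#' Writes the genotype VCF and TSV, panel TSV, phenotype TSV and truth
#' record of a scenario into a directory, as the file-based entry point of
#' the pipeline.
#'
#' @param scn a [scenario()].
#' @param out_dir output directory (created if needed).
#' @return invisible list of file paths plus the in-memory simulation.
#' @export
simulate_to_files <- function(scn, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_population(scn)
  paths <- list(
    geno_vcf = file.path(out_dir, "genotypes.vcf"),
    geno_tsv = file.path(out_dir, "genotypes.tsv"),
    panel = file.path(out_dir, "panel.tsv"),
    pheno = file.path(out_dir, "phenotypes.tsv"),
    truth = file.path(out_dir, "truth.txt"))
  write_genotypes(sim$genotypes, paths$geno_vcf)
  write_genotypes(sim$genotypes, paths$geno_tsv)
  write_panel(scn$panel, paths$panel)
  write_phenotypes(sim$phenotypes, paths$pheno)
  write_truth(sim$truth, paths$truth)
  invisible(c(paths, list(sim = sim)))
}
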