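#' Read a genotype matrix from VCF or a TSV dosage matrix
#'
#' VCF input must be biallelic; the GT field is parsed to counted-ALT-allele
#' dosage and `./.` becomes missing. Multi-allelic records are rejected with
#' an error naming the record. TSV input is a dosage matrix with a
#' `subject_id` first column and one column per SNP. The panel TSV
#' (`snp_id`, `gene`, plus optional `chromosome`, `counted_allele`, `p`) is
#' joined by snp_id; a genotype SNP absent from the panel is an error naming
#' the id.
#'
#' @param path genotype file (`.vcf` or `.tsv`).
#' @param panel_path panel annotation TSV.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, panel_path) {
  panel <- utils::read.delim(panel_path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene") %in% names(panel))) {
    stop("read_genotypes: panel needs snp_id and gene columns")
  }
  if (anyDuplicated(panel$snp_id)) {
    dup <- panel$snp_id[duplicated(panel$snp_id)][1]
    stop(sprintf("read_genotypes: duplicate snp_id '%s' in panel", dup))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    fx <- if (is.matrix(fx)) fx else matrix(fx, nrow = 1,
                                            dimnames = list(NULL, names(fx)))
    alt <- fx[, "ALT"]
    multi <- grepl(",", alt)
    if (any(multi)) {
      stop(sprintf("read_genotypes: multi-allelic VCF record at %s:%s (%s)",
                   fx[multi, "CHROM"][1], fx[multi, "POS"][1],
                   fx[multi, "ID"][1]))
    }
    ids <- fx[, "ID"]
    if (anyDuplicated(ids)) {
      stop(sprintf("read_genotypes: duplicate snp_id '%s' in VCF",
                   ids[duplicated(ids)][1]))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
    dos <- apply(gt, c(1, 2), gt_to_dosage)
    dos <- t(dos)                      # subjects x SNPs
    colnames(dos) <- ids
    subj <- rownames(dos)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(d)[1] != "subject_id") {
      stop("read_genotypes: TSV dosage matrix must start with subject_id")
    }
    subj <- d$subject_id
    dos <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(dos) <- "integer"
  }
  missing_panel <- setdiff(colnames(dos), panel$snp_id)
  if (length(missing_panel)) {
    stop(sprintf("read_genotypes: SNP '%s' missing from panel",
                 missing_panel[1]))
  }
  panel <- panel[match(colnames(dos), panel$snp_id), , drop = FALSE]
  genotype_matrix(subj, panel, dos)
}

gt_to_dosage <- function(gt) {
  if (is.na(gt)) return(NA_integer_)
  gt <- sub(":.*", "", gt)
  if (gt %in% c("./.", ".|.", ".")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(as.integer(alleles))
}

#' Write a genotype matrix to VCF (biallelic, GT field) and/or TSV
#'
#' The VCF writer emits one biallelic record per SNP (REF `A`, ALT `G`
#' placeholders; positions are panel order, 1-based) with per-sample GT;
#' missing dosages become `./.`.
#'
#' @param G a `genotype_matrix`.
#' @param path output path (`.vcf` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "vcf") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", G$subject_id),
                       collapse = "\t")), con)
    gt_codes <- c("0/0", "0/1", "1/1")
    chrom <- if (!is.null(G$panel$chromosome)) G$panel$chromosome
             else rep("1", ncol(G$dosage))
    for (j in seq_len(ncol(G$dosage))) {
      g <- G$dosage[, j]
      gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
      writeLines(paste(c(chrom[j], j, colnames(G$dosage)[j], "A", "G", ".",
                         "PASS", ".", "GT", gt), collapse = "\t"), con)
    }
  } else {
    d <- data.frame(subject_id = G$subject_id, G$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write the SNP panel annotation TSV
#'
#' @param panel a [panel_spec()] or panel data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a phenotype table TSV
#'
#' The TSV carries `subject_id` plus indicator and covariate columns; which
#' columns are which is declared at read time (or via a config).
#'
#' @param pheno a [phenotype_table()].
#' @param path TSV path.
#' @return `path` / a [phenotype_table()].
#' @export
write_phenotypes <- function(pheno, path) {
  stopifnot(inherits(pheno, "phenotype_table"))
  utils::write.table(pheno$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @param indicators,covariates column declarations for the read path.
#' @export
read_phenotypes <- function(path, indicators, covariates = character()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  phenotype_table(d, indicators, covariates)
}

#' Write / read a truth record
#'
#' Plain-text key-value schema, one `key<TAB>value` pair per line; vector
#' values are comma-joined, matrix values are row-major comma-joined with a
#' `dim` prefix (`R x C | values`). Keys: `seed`, `labels`, `genetic_value`,
#' `class_means`, `class_sds`, `gating`, and one `effect.<i>.<field>` group
#' per planted effect.
#'
#' @param truth a `truth_record` from [simulate_population()].
#' @param path output path.
#' @return `path` / a `truth_record`-like list.
#' @export
write_truth <- function(truth, path) {
  fmt_vec <- function(x) paste(format(x, digits = 17, trim = TRUE),
                               collapse = ",")
  fmt_mat <- function(m) sprintf("%dx%d|%s", nrow(m), ncol(m),
                                 fmt_vec(as.vector(t(m))))
  lines <- c(
    paste0("seed\t", truth$seed),
    paste0("labels\t", fmt_vec(truth$labels)),
    paste0("genetic_value\t", fmt_vec(truth$genetic_value)),
    paste0("class_means\t", fmt_mat(truth$class_means)),
    paste0("class_sds\t", fmt_mat(truth$class_sds))
  )
  if (!is.null(truth$gating)) {
    lines <- c(lines, paste0("gating\t", fmt_mat(truth$gating)))
  }
  for (i in seq_along(truth$effects)) {
    ef <- truth$effects[[i]]
    pre <- sprintf("effect.%d.", i)
    lines <- c(lines,
               paste0(pre, "snp_a\t", ef$snp_a),
               paste0(pre, "snp_b\t", if (is.null(ef$snp_b)) "" else ef$snp_b),
               paste0(pre, "component\t", ef$component),
               paste0(pre, "beta\t", format(ef$beta, digits = 17)),
               paste0(pre, "target_class\t", ef$target_class),
               paste0(pre, "expected_variance\t",
                      format(ef$expected_variance, digits = 17)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  get_vec <- function(k) as.numeric(strsplit(vals[keys == k], ",")[[1]])
  get_mat <- function(k) {
    s <- vals[keys == k]
    dimpart <- strsplit(s, "|", fixed = TRUE)[[1]]
    d <- as.integer(strsplit(dimpart[1], "x")[[1]])
    matrix(as.numeric(strsplit(dimpart[2], ",")[[1]]), d[1], d[2],
           byrow = TRUE)
  }
  out <- list(seed = as.integer(vals[keys == "seed"]),
              labels = as.integer(get_vec("labels")),
              genetic_value = get_vec("genetic_value"),
              class_means = get_mat("class_means"),
              class_sds = get_mat("class_sds"))
  if ("gating" %in% keys) out$gating <- get_mat("gating")
  ef_keys <- grep("^effect\\.", keys, value = TRUE)
  if (length(ef_keys)) {
    idx <- unique(as.integer(sub("^effect\\.(\\d+)\\..*", "\\1", ef_keys)))
    out$effects <- lapply(idx, function(i) {
      g <- function(f) vals[keys == sprintf("effect.%d.%s", i, f)]
      list(snp_a = g("snp_a"),
           snp_b = if (nzchar(g("snp_b"))) g("snp_b") else NULL,
           component = g("component"), beta = as.numeric(g("beta")),
           target_class = g("target_class"),
           expected_variance = as.numeric(g("expected_variance")))
    })
  }
  out
}

#' Write a partition TSV (subject, modal class, posteriors)
#'
#' @param part a `partition_result`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "partition_result"))
  post <- as.data.frame(part$posterior)
  names(post) <- sprintf("p_class%d", seq_len(ncol(post)))
  d <- data.frame(subject_id = part$subject_id, modal = part$modal,
                  round(post, 12), stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param geno,panel,pheno input file paths (genotypes, panel TSV,
#'   phenotype TSV).
#' @param indicators,covariates phenotype column declarations.
#' @param K_range candidate class counts for [select_model()].
#' @param alpha nominal family-wise significance level.
#' @param traits traits to scan (default the indicators).
#' @param curation network curation mode.
#' @param min_stratum smallest stratum that is scanned.
#' @param restarts,factor_model EM settings forwarded to [mix_config()].
#' @param hypertension_thresholds case-defining cutoffs for the descriptive
#'   hypertensive-fraction table (never used in the partition itself).
#' @param seed integer seed.
#' @param out output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(geno, panel, pheno, indicators, covariates,
                       K_range = 1:6, alpha = 0.05,
                       traits = NULL, curation = "max-edge",
                       min_stratum = 20L, restarts = 5L,
                       factor_model = FALSE,
                       hypertension_thresholds = c(diastolic = 90,
                                                   systolic = 140),
                       seed = 1L, out = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(geno = geno, panel = panel, pheno = pheno,
                 indicators = indicators, covariates = covariates,
                 K_range = K_range, alpha = alpha,
                 traits = if (is.null(traits)) indicators else traits,
                 curation = curation, min_stratum = as.integer(min_stratum),
                 restarts = as.integer(restarts),
                 factor_model = isTRUE(factor_model),
                 hypertension_thresholds = hypertension_thresholds,
                 seed = as.integer(seed), out = out),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}
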