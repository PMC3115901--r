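#' Construct a gene network
#'
#' @param nodes character vector of gene symbols (the gene universe; isolated
#'   genes stay as nodes).
#' @param edges data.frame with at least `gene_a`, `gene_b`, `weight`;
#'   optional provenance columns `subpop`, `trait`, `snp_a`, `snp_b`, `p`.
#' @return A `gene_network` object (undirected, no self-loops, weights in
#'   (0, 1]).
#' @export
gene_network <- function(nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), subpop = character(),
                        trait = character(), snp_a = character(),
                        snp_b = character(), p = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    for (col in c("subpop", "trait", "snp_a", "snp_b")) {
      if (is.null(edges[[col]])) edges[[col]] <- NA_character_
      edges[[col]] <- as.character(edges[[col]])
    }
    if (is.null(edges$p)) edges$p <- NA_real_
    if (any(edges$gene_a == edges$gene_b)) {
      stop("gene_network: self-loops are not allowed")
    }
    if (any(!is.finite(edges$weight) | edges$weight <= 0 | edges$weight > 1)) {
      stop("gene_network: edge weights must lie in (0, 1]")
    }
    extra <- setdiff(c(edges$gene_a, edges$gene_b), nodes)
    if (length(extra)) {
      stop(sprintf("gene_network: edge genes outside node set: %s",
                   paste(extra, collapse = ", ")))
    }
    # canonical orientation and one row per gene pair
    flip <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[flip]
    edges$gene_a[flip] <- edges$gene_b[flip]
    edges$gene_b[flip] <- tmp
    key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
    if (anyDuplicated(key)) stop("gene_network: duplicate gene-pair edges")
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = sort(nodes), edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d links\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

edge_key <- function(net) paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")

net_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    ia <- match(net$edges$gene_a, net$nodes)
    ib <- match(net$edges$gene_b, net$nodes)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  A
}

net_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b", "weight"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  g
}

#' Build a gene epistasis network from a scan result
#'
#' Keeps significant (`p <= alpha_star`), testable, inter-genic SNP pairs
#' and aggregates them to gene-pair links weighted by relative epistatic
#' variance. Curation `"max-edge"` keeps, per gene pair, the SNP pair of
#' maximal relative epistatic variance. Curation `"representative-snp"`
#' first picks per gene the SNP with the most significant inter-genic
#' interactions (ties broken by larger maximal relative variance, then
#' lexicographic snp_id) and keeps only links between representative SNPs.
#'
#' @param scan a `scan_result` (or the pooled pair data.frame of several).
#' @param alpha_star per-test significance threshold.
#' @param curation `"max-edge"` or `"representative-snp"`.
#' @param gene_universe node set; defaults to all genes in the scan's panel.
#' @return A [gene_network()].
#' @export
build_gene_network <- function(scan, alpha_star,
                               curation = c("max-edge", "representative-snp"),
                               gene_universe = NULL) {
  curation <- match.arg(curation)
  pairs <- if (inherits(scan, "scan_result")) scan$pairs else scan
  if (is.null(gene_universe)) {
    if (inherits(scan, "scan_result") && !is.null(scan$snp_qc)) {
      gene_universe <- unique(c(pairs$gene_a, pairs$gene_b))
    } else {
      gene_universe <- unique(c(pairs$gene_a, pairs$gene_b))
    }
  }
  gene_universe <- setdiff(unique(gene_universe), c(NA, ""))
  if (nrow(pairs) == 0) return(gene_network(gene_universe))
  sig <- pairs$testable & !pairs$intragenic & !is.na(pairs$p_value) &
    pairs$p_value <= alpha_star & !is.na(pairs$rel_epistatic) &
    pairs$rel_epistatic > 0
  sel <- pairs[sig, , drop = FALSE]
  if (nrow(sel) == 0) return(gene_network(gene_universe))
  if (curation == "representative-snp") {
    sel <- curate_representative(sel)
  }
  # per gene pair keep the maximal relative-variance SNP pair
  ga <- pmin(sel$gene_a, sel$gene_b); gb <- pmax(sel$gene_a, sel$gene_b)
  key <- paste(ga, gb, sep = "\r")
  ord <- order(key, -sel$rel_epistatic, sel$snp_a, sel$snp_b)
  sel <- sel[ord, , drop = FALSE]
  keep <- !duplicated(paste(pmin(sel$gene_a, sel$gene_b),
                            pmax(sel$gene_a, sel$gene_b), sep = "\r"))
  sel <- sel[keep, , drop = FALSE]
  edges <- data.frame(
    gene_a = sel$gene_a, gene_b = sel$gene_b,
    weight = pmin(sel$rel_epistatic, 1),
    subpop = as.character(if (!is.null(sel$subpop)) sel$subpop else NA),
    trait = as.character(if (!is.null(sel$trait)) sel$trait else NA),
    snp_a = sel$snp_a, snp_b = sel$snp_b, p = sel$p_value,
    stringsAsFactors = FALSE
  )
  gene_network(gene_universe, edges)
}

# Pick one representative SNP per gene: most significant inter-genic
# interactions, ties by larger maximal relative variance, then lexicographic.
curate_representative <- function(sel) {
  snp_gene <- unique(rbind(
    data.frame(snp = sel$snp_a, gene = sel$gene_a, stringsAsFactors = FALSE),
    data.frame(snp = sel$snp_b, gene = sel$gene_b, stringsAsFactors = FALSE)))
  cnt <- table(c(sel$snp_a, sel$snp_b))
  mx <- vapply(snp_gene$snp, function(s) {
    max(sel$rel_epistatic[sel$snp_a == s | sel$snp_b == s])
  }, numeric(1))
  snp_gene$n_int <- as.integer(cnt[snp_gene$snp])
  snp_gene$max_w <- mx
  reps <- character(0)
  for (g in unique(snp_gene$gene)) {
    cand <- snp_gene[snp_gene$gene == g, , drop = FALSE]
    cand <- cand[order(-cand$n_int, -cand$max_w, cand$snp), , drop = FALSE]
    reps <- c(reps, cand$snp[1])
  }
  sel[sel$snp_a %in% reps & sel$snp_b %in% reps, , drop = FALSE]
}

#' Centrality indices of a gene network
#'
#' Computed on the unweighted topology (edge weights select links, they do
#' not define path lengths): degree; closeness `(c - 1) / sum d(v, u)`
#' within v's component of size `c` (0 for isolated nodes); betweenness
#' `sum sigma_st(v) / sigma_st` over unordered pairs s < t (s, t != v);
#' stress `sum sigma_st(v)` (shortest paths through v); centroid value
#' `min_u [gamma_v(u) - gamma_u(v)]` with `gamma_v(u)` the number of nodes
#' strictly closer to v than to u (u ranges over v's component); Katz status
#' = row sums of `sum_{k>=1} alpha^k A^k` with `alpha = 0.85 / lambda_max`
#' by default; closeness vitality = Wiener(G) - Wiener(G minus v) (sum of
#' finite shortest-path distances over unordered pairs), `NA` with
#' `vitality_disconnects = TRUE` when removing v splits its component.
#'
#' @param net a [gene_network()].
#' @param katz_alpha Katz attenuation; default `0.85 / lambda_max(A)`. Must
#'   be below `1 / lambda_max` or the series diverges (error).
#' @return data.frame, one row per gene: `gene`, `degree`, `closeness`,
#'   `betweenness`, `stress`, `centroid`, `katz`, `vitality`,
#'   `vitality_disconnects`.
#' @export
centrality_indices <- function(net, katz_alpha = NULL) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  if (n == 0) stop("centrality_indices: empty network")
  A <- net_adjacency(net)
  g <- net_igraph(net)
  D <- igraph::distances(g, weights = NA)
  D <- D[net$nodes, net$nodes]
  deg <- rowSums(A)
  comp <- igraph::components(g)
  memb <- comp$membership[net$nodes]
  closeness <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(memb == memb[i])
    c_sz <- length(same)
    closeness[i] <- if (c_sz > 1) (c_sz - 1) / sum(D[i, same]) else 0
  }
  sig <- path_counts(A, D)
  btw <- numeric(n); str_ <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq.int(s + 1, n)) {
        if (s == v || t == v) next
        if (!is.finite(D[s, t]) || sig[s, t] == 0) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          through <- sig[s, v] * sig[v, t]
          btw[v] <- btw[v] + through / sig[s, t]
          str_[v] <- str_[v] + through
        }
      }
    }
  }
  centroid <- numeric(n)
  for (v in seq_len(n)) {
    others <- setdiff(which(memb == memb[v]), v)
    if (!length(others)) { centroid[v] <- 0; next }
    vals <- vapply(others, function(u) {
      gamma_vu <- sum(D[, v] < D[, u])
      gamma_uv <- sum(D[, u] < D[, v])
      gamma_vu - gamma_uv
    }, numeric(1))
    centroid[v] <- min(vals)
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam_max <- max(abs(ev))
  if (is.null(katz_alpha)) {
    katz_alpha <- if (lam_max > 0) 0.85 / lam_max else 0.85
  }
  if (lam_max > 0 && katz_alpha >= 1 / lam_max) {
    stop(sprintf("centrality_indices: Katz alpha %.4f >= 1/lambda_max %.4f",
                 katz_alpha, 1 / lam_max))
  }
  katz <- as.vector(solve(diag(n) - katz_alpha * A, rep(1, n))) - 1
  wiener_total <- sum(D[upper.tri(D)][is.finite(D[upper.tri(D)])])
  vit <- rep(NA_real_, n)
  vit_disc <- rep(FALSE, n)
  for (v in seq_len(n)) {
    same <- which(memb == memb[v])
    if (length(same) <= 1) { vit[v] <- 0; next }
    keep <- setdiff(seq_len(n), v)
    Av <- A[keep, keep, drop = FALSE]
    gv <- igraph::graph_from_adjacency_matrix(Av, mode = "undirected")
    Dv <- igraph::distances(gv, weights = NA)
    rest <- setdiff(same, v)
    rest_idx <- match(rest, keep)
    sub <- Dv[rest_idx, rest_idx, drop = FALSE]
    if (any(!is.finite(sub[upper.tri(sub)]))) {
      vit_disc[v] <- TRUE
      next
    }
    wiener_v <- sum(Dv[upper.tri(Dv)][is.finite(Dv[upper.tri(Dv)])])
    vit[v] <- wiener_total - wiener_v
  }
  data.frame(gene = net$nodes, degree = deg, closeness = closeness,
             betweenness = btw, stress = str_, centroid = centroid,
             katz = katz, vitality = vit, vitality_disconnects = vit_disc,
             stringsAsFactors = FALSE, row.names = NULL)
}

# sigma[s, t]: number of shortest s-t paths, by DP over distance layers.
path_counts <- function(A, D) {
  n <- nrow(A)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      preds <- which(A[, v] == 1 & D[s, ] == D[s, v] - 1)
      sig[s, v] <- sum(sig[s, preds])
    }
  }
  sig
}

#' Merge gene networks (edge union, max weight)
#'
#' @param nets list of [gene_network()] objects over a shared gene universe.
#' @return merged [gene_network()]: node union, edge union, per-pair weight
#'   = max over inputs, provenance concatenated (`;`-joined).
#' @export
merge_networks <- function(nets) {
  if (inherits(nets, "gene_network")) nets <- list(nets)
  stopifnot(length(nets) >= 1)
  nodes <- unique(unlist(lapply(nets, function(x) x$nodes)))
  all_edges <- do.call(rbind, lapply(nets, function(x) x$edges))
  if (is.null(all_edges) || nrow(all_edges) == 0) return(gene_network(nodes))
  key <- paste(all_edges$gene_a, all_edges$gene_b, sep = "\r")
  rows <- lapply(split(seq_len(nrow(all_edges)), key), function(ii) {
    e <- all_edges[ii, , drop = FALSE]
    best <- which.max(e$weight)
    out <- e[best, , drop = FALSE]
    joinu <- function(x) paste(unique(stats::na.omit(x)), collapse = ";")
    out$subpop <- joinu(e$subpop); out$trait <- joinu(e$trait)
    out$snp_a <- joinu(e$snp_a); out$snp_b <- joinu(e$snp_b)
    pv <- suppressWarnings(min(e$p, na.rm = TRUE))
    out$p <- if (is.finite(pv)) pv else NA_real_
    out
  })
  gene_network(nodes, do.call(rbind, rows))
}

#' Subtract a core network
#'
#' Keeps the edges of `a` whose gene pair is absent from `b`; the node set
#' of `a` (plus `b`'s nodes) is preserved.
#'
#' @param a,b [gene_network()] objects over a shared gene universe.
#' @return [gene_network()] with `a`'s private edges.
#' @export
subtract_network <- function(a, b) {
  stopifnot(inherits(a, "gene_network"), inherits(b, "gene_network"))
  nodes <- unique(c(a$nodes, b$nodes))
  if (nrow(a$edges) == 0) return(gene_network(nodes))
  keep <- !(edge_key(a) %in% edge_key(b))
  gene_network(nodes, a$edges[keep, , drop = FALSE])
}

#' Write a gene network to Pajek, GraphML or a TSV edge list
#'
#' Pajek `.net` uses 1-based vertex numbering (`*Vertices` then `*Edges`
#' with weights); GraphML goes through igraph with `name` and `weight`
#' attributes; the TSV edge list carries full provenance (gene_a, gene_b,
#' weight, subpop, trait, snp_a, snp_b, p) plus a node list header line.
#' All three round-trip through [read_network()].
#'
#' @param net a [gene_network()].
#' @param path output file path.
#' @param format `"pajek"`, `"graphml"` or `"tsv"` (default from the file
#'   extension).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, net = "pajek", paj = "pajek", graphml = "graphml",
                     tsv = "tsv", txt = "tsv",
                     stop(sprintf("write_network: cannot infer format from '%s'",
                                  path)))
  }
  if (!format %in% c("pajek", "graphml", "tsv")) {
    stop(sprintf(
      "write_network: unknown format '%s' (supported: pajek, graphml, tsv)",
      format))
  }
  if (format == "pajek") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("*Vertices %d", length(net$nodes)), con)
    writeLines(sprintf('%d "%s"', seq_along(net$nodes), net$nodes), con)
    writeLines("*Edges", con)
    if (nrow(net$edges)) {
      ia <- match(net$edges$gene_a, net$nodes)
      ib <- match(net$edges$gene_b, net$nodes)
      writeLines(sprintf("%d %d %.17g", ia, ib, net$edges$weight), con)
    }
  } else if (format == "graphml") {
    g <- net_igraph(net)
    for (col in c("subpop", "trait", "snp_a", "snp_b")) {
      igraph::edge_attr(g, col) <- net$edges[[col]]
    }
    igraph::edge_attr(g, "p") <- net$edges$p
    igraph::write_graph(g, path, format = "graphml")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# nodes: ", paste(net$nodes, collapse = ",")), con)
    utils::write.table(
      format(net$edges, digits = 17, scientific = FALSE, trim = TRUE),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene network written by [write_network()]
#'
#' @param path file path.
#' @param format `"pajek"`, `"graphml"` or `"tsv"` (default from extension).
#' @return A [gene_network()].
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, net = "pajek", paj = "pajek", graphml = "graphml",
                     tsv = "tsv", txt = "tsv",
                     stop(sprintf("read_network: cannot infer format from '%s'",
                                  path)))
  }
  if (format == "pajek") {
    lines <- readLines(path)
    nv <- as.integer(sub("\\*Vertices\\s+", "", lines[1], ignore.case = TRUE))
    vlines <- lines[2:(1 + nv)]
    nodes <- sub('^\\s*\\d+\\s+"(.*)"\\s*$', "\\1", vlines)
    estart <- grep("^\\*Edges", lines, ignore.case = TRUE)
    edges <- NULL
    if (length(lines) > estart) {
      el <- lines[(estart + 1):length(lines)]
      el <- el[nzchar(trimws(el))]
      if (length(el)) {
        parts <- do.call(rbind, strsplit(trimws(el), "\\s+"))
        edges <- data.frame(gene_a = nodes[as.integer(parts[, 1])],
                            gene_b = nodes[as.integer(parts[, 2])],
                            weight = as.numeric(parts[, 3]),
                            stringsAsFactors = FALSE)
      }
    }
    gene_network(nodes, edges)
  } else if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::vertex_attr(g, "name")
    ed <- igraph::as_data_frame(g, what = "edges")
    if (nrow(ed)) {
      names(ed)[names(ed) == "from"] <- "gene_a"
      names(ed)[names(ed) == "to"] <- "gene_b"
    } else {
      ed <- NULL
    }
    gene_network(nodes, ed)
  } else if (format == "tsv") {
    lines <- readLines(path, n = 1)
    nodes <- strsplit(sub("^# nodes: ", "", lines), ",")[[1]]
    ed <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (nrow(ed) == 0) ed <- NULL
    gene_network(nodes, ed)
  } else {
    stop(sprintf(
      "read_network: unknown format '%s' (supported: pajek, graphml, tsv)",
      format))
  }
}
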