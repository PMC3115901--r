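# Shared fixture builders. Everything is generated in code; no stored data.

two_snp_panel <- function(p_a = 0.5, p_b = 0.5, genes = c("G1", "G2")) {
  panel_spec(c("snpA", "snpB"), genes, c(p_a, p_b))
}

# Genotype vector with counts exactly proportional to HWE at frequency p
# (p chosen so q^2*n, 2pq*n, p^2*n are integers).
exact_hwe_genotypes <- function(p, n) {
  q <- 1 - p
  n0 <- round(q^2 * n); n1 <- round(2 * p * q * n); n2 <- round(p^2 * n)
  stopifnot(n0 + n1 + n2 == n,
            abs(n0 - q^2 * n) < 1e-9, abs(n1 - 2 * p * q * n) < 1e-9)
  rep(c(0L, 1L, 2L), c(n0, n1, n2))
}

# Exact-HWE two-locus design: all 9 genotype combinations with counts
# proportional to the product of the marginal HWE probabilities.
exact_hwe_pair <- function(p_a, p_b, n_unit) {
  ga <- exact_hwe_genotypes(p_a, n_unit)
  # every combination of ga with an exact HWE column for B
  gb <- exact_hwe_genotypes(p_b, n_unit)
  list(g_a = rep(ga, each = length(gb)), g_b = rep(gb, times = length(ga)))
}

# Brute-force HWE exact test: enumerate all heterozygote counts compatible
# with the allele counts and sum probabilities <= observed. Independent of
# the package path: plain factorial() arithmetic.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- n1 + 2 * n2; na_ <- n1 + 2 * n0
  if (nA == 0 || na_ == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na_), by = 2)
  prob <- sapply(hets, function(h) {
    nAA <- (nA - h) / 2; naa <- (na_ - h) / 2
    factorial(n) / (factorial(nAA) * factorial(h) * factorial(naa)) *
      2^h * factorial(nA) * factorial(na_) / factorial(2 * n)
  })
  obs <- prob[hets == n1]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# A deterministic random graph on n nodes with edge probability prob,
# returned as a gene_network with unit-free weights in (0, 1].
random_gene_graph <- function(n, prob, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  prs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(prs)) < prob
  edges <- NULL
  if (any(keep)) {
    edges <- data.frame(gene_a = prs[1, keep], gene_b = prs[2, keep],
                        weight = round(stats::runif(sum(keep), 0.05, 1), 3),
                        stringsAsFactors = FALSE)
  }
  gene_network(nodes, edges)
}

# Floyd-Warshall distances + exhaustive shortest-path enumeration oracle for
# betweenness/stress/closeness/centroid on small graphs.
centrality_oracle <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    ia <- match(net$edges$gene_a, nodes); ib <- match(net$edges$gene_b, nodes)
    A[cbind(ia, ib)] <- 1; A[cbind(ib, ia)] <- 1
  }
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  # enumerate all shortest s-t paths by recursive descent
  all_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (v in which(A[, t] == 1 & D[s, ] == D[s, t] - 1)) {
      for (pth in all_paths(s, v)) out <- c(out, list(c(pth, t)))
    }
    out
  }
  btw <- numeric(n); str_ <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    paths <- all_paths(s, t)
    np <- length(paths)
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      cnt <- table(inner)
      idx <- as.integer(names(cnt))
      btw[idx] <- btw[idx] + as.numeric(cnt) / np
      str_[idx] <- str_[idx] + as.numeric(cnt)
    }
  }
  clo <- numeric(n)
  cen <- numeric(n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(D[v, ]))
    if (length(comp) > 1) clo[v] <- (length(comp) - 1) / sum(D[v, comp])
    others <- setdiff(comp, v)
    if (length(others)) {
      cen[v] <- min(sapply(others, function(u) {
        sum(D[, v] < D[, u]) - sum(D[, u] < D[, v])
      }))
    }
  }
  list(betweenness = btw, stress = str_, closeness = clo, centroid = cen,
       A = A, D = D)
}
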