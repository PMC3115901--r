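path3 <- function() {
  gene_network(c("A", "B", "C"),
               data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                          weight = c(0.5, 0.4)))
}

test_that("a 3-path has the analytically forced centralities", {
  ct <- centrality_indices(path3())
  b <- which(ct$gene == "B"); a <- which(ct$gene == "A")
  expect_equal(ct$degree[b], 2)
  expect_equal(ct$betweenness[b], 1)
  expect_equal(ct$stress[b], 1)
  expect_equal(ct$closeness[b], 1)
  expect_equal(ct$closeness[a], 2 / 3)
  expect_equal(ct$betweenness[a], 0)
  # vitality: removing a leaf node drops Wiener from 4 to 1
  expect_equal(ct$vitality[a], 3)
  expect_true(ct$vitality_disconnects[b])
})

test_that("centralities match brute-force enumeration on small graphs", {
  for (seed in 1:25) {
    n <- 4 + (seed %% 5)
    net <- random_gene_graph(n, prob = 0.4, seed = seed)
    ct <- centrality_indices(net)
    orc <- centrality_oracle(net)
    expect_equal(ct$betweenness, orc$betweenness, tolerance = 1e-12)
    expect_equal(ct$stress, orc$stress, tolerance = 1e-12)
    expect_equal(ct$closeness, orc$closeness, tolerance = 1e-12)
    expect_equal(ct$centroid, orc$centroid, tolerance = 1e-12)
    # Katz equals the truncated series within 1e-8
    A <- orc$A
    lam <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
    if (lam > 0) {
      alpha <- 0.85 / lam
      acc <- rep(0, n); Ak <- diag(n)
      for (k in 1:200) {
        Ak <- alpha * (Ak %*% A)
        acc <- acc + rowSums(Ak)
      }
      expect_equal(ct$katz, acc, tolerance = 1e-8)
    }
  }
})

test_that("centralities are invariant under node relabeling", {
  net <- random_gene_graph(7, 0.45, seed = 99)
  ct <- centrality_indices(net)
  # relabel nodes and rebuild
  map <- setNames(sprintf("Z%02d", sample(7)), net$nodes)
  ed <- net$edges
  ed$gene_a <- unname(map[ed$gene_a]); ed$gene_b <- unname(map[ed$gene_b])
  net2 <- gene_network(unname(map), ed)
  ct2 <- centrality_indices(net2)
  ct2 <- ct2[match(unname(map[ct$gene]), ct2$gene), ]
  for (col in c("degree", "closeness", "betweenness", "stress", "centroid",
                "katz")) {
    expect_equal(unname(ct2[[col]]), unname(ct[[col]]), tolerance = 1e-10)
  }
})

test_that("a diverging Katz attenuation errors", {
  net <- path3()
  expect_error(centrality_indices(net, katz_alpha = 5), "alpha")
})

test_that("gene networks are built, curated and counted correctly", {
  # 23-gene universe: 253 possible links
  genes <- unique(monica_like_panel()$gene)
  expect_equal(choose(length(genes), 2), 253)

  # synthetic scan table with significant inter- and intragenic pairs
  pairs <- data.frame(
    snp_a = c("s1", "s2", "s3", "s1", "s4"),
    snp_b = c("s3", "s3", "s4", "s2", "s5"),
    gene_a = c("G1", "G1", "G2", "G1", "G3"),
    gene_b = c("G2", "G2", "G3", "G1", "G3"),
    intragenic = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    testable = TRUE,
    rel_epistatic = c(0.30, 0.40, 0.20, 0.9, 0.9),
    p_value = c(1e-8, 1e-9, 1e-8, 1e-12, 1e-12),
    subpop = 1, trait = "diastolic", stringsAsFactors = FALSE)
  net <- build_gene_network(pairs, alpha_star = 1e-6,
                            gene_universe = c("G1", "G2", "G3"))
  # intragenic links dropped; per gene pair the max-variance SNP pair kept
  expect_equal(nrow(net$edges), 2)
  e12 <- net$edges[net$edges$gene_a == "G1" & net$edges$gene_b == "G2", ]
  expect_equal(e12$weight, 0.40)
  expect_equal(e12$snp_a, "s2")

  # representative-snp curation: G1 -> s2? counts: s1:1, s2:1, s3:2, s4:1
  net_r <- build_gene_network(pairs, alpha_star = 1e-6,
                              curation = "representative-snp",
                              gene_universe = c("G1", "G2", "G3"))
  # representative of G1 is s1 (tie s1/s2 broken by weight then id: s2 has
  # larger max weight) -> s2; G2 -> s3; G3 -> s4
  expect_true(all(c(net_r$edges$snp_a, net_r$edges$snp_b) %in%
                    c("s2", "s3", "s4")))
  expect_lte(nrow(net_r$edges), nrow(net$edges))

  # zero significant pairs -> empty network with all genes isolated
  net0 <- build_gene_network(pairs, alpha_star = 1e-20,
                             gene_universe = c("G1", "G2", "G3"))
  expect_equal(nrow(net0$edges), 0)
  expect_equal(length(net0$nodes), 3)
})

test_that("94 links among 23 genes is 37.2% of possible", {
  genes <- sprintf("G%02d", 1:23)
  prs <- utils::combn(genes, 2)
  set.seed(123)
  keep <- sample(ncol(prs), 94)
  net <- gene_network(genes, data.frame(
    gene_a = prs[1, keep], gene_b = prs[2, keep], weight = 0.1))
  frac <- nrow(net$edges) / choose(length(net$nodes), 2)
  expect_equal(round(100 * frac, 1), 37.2)
})

test_that("merge is idempotent, has an identity, and adds disjoint edges", {
  x <- random_gene_graph(6, 0.5, seed = 7)
  e0 <- gene_network(x$nodes)
  expect_equal(merge_networks(list(x))$edges[, c("gene_a", "gene_b", "weight")],
               x$edges[, c("gene_a", "gene_b", "weight")])
  expect_equal(merge_networks(list(x, e0))$edges[, c("gene_a", "gene_b", "weight")],
               x$edges[, c("gene_a", "gene_b", "weight")])
  y <- gene_network(c("P1", "P2"), data.frame(gene_a = "P1", gene_b = "P2",
                                              weight = 0.2))
  m <- merge_networks(list(x, y))
  expect_equal(nrow(m$edges), nrow(x$edges) + 1)

  # max-weight, commutative, associative
  a <- random_gene_graph(6, 0.5, seed = 8)
  b <- random_gene_graph(6, 0.5, seed = 9)
  c_ <- random_gene_graph(6, 0.5, seed = 10)
  w_of <- function(net) setNames(net$edges$weight,
                                 paste(net$edges$gene_a, net$edges$gene_b))
  m1 <- merge_networks(list(a, merge_networks(list(b, c_))))
  m2 <- merge_networks(list(merge_networks(list(a, b)), c_))
  m3 <- merge_networks(list(c_, b, a))
  expect_equal(w_of(m1), w_of(m2))
  expect_equal(w_of(m1), w_of(m3))
  shared <- intersect(names(w_of(a)), names(w_of(b)))
  if (length(shared)) {
    m_ab <- merge_networks(list(a, b))
    expect_equal(w_of(m_ab)[shared],
                 pmax(w_of(a)[shared], w_of(b)[shared]))
  }
})

test_that("core subtraction obeys set algebra", {
  x <- random_gene_graph(7, 0.5, seed = 11)
  e0 <- gene_network(x$nodes)
  expect_equal(nrow(subtract_network(x, x)$edges), 0)
  expect_equal(subtract_network(x, e0)$edges, x$edges)
  for (seed in 12:16) {
    a <- random_gene_graph(7, 0.4, seed = seed)
    b <- random_gene_graph(7, 0.4, seed = seed + 100)
    akey <- paste(a$edges$gene_a, a$edges$gene_b)
    bkey <- paste(b$edges$gene_a, b$edges$gene_b)
    expect_equal(nrow(a$edges),
                 nrow(subtract_network(a, b)$edges) +
                   length(intersect(akey, bkey)))
  }
  # node set preserved even when all edges vanish
  expect_equal(subtract_network(x, x)$nodes, x$nodes)
})

test_that("all formats round-trip nodes, edges and weights exactly", {
  net <- random_gene_graph(8, 0.4, seed = 17)
  td <- withr::local_tempdir()
  for (spec in list(c("pajek", "x.net"), c("graphml", "x.graphml"),
                    c("tsv", "x.tsv"))) {
    p <- file.path(td, spec[2])
    write_network(net, p)
    back <- read_network(p)
    expect_identical(back$nodes, net$nodes)
    expect_equal(back$edges$gene_a, net$edges$gene_a)
    expect_equal(back$edges$gene_b, net$edges$gene_b)
    expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-15)
  }
  # pajek structure of a 3-path: *Vertices 3 and two edge rows
  p3 <- file.path(td, "p3.net")
  write_network(path3(), p3)
  lines <- readLines(p3)
  expect_equal(lines[1], "*Vertices 3")
  expect_equal(sum(grepl("^\\d+ \\d+ ", lines)), 2)
  # graphml is well-formed XML with the right number of edge elements
  gml <- file.path(td, "g.graphml")
  write_network(net, gml)
  doc <- xml2::read_xml(gml)
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:edge",
                                         xml2::xml_ns(doc))),
               nrow(net$edges))

  expect_error(write_network(net, "x.foo", format = "foo"), "supported")
  expect_error(read_network("x.foo", format = "foo"), "supported")
})
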