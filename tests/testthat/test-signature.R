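test_that("basal-plus-extension annotation follows hand interval arithmetic", {
  genes <- data.frame(
    gene = c("G1", "G2"),
    chrom = c("chr1", "chr1"),
    tss = c(100000, 110000),  # 10 kb apart
    strand = c("+", "+"),
    stringsAsFactors = FALSE
  )
  # basal domains (up 5000 / down 1000): G1 [95000, 101000), G2 [105000, 111000)
  # extensions are truncated at the neighbor's basal region, so the gap
  # [101000, 105000) belongs to both genes' extended domains.
  peak_between <- data.frame(chrom = "chr1", start = 102000, end = 102100)
  bound <- annotate_peaks_to_genes(peak_between, genes)
  expect_setequal(bound, c("G1", "G2"))

  # peak on the TSS of a + strand gene
  peak_tss <- data.frame(chrom = "chr1", start = 99990, end = 100010)
  expect_true("G1" %in% annotate_peaks_to_genes(peak_tss, genes))

  # a peak inside G2's basal region binds only G2 (G1's extension stops at
  # G2's basal boundary 105000)
  peak_basal2 <- data.frame(chrom = "chr1", start = 106000, end = 106050)
  expect_identical(annotate_peaks_to_genes(peak_basal2, genes), "G2")

  # far beyond the 1 Mb extension: bound by neither
  peak_far <- data.frame(chrom = "chr1", start = 5e6, end = 5e6 + 100)
  expect_length(annotate_peaks_to_genes(peak_far, genes), 0)

  # empty peak set, wrong chromosome, strand awareness
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  expect_length(annotate_peaks_to_genes(empty, genes), 0)
  other_chr <- data.frame(chrom = "chr2", start = 100000, end = 100100)
  expect_length(annotate_peaks_to_genes(other_chr, genes), 0)
  minus <- data.frame(gene = "M1", chrom = "chr1", tss = 50000, strand = "-",
                      stringsAsFactors = FALSE)
  # minus strand: basal [tss - 1000, tss + 5000)
  pk_up <- data.frame(chrom = "chr1", start = 54000, end = 54500)
  expect_identical(annotate_peaks_to_genes(pk_up, minus), "M1")
  pk_down <- data.frame(chrom = "chr1", start = 44000, end = 44500)
  # within extension on the downstream side -> still bound (no neighbor)
  expect_identical(annotate_peaks_to_genes(pk_down, minus), "M1")
  bad <- data.frame(gene = "B", chrom = "chr1", tss = 1, strand = "*",
                    stringsAsFactors = FALSE)
  expect_error(annotate_peaks_to_genes(pk_up, bad), "strand")
})

test_that("three-filter derivation recovers exactly the planted anti-correlated genes", {
  sim <- simulate_cellline_panel(
    panel_sim_config(seed = 8, n_negative = 2, n_positive = 1, n_null = 10,
                     correlation_strength = 0.9)
  )
  planted_neg <- names(sim$classes)[sim$classes == "negative"]
  planted_pos <- names(sim$classes)[sim$classes == "positive"]
  bound <- c(planted_neg, planted_pos)
  de <- data.frame(gene = rownames(sim$expr),
                   log2fc = 1, p_adj = 0.001, stringsAsFactors = FALSE)
  sig <- derive_repression_signature(bound, de, sim$expr, sim$anchor)
  expect_setequal(sig$genes, planted_neg)
  expect_equal(sig$provenance$n_candidates, 3)
  expect_equal(sig$provenance$n_anticorrelated, 2)
})

test_that("derivation returns empty signatures for degenerate filters", {
  sim <- simulate_cellline_panel(panel_sim_config(seed = 8, n_null = 5))
  de <- data.frame(gene = rownames(sim$expr), log2fc = 1, p_adj = 0.001,
                   stringsAsFactors = FALSE)
  # bound and upregulated sets disjoint
  sig1 <- derive_repression_signature("not_in_de", de, sim$expr, sim$anchor)
  expect_length(sig1$genes, 0)
  # all candidates positively correlated
  pos_genes <- names(sim$classes)[sim$classes == "positive"]
  sig2 <- derive_repression_signature(pos_genes, de, sim$expr, sim$anchor)
  expect_length(sig2$genes, 0)
  expect_error(derive_repression_signature("g", de, sim$expr, "MISSING"),
               "anchor")
})

test_that("derivation is a pure deterministic filter", {
  sim <- simulate_cellline_panel(panel_sim_config(seed = 14))
  de <- data.frame(gene = rownames(sim$expr),
                   log2fc = rnorm(nrow(sim$expr)),
                   p_adj = runif(nrow(sim$expr)), stringsAsFactors = FALSE)
  bound <- sample(rownames(sim$expr), 100)
  a <- derive_repression_signature(bound, de, sim$expr, sim$anchor)
  b <- derive_repression_signature(bound, de, sim$expr, sim$anchor)
  expect_identical(a, b)
  up <- de$gene[de$p_adj <= 0.05 & de$log2fc >= 0]
  expect_true(all(a$genes %in% intersect(bound, up)))
})

test_that("spearman correlation matches hand rank arithmetic", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  r <- spearman_cor(x, y)
  # direct rank arithmetic: d = (-1, 1, -1, 1, 0), sum d^2 = 4,
  # rho = 1 - 6 * 4 / (5 * 24) = 0.8
  expect_equal(r$rho, 0.8)
  expect_equal(spearman_cor(x, -y)$rho, -0.8)
  # monotone relation
  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)
  # t-approximation p agrees with the reference implementation
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(r$rho, unname(ref$estimate))
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # zero rank variance flagged
  expect_true(spearman_cor(rep(1, 5), y)$degenerate)
})

test_that("single-sample scores match the independent oracle on a traceable matrix", {
  set.seed(99)
  expr <- matrix(rnorm(5 * 3), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  set_genes <- c("g2", "g4")
  for (kcdf in c("gaussian", "ecdf")) {
    got <- gsva_scores(expr, set_genes, tau = 1, kcdf = kcdf)
    want <- oracle_gsva(expr, set_genes, tau = 1, kcdf = kcdf)
    expect_equal(unclass(got), want, tolerance = 1e-12)
  }
  # a larger random instance, tau != 1
  expr2 <- matrix(rnorm(20 * 6), nrow = 20,
                  dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  got2 <- gsva_scores(expr2, paste0("g", c(3, 7, 11)), tau = 0.5)
  want2 <- oracle_gsva(expr2, paste0("g", c(3, 7, 11)), tau = 0.5)
  expect_equal(unclass(got2), want2, tolerance = 1e-12)
})

test_that("identical samples receive identical scores", {
  expr <- matrix(rnorm(10), nrow = 10, ncol = 3,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  sc <- gsva_scores(expr, c("g1", "g2", "g3"))
  expect_equal(sc[["s1"]], sc[["s2"]])
  expect_equal(sc[["s1"]], sc[["s3"]])
})

test_that("up-shifting one sample's signature genes raises its score", {
  set.seed(7)
  expr <- matrix(rnorm(30 * 8), nrow = 30,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  set_genes <- paste0("g", 1:5)
  base <- gsva_scores(expr, set_genes)
  expr2 <- expr
  expr2[set_genes, "s1"] <- expr2[set_genes, "s1"] + 3
  shifted <- gsva_scores(expr2, set_genes)
  expect_gt(shifted[["s1"]], base[["s1"]])
})

test_that("scores track the planted latent activity", {
  sim <- simulate_expression_cohort(
    cohort_sim_config(seed = 17, n_samples = 60, n_genes = 300,
                      signature_size = 20)
  )
  sc <- gsva_scores(sim$expr, sim$signature_genes)
  rho <- spearman_cor(sc, sim$latent[names(sc)])$rho
  expect_gte(rho, 0.8)
})

test_that("scoring requires enough signature genes in the matrix", {
  expr <- matrix(rnorm(12), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_error(gsva_scores(expr, c("g1", "missing1", "missing2")), "missing")
})

test_that("preranked enrichment matches the hand running sum", {
  scores <- c(a = 3, b = 2, c = 1, d = -1, e = -2, f = -3)
  # set = top 2: up steps 3/5 then 2/5, down steps 1/4
  res <- preranked_gsea(scores, c("a", "b"), p = 1, n_perm = 100, seed = 1)
  expect_equal(res$es, 1)  # walk peaks at 1 after both hits
  expect_equal(res$es, oracle_gsea_es(scores, c("a", "b")))
  # a set at the bottom scores negatively, mirrored by the oracle
  res2 <- preranked_gsea(scores, c("e", "f"), p = 1, n_perm = 100, seed = 1)
  expect_lt(res2$es, 0)
  expect_equal(res2$es, oracle_gsea_es(scores, c("e", "f")))
  # an interior set traced by hand: hit at ranks 2 and 4, weight p = 1
  res3 <- preranked_gsea(scores, c("b", "d"), p = 1, n_perm = 100, seed = 1)
  expect_equal(res3$es, oracle_gsea_es(scores, c("b", "d")))
  # whole list as the set: no miss steps, ES = 1
  res4 <- preranked_gsea(scores, names(scores), n_perm = 10, seed = 1)
  expect_equal(res4$es, 1)
  expect_error(preranked_gsea(scores, c("zz")), "disjoint")
})

test_that("enrichment score is bounded and reversing the list negates it", {
  set.seed(3)
  for (i in 1:20) {
    scores <- sort(rnorm(50), decreasing = TRUE)
    names(scores) <- paste0("g", 1:50)
    set <- sample(names(scores), 8)
    es <- preranked_gsea(scores, set, n_perm = 10, seed = i)$es
    expect_lte(abs(es), 1)
    rev_scores <- -scores
    es_rev <- preranked_gsea(rev_scores, set, n_perm = 10, seed = i)$es
    expect_equal(es_rev, -es, tolerance = 1e-12)
  }
})

test_that("set and sample level enrichment agree qualitatively", {
  set.seed(21)
  n_a <- 6; n_b <- 6
  expr <- matrix(rnorm(40 * 12), nrow = 40,
                 dimnames = list(paste0("g", 1:40),
                                 c(paste0("a", 1:n_a), paste0("b", 1:n_b))))
  set_genes <- paste0("g", 1:6)
  expr[set_genes, 1:n_a] <- expr[set_genes, 1:n_a] + 2  # up in group A
  sc <- gsva_scores(expr, set_genes)
  expect_gt(mean(sc[1:n_a]) - mean(sc[n_a + 1:n_b]), 0)
  # ranked list by A-vs-B difference
  diff <- rowMeans(expr[, 1:n_a]) - rowMeans(expr[, n_a + 1:n_b])
  es <- preranked_gsea(diff, set_genes, n_perm = 50, seed = 2)$es
  expect_gt(es, 0)
})
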