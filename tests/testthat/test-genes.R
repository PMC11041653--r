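test_that("variant-to-gene assignment respects boundaries and windows", {
  v <- data.frame(variant_id = c("a", "b", "c"), chrom = "1",
                  pos_bp = c(1000L, 2000L, 2001L),
                  allele_effect = "A", allele_other = "G")
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                  start_bp = c(1000L, 1500L), end_bp = c(2000L, 2500L))
  m <- map_snps_to_genes(v, g)
  expect_equal(m$g1, c(1L, 2L))       # pos == start and pos == end assigned
  expect_equal(m$g2, c(2L, 3L))       # overlapping genes share variant b
  m0 <- map_snps_to_genes(v, data.frame(gene_id = "g3", chrom = "1",
                                        start_bp = 1L, end_bp = 999L))
  expect_length(m0$g3, 0L)            # 1 bp past the end is out
  mw <- map_snps_to_genes(v, data.frame(gene_id = "g3", chrom = "1",
                                        start_bp = 1L, end_bp = 999L),
                          window_down_bp = 1L)
  expect_equal(mw$g3, 1L)
})

test_that("a single-variant gene reduces to the per-variant linear test", {
  set.seed(1)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  X <- cbind(rnorm(n))
  y <- 0.3 * g + rnorm(n)
  gt <- gene_test(y, matrix(g, ncol = 1), X)
  lt <- assoc_linear(y, g, X)
  expect_equal(gt$p, lt$p, tolerance = 1e-10)

  ## duplicated identical variants: rank deficiency absorbed, same p
  gt2 <- gene_test(y, cbind(g, g), X)
  expect_equal(gt2$p, gt$p, tolerance = 1e-10)
  expect_equal(gt2$n_components, 1L)

  ## variant order within the gene is irrelevant
  sim <- tiny_cohort(seed = 2, n = 200, m = 10, blocks = 2)
  yy <- rnorm(200)
  pa <- gene_test(yy, sim$G[, 1:5])$p
  pb <- gene_test(yy, sim$G[, 5:1])$p
  expect_equal(pa, pb, tolerance = 1e-10)

  expect_equal(gene_test(yy, matrix(1, 200, 1))$flag, "no_usable_variants")
})

test_that("gene selection applies a strict threshold over outcome scans", {
  s1 <- data.frame(gene_id = c("a", "b", "c"), p = c(0.0005, 0.001, 0.5))
  s2 <- data.frame(gene_id = c("a", "d"), p = c(0.9, 0.0002))
  expect_equal(select_genes(s1, s2, p_threshold = 0.001), c("a", "d"))
  expect_equal(select_genes(s1, p_threshold = 1.0), c("a", "b", "c"))
  ## p exactly at the threshold is excluded
  expect_false("b" %in% select_genes(s1, p_threshold = 0.001))
})

test_that("a gene carrying concentrated signal is selected", {
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    sim <- tiny_cohort(seed = 100 + s, n = 500, m = 40, blocks = 8,
                       h2_liability = 0)
    y <- drop(1.0 * scale(sim$G[, 13]) + rnorm(500, 0, 1))
    genes <- data.frame(gene_id = sprintf("g%02d", 1:8), chrom = "1",
                        start_bp = seq(1, 40, 5) * 1000L,
                        end_bp = seq(5, 40, 5) * 1000L)
    scan <- run_gene_scan(sim$G, sim$variants, genes, y)
    "g03" %in% select_genes(scan, p_threshold = 0.001)
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  ref <- sprintf("G%04d", 1:1000)
  paths <- list(pw = ref[1:10])
  input <- c(ref[1:5], ref[101:115])  # k=5 of K=10, n=20
  res <- fisher_enrichment(input, paths, ref)
  expect_equal(res$p_fisher, fisher_oracle(5, 10, 20, 1000),
               tolerance = 1e-12)
  ## and equals R's own one-sided Fisher test (independent route)
  ft <- fisher.test(matrix(c(5, 15, 5, 975), 2), alternative = "greater")
  expect_equal(res$p_fisher, ft$p.value, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, res$p_fisher)  # single pathway, m = 1

  ## pathway identical to the input set is the best hit
  paths2 <- list(self = input, other = ref[301:350], pw = ref[1:10])
  res2 <- fisher_enrichment(input, paths2, ref)
  expect_equal(res2$pathway[1], "self")
  ## bonferroni never decreases p and counts is bounded by m * p
  expect_true(all(res2$p_bonferroni >= res2$p_fisher))
  expect_equal(res2$p_bonferroni,
               pmin(1, res2$p_fisher * 3), tolerance = 1e-12)

  ## invariance under relabeling of non-input reference genes
  ref_rl <- c(ref[1:120], sprintf("X%04d", 121:1000))
  res3 <- fisher_enrichment(input, paths, ref_rl)
  expect_equal(res3$p_fisher, res$p_fisher, tolerance = 1e-12)

  expect_error(fisher_enrichment(character(0), paths, ref), "empty")
  expect_error(fisher_enrichment("nope", paths, ref), "outside")
})
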