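test_that("exact HWE test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)  # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  p_allhet <- hwe_exact_test(0, 100, 0)
  expect_equal(p_allhet, hwe_oracle(0, 100, 0), tolerance = 1e-12)
  expect_lt(p_allhet, 1e-6)
  expect_true(is.na(hwe_exact_test(0, 0, 0)))

  ## property: random tables up to n = 200 agree to 1e-12
  set.seed(42)
  for (i in 1:60) {
    n <- sample(1:200, 1)
    cc <- as.vector(stats::rmultinom(1, n, prob = runif(3)))
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 hwe_oracle(cc[1], cc[2], cc[3]), tolerance = 1e-12)
  }
})

test_that("pre-imputation variant filters apply the four rules in order", {
  sim <- tiny_cohort(seed = 7, n = 100, m = 20, blocks = 4)
  G <- round(sim$G)
  v <- sim$variants
  ## plant violations
  v$allele_effect[1] <- "A"; v$allele_other[1] <- "T"      # ambiguous
  G[, 2] <- c(rep(0, 99), 1)                               # MAF 0.005
  G[, 3] <- rep(c(2, 0), 50)                               # HWE (50,0,50)
  G[1:10, 4] <- NA                                         # call rate 0.90
  res <- filter_variants_pre(G, v)
  kept <- res$variants$variant_id
  expect_false(any(v$variant_id[1:4] %in% kept))
  expect_equal(ncol(res$G), nrow(res$variants))
  ## report reconciles with shapes and attributes steps in order
  expect_equal(sum(res$report$steps$removed), ncol(G) - ncol(res$G))
  expect_identical(res$report$steps$filter,
                   c("variant_call_rate", "strand_ambiguity", "maf",
                     "hwe_exact"))
  expect_equal(res$report$steps$removed, c(1L, 1L, 1L, 1L))

  ## kept set invariant to filter attribution order: rerun without the
  ## ambiguity filter removes only that rule
  res2 <- filter_variants_pre(G, v, drop_ambiguous = FALSE)
  expect_setequal(setdiff(res2$variants$variant_id, kept), v$variant_id[1])
})

test_that("boundary MAF/HWE values are kept (inclusive thresholds)", {
  ## MAF exactly 0.01 at n = 100 haplotype counts: 2 alt alleles
  G <- matrix(c(rep(0, 98), 1, 1), ncol = 1)
  v <- data.frame(variant_id = "v1", chrom = "1", pos_bp = 1L,
                  allele_effect = "A", allele_other = "G", maf = NA,
                  info_r2 = NA)
  expect_equal(nrow(filter_variants_pre(G, v)$variants), 1L)
})

test_that("sample filters remove duplicates, sex mismatches, low call rate", {
  sim <- tiny_cohort(seed = 8, n = 40, m = 600, blocks = 60)
  G <- sim$G
  G[2, ] <- G[1, ]                      # duplicate pair (kinship ~ 0.5)
  G[5, 1:400] <- NA                     # call rate 200/600
  ph <- sim$phenos
  ph$genetic_sex[7] <- setdiff(c("female", "male"), ph$sex[7])
  res <- filter_samples(G, sim$samples, ph)
  expect_false(sim$samples[5] %in% res$samples)
  expect_false(sim$samples[7] %in% res$samples)
  ## exactly one of the duplicated pair dropped (tie -> later id removed)
  expect_equal(sum(c(sim$samples[1], sim$samples[2]) %in% res$samples), 1L)
  expect_true(sim$samples[1] %in% res$samples)
  expect_equal(nrow(res$G), length(res$samples))

  ## clean matrix passes untouched (enough markers that kinship noise
  ## stays well below the 0.125 threshold)
  simc <- tiny_cohort(seed = 81, n = 40, m = 600, blocks = 60)
  clean <- filter_samples(simc$G, simc$samples, simc$phenos)
  expect_identical(clean$samples, simc$samples)
})

test_that("post-imputation filters use inclusive MAF/info boundaries", {
  v <- data.frame(variant_id = paste0("v", 1:4), chrom = "1",
                  pos_bp = 1:4, allele_effect = "A", allele_other = "G",
                  maf = c(0.10, 0.08, 0.30, 0.30),
                  info_r2 = c(0.6, 0.9, 0.5, 0.95))
  res <- filter_variants_post(v)
  expect_identical(res$variants$variant_id, c("v1", "v4"))
  expect_equal(sum(res$report$steps$removed), 2L)
  v$info_r2 <- NA_real_
  expect_error(filter_variants_post(v), "info_r2")
})

test_that("cohort merge intersects, drops mismatches and flips alleles", {
  sim <- tiny_cohort(seed = 9, n = 30, m = 10, blocks = 2)
  G1 <- round(sim$G); v1 <- sim$variants
  ## cohort 2: variants 3..7 shared, one with swapped allele labels, one
  ## with a different allele pair at the same position
  idx <- 3:7
  G2 <- G1[1:10, idx, drop = FALSE]
  v2 <- v1[idx, ]
  v2$allele_effect[2] <- v1$allele_other[idx[2]]
  v2$allele_other[2] <- v1$allele_effect[idx[2]]
  G2[, 2] <- 2 - G2[, 2]
  v2$allele_effect[4] <- "A"; v2$allele_other[4] <- "G"
  v1$allele_effect[idx[4]] <- "T"; v1$allele_other[idx[4]] <- "C"
  s2 <- paste0("dup_", sim$samples[1:10])
  res <- merge_cohorts(list(
    list(G = G1, variants = v1, samples = sim$samples),
    list(G = G2, variants = v2, samples = s2)))
  expect_equal(nrow(res$variants), 4L)   # 5 shared - 1 allele mismatch
  expect_equal(nrow(res$G), 40L)
  ## duplicated samples are perfectly concordant after the flip
  for (j in seq_len(ncol(res$G))) {
    expect_equal(unname(res$G[1:10, j]), unname(res$G[31:40, j]))
  }
  expect_error(merge_cohorts(list(
    list(G = G1[, 1:2], variants = v1[1:2, ], samples = sim$samples),
    list(G = G1[, 9:10], variants = v1[9:10, ], samples = s2))),
    "no common variants")
})
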