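test_that("configuration invariants are enforced", {
  expect_error(sim_config(seed = 1, n_variants = 100, n_blocks = 7),
               "divisible")
  expect_error(sim_config(seed = 1, maf_range = c(0.05, 0.3)), "maf_range")
  expect_error(sim_config(seed = 1, fst = 0.5), "fst")
  expect_error(sim_config(n_samples = 10), "seed")
})

test_that("LD is block-structured: adjacent within-block correlation
           dominates between-block correlation", {
  cfg <- sim_config(n_samples = 500, n_variants = 200, n_blocks = 20,
                    block_rho = 0.8, fst = 0.05, seed = 1)
  sim <- simulate_genotypes(cfg)
  X <- scale(sim$G)
  blk <- sim$variants$block
  within <- vapply(seq_len(199), function(j) {
    if (blk[j] == blk[j + 1]) abs(cor(X[, j], X[, j + 1])) else NA_real_
  }, numeric(1))
  ## one representative variant per block, against the next block's
  between <- abs(diag(cor(X[, seq(5, 195, 10)], X[, seq(15, 195, 10)])))
  expect_gt(mean(within, na.rm = TRUE), mean(between) + 0.2)
  expect_lt(mean(between), 0.1)
})

test_that("zero divergence gives equal population frequencies", {
  cfg <- sim_config(n_samples = 1000, n_variants = 100, n_blocks = 10,
                    fst = 0, seed = 2)
  sim <- simulate_genotypes(cfg)
  f1 <- colMeans(sim$G[sim$pop == 1, ]) / 2
  f2 <- colMeans(sim$G[sim$pop == 2, ]) / 2
  ## equal generating frequencies; only sampling noise remains
  expect_identical(sim$freq_pop[, 1], sim$freq_pop[, 2])
  expect_lt(max(abs(f1 - f2)), 0.12)
})

test_that("the generator is deterministic in the seed", {
  cfg <- sim_config(n_samples = 50, n_variants = 40, n_blocks = 8, seed = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$G, b$G)
  expect_identical(a$phenos, b$phenos)
  c <- simulate_cohort(sim_config(n_samples = 50, n_variants = 40,
                                  n_blocks = 8, seed = 4))
  expect_false(identical(a$G, c$G))
})

test_that("empirical MAF stays near the configured range", {
  cfg <- sim_config(n_samples = 800, n_variants = 200, n_blocks = 20,
                    maf_range = c(0.15, 0.45), fst = 0.05, seed = 5)
  sim <- simulate_genotypes(cfg)
  expect_true(all(sim$variants$maf >= 0.15 - 0.03))
  expect_true(all(sim$variants$maf <= 0.45 + 0.03))
})

test_that("phenotypes are calibrated to the cohort's demographics", {
  cfg <- sim_config(n_samples = 2000, n_variants = 100, n_blocks = 10,
                    target_responder_rate = 0.279, seed = 7)
  sim <- simulate_cohort(cfg)
  ph <- sim$phenos
  resp <- mean(compute_alda_total(ph$alda_a,
                                  ph[, paste0("alda_b", 1:5)]) >= 7)
  expect_gte(resp, 0.249)
  expect_lte(resp, 0.309)
  expect_lt(abs(mean(ph$age_years) - 47.5), 1.0)
  expect_true(all(ph$age_years >= 18 & ph$age_years <= 90))
  expect_gt(mean(ph$sex == "female"), 0.53)
  expect_lt(mean(ph$sex == "female"), 0.63)
  expect_gt(mean(ph$months_on_lithium >= 6), 0.92)
  for (b in paste0("alda_b", 1:5)) {
    expect_true(all(ph[[b]] %in% 0:2))
  }
})

test_that("the fixture bundle round-trips through the readers", {
  outdir <- withr::local_tempdir()
  cfg <- sim_config(n_samples = 40, n_variants = 50, n_blocks = 10,
                    seed = 8)
  sim <- expect_no_warning(write_fixture_bundle(cfg, outdir))
  geno <- expect_no_warning(
    read_genotypes(file.path(outdir, "genotypes"), "plink1"))
  ph <- expect_no_warning(
    read_phenotypes(file.path(outdir, "phenotypes.tsv")))
  genes <- read_gene_annotation(file.path(outdir, "genes.tsv"))
  paths <- read_gmt(file.path(outdir, "pathways.gmt"))
  expect_equal(dim(geno$G), c(40L, 50L))
  expect_equal(nrow(ph), 40L)
  expect_equal(nrow(genes), 10L)

  ## every gene in causal_set contains a causal variant, by construction
  amap <- map_snps_to_genes(geno$variants, genes)
  causal_ids <- geno$variants$variant_id[sim$causal]
  frac <- mean(vapply(paths$causal_set, function(g) {
    any(geno$variants$variant_id[amap[[g]]] %in% causal_ids)
  }, logical(1)))
  expect_gte(frac, 0.8)

  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_equal(manifest$seed, 8L)

  ## byte-identical reproducibility of the whole bundle
  outdir2 <- withr::local_tempdir()
  write_fixture_bundle(cfg, outdir2)
  for (f in list.files(outdir)) {
    expect_identical(readBin(file.path(outdir, f), "raw", 1e6),
                     readBin(file.path(outdir2, f), "raw", 1e6),
                     label = f)
  }
})
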