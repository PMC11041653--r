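test_that("GIG sampler matches numerically integrated moments", {
  moments <- function(lambda, chi, psi) {
    f <- function(t) t^(lambda - 1) * exp(-(chi / t + psi * t) / 2)
    z <- integrate(f, 0, Inf)$value
    c(m1 = integrate(function(t) t * f(t), 0, Inf)$value / z,
      m2 = integrate(function(t) t^2 * f(t), 0, Inf)$value / z)
  }
  set.seed(1)
  for (par in list(c(0.5, 2, 3), c(-0.5, 1.5, 0.7), c(1.7, 2, 3),
                   c(0.5, 1e-4, 5))) {
    x <- rgig(40000, par[1], par[2], par[3])
    m <- moments(par[1], par[2], par[3])
    expect_equal(mean(x), m[["m1"]], tolerance = 0.03)
    expect_equal(mean(x^2), m[["m2"]], tolerance = 0.06)
  }
  ## chi = 0 boundary is a gamma draw
  set.seed(2)
  x0 <- rgig(40000, 0.5, 0, 4)
  expect_equal(mean(x0), 0.5 / (4 / 2), tolerance = 0.02)
})

test_that("LD blocks have unit diagonals, floors and structure", {
  b1 <- build_ld_blocks(matrix(rbinom(40, 2, 0.4), ncol = 1), 1L)
  expect_equal(b1[[1]]$R, matrix(1, 1, 1))

  ## duplicated variant: off-diagonal 1 before flooring, PSD after
  g <- rbinom(50, 2, 0.4)
  Gdup <- cbind(g, g)
  bd <- build_ld_blocks(Gdup, c(1L, 1L))
  ev <- eigen(bd[[1]]$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-3 - 1e-9)
  expect_equal(unname(diag(bd[[1]]$R)), c(1, 1), tolerance = 1e-12)

  ## AR(1) fixture: mean adjacent dosage correlation near the latent rho,
  ## attenuated by the double thresholding
  sim <- tiny_cohort(seed = 20, n = 2000, m = 50, blocks = 5,
                     block_rho = 0.8, fst = 0)
  bl <- build_ld_blocks(sim$G, sim$variants$block)
  adj <- unlist(lapply(bl, function(b) {
    R <- b$R
    R[cbind(seq_len(nrow(R) - 1), seq_len(nrow(R) - 1) + 1)]
  }))
  expect_gt(mean(adj), 0.45)
  expect_lt(mean(adj), 0.85)

  Gz <- cbind(rbinom(30, 2, 0.3), rep(2, 30))
  colnames(Gz) <- c("a", "bad")
  expect_error(build_ld_blocks(Gz, c(1L, 1L)), "bad")
})

test_that("standardized betas follow z / sqrt(n)", {
  st <- data.frame(z = c(0, 5, -3, NA), n = c(100, 2500, 400, 900))
  b <- standardize_betas(st)
  expect_equal(b, c(0, 0.1, -0.15, 0))
  expect_error(standardize_betas(data.frame(z = 1, n = NA)), "missing n")
  ## sign is preserved
  expect_identical(sign(b[2:3]), sign(st$z[2:3]))
})

test_that("null summary statistics give posterior means near zero", {
  sim <- tiny_cohort(seed = 21, n = 200, m = 40, blocks = 8)
  blocks <- build_ld_blocks(sim$G, sim$variants$block)
  prm <- cs_prior_params(n_iter = 400, n_burnin = 100, thin = 2, seed = 3)
  eff <- gibbs_cs(rep(0, 40), blocks, n_gwas = 1000, params = prm)
  ## 3 Monte-Carlo SEs of zero; posterior sd <= sqrt(sigma2/N) * small
  mc_se <- 1 / sqrt(1000) / sqrt(150)
  expect_true(all(abs(eff$effect_mean) < 30 * mc_se))
  expect_lt(mean(abs(eff$effect_mean)), 3 / sqrt(1000))
})

test_that("conjugate sub-cases match closed forms", {
  res <- experiment_conjugate_shrinkage(seed = 4)
  expect_equal(res$shrinkage, res$expected, tolerance = 4 * res$mc_se)

  ## two-variant block with psi, sigma2, phi all fixed: posterior mean is
  ## the closed-form generalized-ridge solution
  R <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  blocks <- structure(list(list(idx = 1:2, R = R)), class = "ld_blocks")
  bhat <- c(0.05, -0.02)
  N <- 800; c_fix <- 0.01
  prm <- cs_prior_params(phi = 1, n_iter = 8000, n_burnin = 1000,
                         thin = 1, seed = 5)
  eff <- gibbs_cs(bhat, blocks, n_gwas = N, params = prm,
                  fix_psi = c_fix, fix_sigma2 = 1)
  closed <- solve(R + diag(1 / (N * c_fix), 2), bhat)
  expect_lt(max(abs(eff$effect_mean - closed)), 0.003)
})

test_that("smaller fixed phi shrinks harder, never less", {
  sim <- tiny_cohort(seed = 22, n = 300, m = 40, blocks = 8,
                     h2_liability = 0.4)
  y <- as.numeric(scale(sim$liability))
  st <- run_gwas(sim$G, sim$variants, y, NULL, "continuous")
  bstd <- standardize_betas(st)
  blocks <- build_ld_blocks(sim$G, sim$variants$block)
  totals <- vapply(c(1e-4, 1e-2, 1), function(phi) {
    prm <- cs_prior_params(phi = phi, n_iter = 300, n_burnin = 100,
                           thin = 2, seed = 6)
    sum(abs(gibbs_cs(bstd, blocks, n_gwas = 300,
                     params = prm)$effect_mean))
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("scoring is linear, allele-aware and sign-symmetric", {
  sim <- tiny_cohort(seed = 23, n = 50, m = 10, blocks = 2)
  v <- sim$variants
  eff0 <- data.frame(variant_id = v$variant_id, allele_effect =
                       v$allele_effect, effect_mean = 0)
  expect_equal(unname(score_individuals(sim$G, v, eff0)), rep(0, 50))

  w <- rnorm(10) / 10
  eff <- transform(eff0, effect_mean = w)
  manual <- unname(drop(scale(sim$G) %*% w))
  expect_equal(unname(score_individuals(sim$G, v, eff)), manual,
               tolerance = 1e-12)

  ## flipping every recorded effect allele negates the scores exactly
  eff_fl <- data.frame(variant_id = v$variant_id,
                       allele_effect = v$allele_other, effect_mean = w)
  expect_equal(unname(score_individuals(sim$G, v, eff_fl)), -manual,
               tolerance = 1e-12)

  expect_error(score_individuals(sim$G, v,
                                 transform(eff, variant_id = paste0("x",
                                                                    1:10))),
               "no overlap")
})

test_that("fold assignment is balanced, seeded and stratifiable", {
  f <- make_folds(2367, 5, seed = 1)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(474L, 474L, 473L, 473L, 473L))
  expect_identical(f, make_folds(2367, 5, seed = 1))
  expect_false(identical(f, make_folds(2367, 5, seed = 2)))
  ## discovery complements are the 80% splits
  expect_setequal(2367 - as.integer(table(f)), c(1893L, 1894L))

  y <- rep(c(1, 0), c(20, 80))
  fs <- make_folds(100, 5, seed = 3, strata = y)
  tab <- table(fs, y)
  expect_true(all(tab[, "1"] == 4))
})

test_that("cross-fitting scores every sample once, out of fold, and is
           deterministic", {
  sim <- tiny_cohort(seed = 24, n = 150, m = 40, blocks = 8,
                     h2_liability = 0.3)
  y <- as.numeric(scale(sim$liability))
  blocks <- build_ld_blocks(sim$G, sim$variants$block)
  prm <- cs_prior_params(n_iter = 60, n_burnin = 20, thin = 2, seed = 7)
  cf <- log_crossfit(sim$G, sim$variants, y, NULL, blocks, prm, k = 5,
                     seed = 7, outcome_type = "continuous")
  expect_equal(nrow(cf), 150L)
  expect_false(anyNA(cf$pgs))
  expect_equal(sort(unique(cf$fold)), 1:5)
  expect_equal(mean(cf$pgs), 0, tolerance = 1e-12)
  expect_equal(sd(cf$pgs), 1, tolerance = 1e-12)
  cf2 <- log_crossfit(sim$G, sim$variants, y, NULL, blocks, prm, k = 5,
                      seed = 7, outcome_type = "continuous")
  expect_identical(cf, cf2)

  ## losing an outcome class in a fold is caught with advice
  yy <- rep("poor", 150); yy[1] <- "good"
  expect_error(log_crossfit(sim$G, sim$variants, yy, NULL, blocks, prm,
                            k = 5, seed = 7), "stratified")
})

test_that("external scoring tracks the cross-fitted score on heritable
           data and is deterministic", {
  cfg <- sim_config(n_samples = 1500, n_variants = 200, n_blocks = 20,
                    h2_liability = 0.3, seed = 17)
  sim <- simulate_cohort(cfg)
  y <- as.numeric(scale(sim$liability))
  blocks <- build_ld_blocks(sim$G, sim$variants$block)
  prm <- cs_prior_params(n_iter = 200, n_burnin = 80, thin = 2, seed = 5)
  cf <- log_crossfit(sim$G, sim$variants, y, NULL, blocks, prm, k = 5,
                     seed = 5, outcome_type = "continuous")
  st <- run_gwas(sim$G, sim$variants, y, NULL, "continuous")
  ext <- external_score(st, blocks, prm, sim$G, sim$variants)
  expect_gt(cor(ext$pgs, cf$pgs), 0.9)
  ext2 <- external_score(st, blocks, prm, sim$G, sim$variants)
  expect_identical(ext$pgs, ext2$pgs)
  expect_error(external_score(st, blocks, prm, sim$G[0, ], sim$variants),
               "empty target")
})

test_that("cross-fitted scores recover heritable signal across seeds", {
  rec <- experiment_pgs_recovery(n_seeds = 5, n = 800, m = 200, seed = 30)
  expect_gte(rec$n_positive, 4L)
  expect_gt(rec$mean_cor, 0.05)
})

test_that("heritability knob is monotone in recovered signal", {
  cors <- vapply(c(0, 0.1, 0.3), function(h2) {
    mean(experiment_pgs_recovery(n_seeds = 3, n = 600, m = 100, h2 = h2,
                                 seed = 40)$correlations)
  }, numeric(1))
  expect_true(all(diff(cors) > -0.05))  # nondecreasing up to noise
  expect_gt(cors[3], cors[1])
})
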