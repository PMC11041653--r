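test_that("linear engine matches exact fits and closed forms", {
  set.seed(10)
  g <- rbinom(50, 2, 0.4)
  r <- assoc_linear(2 * g, g)
  expect_equal(r$beta, 2, tolerance = 1e-10)
  expect_lt(r$p, 1e-12)

  y <- rnorm(50)
  r2 <- assoc_linear(y, g)
  expect_equal(r2$beta, cov(g, y) / var(g), tolerance = 1e-10)

  const <- assoc_linear(y, rep(1, 50))
  expect_equal(const$beta, 0)
  expect_equal(const$p, 1)
  expect_equal(const$flag, "degenerate")
})

test_that("logistic engine reproduces the 2x2 cross-product odds ratio", {
  g <- rep(c(1, 0), c(100, 100))
  y <- c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85))
  r <- assoc_logistic(y, g)
  expect_equal(exp(r$beta), (30 * 85) / (70 * 15), tolerance = 1e-6)
  ## se agrees with the Woolf formula for a saturated 2x2
  expect_equal(r$se, sqrt(1/30 + 1/70 + 1/15 + 1/85), tolerance = 1e-6)

  expect_equal(assoc_logistic(y, rep(1, 200))$flag, "degenerate")
  sep <- assoc_logistic(y = c(rep(0, 20), rep(1, 20)),
                        g = c(rep(0, 20), rep(2, 20)))
  expect_equal(sep$flag, "separation")
  expect_true(is.na(sep$p))
})

test_that("both engines agree with glm on random small datasets", {
  set.seed(11)
  for (i in 1:5) {
    n <- 80
    g <- rbinom(n, 2, runif(1, 0.2, 0.5))
    X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    yb <- rbinom(n, 1, plogis(-0.5 + 0.3 * g + 0.2 * X[, 1]))
    yc <- 0.4 * g + X %*% c(0.3, -0.2) + rnorm(n)
    rl <- assoc_logistic(yb, g, X)
    gl <- glm(yb ~ g + X, family = binomial())
    expect_equal(rl$beta, unname(coef(gl)["g"]), tolerance = 1e-6)
    expect_equal(rl$se, unname(sqrt(diag(vcov(gl)))["g"]), tolerance = 1e-5)
    rn <- assoc_linear(drop(yc), g, X)
    ln <- lm(yc ~ g + X)
    expect_equal(rn$beta, unname(coef(ln)["g"]), tolerance = 1e-8)
    expect_equal(rn$p, summary(ln)$coefficients["g", 4], tolerance = 1e-8)
  }
})

test_that("a covariate orthogonal to dosage and outcome leaves beta alone", {
  set.seed(12)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  y <- 0.5 * g + rnorm(n)
  v <- rnorm(n)
  v_orth <- residuals(lm(v ~ g + y))  # orthogonal to both by construction
  b0 <- assoc_linear(y, g)$beta
  b1 <- assoc_linear(y, g, cbind(v_orth))$beta
  expect_equal(b0, b1, tolerance = 1e-8)
})

test_that("the scan returns one flagged-or-fitted row per variant", {
  sim <- tiny_cohort(seed = 13, n = 150, m = 20, blocks = 4)
  y <- binary_outcome_of(sim)
  G <- sim$G
  G[, 5] <- 1  # constant
  st <- run_gwas(G, sim$variants, y, NULL, "binary")
  expect_equal(nrow(st), 20L)
  expect_equal(st$flag[5], "degenerate")
  ok <- st$flag == "ok"
  expect_equal(st$z[ok], st$beta[ok] / st$se[ok])
  expect_true(all(st$n == 150L))
  expect_error(run_gwas(G[, 0], sim$variants[0, ], y, NULL, "binary"),
               "zero variants")
})

test_that("a planted causal variant attains the scan minimum p", {
  set.seed(14)
  sim <- tiny_cohort(seed = 14, n = 400, m = 40, blocks = 8,
                     h2_liability = 0)
  g <- sim$G[, 17]
  y <- 1.2 * scale(g) + rnorm(400, 0, 0.8)
  st <- run_gwas(sim$G, sim$variants, drop(y), NULL, "continuous")
  expect_equal(which.min(st$p), 17L)
})

test_that("PC1 separates populations under divergence and not without", {
  sim <- tiny_cohort(seed = 15, n = 300, m = 300, blocks = 30, fst = 0.05)
  pcs <- compute_pcs(sim$G, k = 4)
  expect_gt(abs(cor(pcs[, 1], sim$pop)), 0.8)
  expect_equal(apply(pcs, 2, sd), rep(1, 4),
               tolerance = 1e-8, ignore_attr = TRUE)

  sim0 <- tiny_cohort(seed = 16, n = 300, m = 300, blocks = 30, fst = 0)
  pcs0 <- compute_pcs(sim0$G, k = 2)
  expect_lt(abs(cor(pcs0[, 1], sim0$pop)), 0.2)

  expect_equal(ncol(compute_pcs(sim$G, k = 0)), 0L)
  expect_error(compute_pcs(sim$G[1:5, ], k = 10), "rank")
})

test_that("covariate builder drops incomplete rows and reference levels", {
  ph <- tiny_cohort(seed = 17, n = 20, m = 5, blocks = 5)$phenos
  ph$age_years[3] <- NA
  cov <- build_covariates(ph, include_chip = TRUE)
  expect_equal(cov$n_dropped, 1L)
  expect_false(3 %in% cov$rows)
  expect_true("chip_chipB" %in% colnames(cov$X))
  expect_false("chip_chipA" %in% colnames(cov$X))
  cov2 <- build_covariates(ph, include_chip = FALSE)
  expect_identical(colnames(cov2$X), c("age_years", "sex_female"))
})
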