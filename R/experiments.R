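## Packaged simulation studies: the validation experiments that establish
## the statistical properties of the pipeline (cross-fitting removes
## discovery-target circularity, the Tobit recovers censored slopes that
## OLS attenuates, the shrinkage sampler matches its conjugate closed form
## and improves on raw marginal estimates, and the scan engines are
## calibrated under the null). Each experiment is seeded and returns the
## measured quantities; tests and the acceptance script assert on them.

.default_chain <- function(seed) {
  cs_prior_params(n_iter = 100L, n_burnin = 40L, thin = 2L, seed = seed)
}

.sim_binary_outcome <- function(sim) {
  classify_response(compute_alda_total(
    sim$phenos$alda_a, sim$phenos[, paste0("alda_b", 1:5)]))
}

#' Circularity-control experiment
#'
#' On replicated null cohorts (zero heritability), compares the rejection
#' rate at \code{alpha} of the PGS-response association when the PGS is
#' cross-fitted (leave-one-group-out; each sample scored by weights
#' estimated without it) versus deliberately circular (discovery = full
#' cohort, scored on itself). A calibrated cross-fit rejects at about
#' \code{alpha}; the circular score rejects far more often.
#'
#' @param n_rep number of replicate cohorts.
#' @param n,m cohort size and variant count per replicate.
#' @param seed base seed (replicate r uses \code{seed + r}).
#' @param alpha test level.
#' @return list \code{log_rate}, \code{insample_rate}, \code{n_rep},
#'   \code{p_log}, \code{p_insample}.
#' @export
experiment_circularity <- function(n_rep = 200L, n = 400L, m = 200L, seed,
                                   alpha = 0.05) {
  p_log <- numeric(n_rep)
  p_ins <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_samples = n, n_variants = m, n_blocks = m %/% 10L,
                      h2_liability = 0, seed = seed + r)
    sim <- simulate_cohort(cfg)
    y <- .sim_binary_outcome(sim)
    blocks <- build_ld_blocks(sim$G, sim$variants$block)
    prm <- .default_chain(seed + r)

    cf <- log_crossfit(sim$G, sim$variants, y, NULL, blocks, prm,
                       k = 5L, seed = seed + r)
    p_log[r] <- fit_logistic_pgs(cf$pgs, y)$p

    st <- run_gwas(sim$G, sim$variants, y, NULL, "binary")
    eff <- gibbs_cs(standardize_betas(st), blocks, n_gwas = n, params = prm,
                    variant_id = sim$variants$variant_id,
                    allele_effect = sim$variants$allele_effect)
    pgs_ins <- as.numeric(scale(score_individuals(sim$G, sim$variants,
                                                  eff)))
    p_ins[r] <- fit_logistic_pgs(pgs_ins, y)$p
  }
  list(log_rate = mean(p_log < alpha),
       insample_rate = mean(p_ins < alpha),
       n_rep = n_rep, p_log = p_log, p_insample = p_ins)
}

#' Tobit parameter-recovery experiment
#'
#' Generates \code{y* = 1 + 0.8 x + N(0, 1.5)} clipped to [0, 10] with
#' roughly a quarter of observations at the bounds, fits the two-limit
#' Tobit and plain OLS, and returns both slopes and the estimated scale.
#'
#' @param n sample size.
#' @param seed RNG seed.
#' @return list \code{slope}, \code{sigma}, \code{ols_slope},
#'   \code{censored_fraction}, \code{n}.
#' @export
experiment_tobit_recovery <- function(n = 5000L, seed) {
  set.seed(seed)
  ## x placed so the clip points carry ~25% of the mass
  x <- stats::rnorm(n, 5, 5)
  y <- pmin(pmax(1 + 0.8 * x + stats::rnorm(n, 0, 1.5), 0), 10)
  ft <- fit_tobit(y, cbind(x = x))
  ols <- stats::coef(stats::lm(y ~ x))[["x"]]
  list(slope = unname(stats::coef(ft)[["x"]]), sigma = ft$sigma,
       ols_slope = ols,
       censored_fraction = mean(y == 0 | y == 10), n = n)
}

#' Conjugate-shrinkage check of the Gibbs sampler
#'
#' Single variant, unit LD, local and residual scales held fixed at
#' \code{phi * psi = c} and \code{sigma2 = 1}: the posterior mean is
#' \code{beta_hat * N c / (N c + 1)} in closed form. Returns the measured
#' and expected shrinkage factors.
#'
#' @param seed RNG seed.
#' @param n_gwas discovery sample size N.
#' @param c_shrink fixed prior-variance product \code{phi * psi}.
#' @param beta_hat marginal estimate fed to the sampler.
#' @param n_iter,n_burnin chain length.
#' @return list \code{shrinkage}, \code{expected}, \code{mc_se}.
#' @export
experiment_conjugate_shrinkage <- function(seed, n_gwas = 1000L,
                                           c_shrink = 0.005,
                                           beta_hat = 0.05,
                                           n_iter = 6000L,
                                           n_burnin = 1000L) {
  blocks <- structure(list(list(idx = 1L, R = matrix(1, 1, 1))),
                      class = "ld_blocks")
  prm <- cs_prior_params(phi = 1, n_iter = n_iter, n_burnin = n_burnin,
                         thin = 1L, seed = seed)
  eff <- gibbs_cs(beta_hat, blocks, n_gwas = n_gwas, params = prm,
                  fix_psi = c_shrink, fix_sigma2 = 1)
  expected <- n_gwas * c_shrink / (n_gwas * c_shrink + 1)
  ## MC standard error of the posterior-mean estimate (draws are
  ## near-independent here: each beta draw conditions only on fixed state)
  post_sd <- sqrt(1 / n_gwas / (1 + 1 / (n_gwas * c_shrink)))
  list(shrinkage = eff$effect_mean / beta_hat, expected = expected,
       mc_se = post_sd / abs(beta_hat) / sqrt(n_iter - n_burnin))
}

#' Shrinkage mean-squared-error experiment
#'
#' On cohorts with 30% causal variants, compares (i) the mean absolute
#' posterior effect of causal versus null variants and (ii) the squared
#' error of the posterior means versus the raw marginal estimates, both
#' against the true standardized effects.
#'
#' @param n_seeds number of replicate cohorts.
#' @param n,m cohort size and variant count.
#' @param seed base seed.
#' @return list \code{mse_posterior}, \code{mse_raw}, \code{mse_ratio}
#'   (posterior / raw, averaged over seeds), \code{causal_gt_null} (count
#'   of seeds where causal variants carry larger mean |effect|),
#'   \code{n_seeds}.
#' @export
experiment_shrinkage_mse <- function(n_seeds = 5L, n = 800L, m = 200L,
                                     seed) {
  mse_post <- numeric(n_seeds)
  mse_raw <- numeric(n_seeds)
  causal_gt <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_samples = n, n_variants = m, n_blocks = m %/% 10L,
                      h2_liability = 0.5, causal_fraction = 0.3,
                      seed = seed + s)
    sim <- simulate_cohort(cfg)
    y <- as.numeric(scale(sim$liability))
    truth <- sim$beta / stats::sd(sim$liability)
    st <- run_gwas(sim$G, sim$variants, y, NULL, "continuous")
    bstd <- standardize_betas(st)
    blocks <- build_ld_blocks(sim$G, sim$variants$block)
    prm <- cs_prior_params(n_iter = 300L, n_burnin = 100L, thin = 2L,
                           seed = seed + s)
    eff <- gibbs_cs(bstd, blocks, n_gwas = n, params = prm)
    mse_post[s] <- mean((eff$effect_mean - truth)^2)
    mse_raw[s] <- mean((bstd - truth)^2)
    is_causal <- seq_len(m) %in% sim$causal
    causal_gt[s] <- mean(abs(eff$effect_mean[is_causal])) >
      mean(abs(eff$effect_mean[!is_causal]))
  }
  list(mse_posterior = mean(mse_post), mse_raw = mean(mse_raw),
       mse_ratio = mean(mse_post / mse_raw),
       causal_gt_null = sum(causal_gt), n_seeds = n_seeds)
}

#' Null-calibration experiment for the scan engines
#'
#' On zero-heritability cohorts, measures the per-variant logistic type-I
#' error at \code{alpha}, the Kolmogorov-Smirnov statistics of the GWAS and
#' gene-level p-value distributions against uniform, and the genomic
#' inflation factor. P-values are pooled over \code{n_rep} replicate
#' cohorts so the summaries estimate the same population quantities with
#' proportionally smaller Monte-Carlo noise.
#'
#' @param seed base RNG seed (replicate r uses \code{seed + r - 1}).
#' @param n,m cohort size and variant count per replicate.
#' @param alpha test level.
#' @param n_rep number of replicate cohorts pooled.
#' @return list \code{type1_rate}, \code{ks_gwas}, \code{ks_gene},
#'   \code{lambda_gc}, \code{m}, \code{n_genes}.
#' @export
experiment_null_calibration <- function(seed, n = 500L, m = 2000L,
                                        alpha = 0.05, n_rep = 3L) {
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(m %/% 4L)),
    chrom = "1",
    start_bp = (seq(0L, m - 4L, by = 4L)) * 1000L + 1L,
    end_bp = seq(4L, m, by = 4L) * 1000L,
    stringsAsFactors = FALSE
  )
  p <- numeric(0)
  gp <- numeric(0)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_samples = n, n_variants = m, n_blocks = m %/% 10L,
                      h2_liability = 0, seed = seed + r - 1L)
    sim <- simulate_cohort(cfg)
    y <- .sim_binary_outcome(sim)
    st <- run_gwas(sim$G, sim$variants, y, NULL, "binary")
    p <- c(p, st$p[!is.na(st$p)])
    gs <- run_gene_scan(sim$G, sim$variants, genes, y)
    gp <- c(gp, gs$p[!is.na(gs$p)])
  }
  ks_gwas <- suppressWarnings(stats::ks.test(p, "punif")$statistic[[1L]])
  ks_gene <- suppressWarnings(stats::ks.test(gp, "punif")$statistic[[1L]])
  list(type1_rate = mean(p < alpha), ks_gwas = ks_gwas, ks_gene = ks_gene,
       lambda_gc = genomic_inflation(p), m = length(p),
       n_genes = length(gp))
}

#' Cross-fitted signal-recovery experiment
#'
#' On heritable cohorts (liability heritability 0.3 unless overridden),
#' measures the correlation between the cross-fitted PGS and the true
#' latent liability over replicate seeds.
#'
#' @param n_seeds replicate count.
#' @param n,m cohort size and variant count.
#' @param h2 liability heritability.
#' @param seed base seed.
#' @return list \code{correlations}, \code{n_positive}, \code{mean_cor}.
#' @export
experiment_pgs_recovery <- function(n_seeds = 20L, n = 2000L, m = 400L,
                                    h2 = 0.3, seed) {
  cors <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_samples = n, n_variants = m, n_blocks = m %/% 10L,
                      h2_liability = h2, seed = seed + s)
    sim <- simulate_cohort(cfg)
    y <- as.numeric(scale(sim$liability))
    blocks <- build_ld_blocks(sim$G, sim$variants$block)
    prm <- .default_chain(seed + s)
    cf <- log_crossfit(sim$G, sim$variants, y, NULL, blocks, prm,
                       k = 5L, seed = seed + s,
                       outcome_type = "continuous")
    cors[s] <- stats::cor(cf$pgs, sim$liability)
  }
  list(correlations = cors, n_positive = sum(cors > 0),
       mean_cor = mean(cors))
}
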