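## Posterior SNP effects under a continuous-shrinkage prior, individual
## scoring, and leave-one-group-out cross-fitting.
##
## Model (per variant j, on the standardized-genotype / unit-variance
## phenotype scale): marginal estimate beta_hat ~ N(R beta, sigma2/N R) per
## LD block; prior beta_j ~ N(0, sigma2 * phi * psi_j) with local scales
## psi_j ~ Gamma(a, delta_j), delta_j ~ Gamma(b, phi), and global scale phi
## either fixed or given a half-Cauchy prior (sampled through its
## gamma-mixture representation). The defaults a = 1, b = 1/2 give the
## horseshoe-like continuous-shrinkage family used for polygenic scores.
## With a single variant, unit R, fixed phi*psi = c and sigma2 = 1 the
## posterior mean reduces to beta_hat * N c / (N c + 1).

#' Continuous-shrinkage prior and chain settings
#'
#' @param a,b prior shapes (both > 0); defaults 1 and 1/2.
#' @param phi global shrinkage: a positive number to hold it fixed, or
#'   \code{"auto"} to sample it under a half-Cauchy prior.
#' @param n_iter total Gibbs iterations.
#' @param n_burnin burn-in iterations (must be < \code{n_iter}).
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param seed mandatory RNG seed.
#' @return validated list of class \code{cs_prior_params}.
#' @export
cs_prior_params <- function(a = 1, b = 0.5, phi = "auto", n_iter = 1000L,
                            n_burnin = 500L, thin = 5L, seed) {
  assert_that(!missing(seed), "cs_prior_params: seed is mandatory")
  assert_that(a > 0 && b > 0, "cs_prior_params: a and b must be > 0")
  assert_that(n_burnin < n_iter,
              "cs_prior_params: n_burnin must be < n_iter")
  if (!identical(phi, "auto")) {
    assert_that(is.numeric(phi) && phi > 0,
                "cs_prior_params: phi must be positive or 'auto'")
  }
  structure(list(a = a, b = b, phi = phi, n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "cs_prior_params")
}

#' Marginal effects on the standardized scale
#'
#' Converts GWAS summary statistics to standardized-scale marginal effect
#' estimates \code{beta_hat = z / sqrt(n)}. Flagged (degenerate/separated)
#' variants with missing z contribute 0 (no information).
#'
#' @param stats summary-statistics data.frame with \code{z} and \code{n}.
#' @return numeric vector aligned to \code{stats} rows.
#' @export
standardize_betas <- function(stats) {
  check_columns(stats, c("z", "n"), "summary statistics")
  assert_that(all(!is.na(stats$n)), "standardize_betas: missing n")
  b <- stats$z / sqrt(stats$n)
  b[is.na(b)] <- 0
  b
}

#' Gibbs sampler for posterior SNP effects under continuous shrinkage
#'
#' Block-updates the effect vector from its multivariate-normal conditional
#' (generalized-ridge mean, block Cholesky solves), the local scales from
#' their generalized-inverse-Gaussian conditionals, their rates from gamma
#' conditionals, the residual variance from its inverse-gamma conditional,
#' and (when \code{phi = "auto"}) the global scale from a conjugate gamma
#' step under the half-Cauchy prior. Fully reproducible from
#' \code{params$seed}.
#'
#' @param betas_std standardized marginal effects (from
#'   \code{\link{standardize_betas}}), aligned to the block partition.
#' @param blocks an \code{\link{build_ld_blocks}} object partitioning the
#'   same variants.
#' @param n_gwas GWAS sample size behind \code{betas_std}.
#' @param params a \code{\link{cs_prior_params}}.
#' @param variant_id,allele_effect optional metadata carried into the
#'   result.
#' @param fix_psi,fix_sigma2 hold the local scales / residual variance
#'   fixed at the given values instead of sampling them (used to reduce the
#'   sampler to conjugate sub-cases with known closed forms).
#' @return object of class \code{cs_posterior}: data.frame
#'   \code{variant_id, allele_effect, effect_mean} with attributes
#'   \code{phi} (posterior mean), \code{sigma2} (posterior mean) and
#'   \code{params}.
#' @export
gibbs_cs <- function(betas_std, blocks, n_gwas, params,
                     variant_id = NULL, allele_effect = NULL,
                     fix_psi = NULL, fix_sigma2 = NULL) {
  stopifnot(inherits(params, "cs_prior_params"))
  p <- length(betas_std)
  all_idx <- sort(as.integer(unlist(lapply(blocks, `[[`, "idx"),
                                    use.names = FALSE)))
  assert_that(identical(all_idx, seq_len(p)),
              "blocks do not partition the %d variants", p)
  set.seed(params$seed)

  N <- n_gwas
  a <- params$a
  b <- params$b
  phi_auto <- identical(params$phi, "auto")
  phi <- if (phi_auto) 1 / N else params$phi
  beta <- numeric(p)
  psi <- if (is.null(fix_psi)) rep(1, p) else rep_len(fix_psi, p)
  sigma2 <- fix_sigma2 %||% 1
  w <- 1

  n_keep <- 0L
  beta_sum <- numeric(p)
  phi_sum <- 0
  sigma2_sum <- 0

  for (it in seq_len(params$n_iter)) {
    quad <- 0
    for (blk in blocks) {
      idx <- blk$idx
      dinv <- 1 / (N * phi * psi[idx])
      A <- blk$R + diag(dinv, length(idx))
      ch <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(ch)) {
        stop_lipgs("non-positive-definite LD block reached the sampler")
      }
      mu <- backsolve(ch, forwardsolve(t(ch), betas_std[idx]))
      z <- stats::rnorm(length(idx))
      beta[idx] <- mu + sqrt(sigma2 / N) * backsolve(ch, z)
      quad <- quad + sum(beta[idx] * (A %*% beta[idx]))
    }
    ## sigma2 | rest: inverse gamma; the second term guards the rate when
    ## the reference R and the summary statistics are inconsistent enough
    ## to drive the quadratic form negative.
    if (is.null(fix_sigma2)) {
      pen <- sum(beta^2 / psi) / (2 * phi)
      rate <- max(N / 2 * (1 - 2 * sum(beta * betas_std) + quad), pen)
      sigma2 <- 1 / stats::rgamma(1L, shape = (N + p) / 2, rate = rate)
    }

    if (is.null(fix_psi)) {
      delta <- stats::rgamma(p, shape = a + b, rate = psi + phi)
      psi <- rgig(p, lambda = a - 0.5, chi = beta^2 / (sigma2 * phi),
                  psi = 2 * delta)
      psi <- pmin(psi, 1)
    }

    if (phi_auto) {
      w <- stats::rgamma(1L, shape = 1, rate = phi + 1)
      phi <- stats::rgamma(1L, shape = p * b + 0.5,
                           rate = sum(beta^2 / psi) / (2 * sigma2) + w)
    }

    if (it > params$n_burnin &&
        (it - params$n_burnin) %% params$thin == 0L) {
      n_keep <- n_keep + 1L
      beta_sum <- beta_sum + beta
      phi_sum <- phi_sum + phi
      sigma2_sum <- sigma2_sum + sigma2
    }
  }
  assert_that(n_keep > 0L, "no post-burn-in draws kept; check n_iter/thin")
  out <- data.frame(
    variant_id = variant_id %||% sprintf("v%05d", seq_len(p)),
    allele_effect = allele_effect %||% NA_character_,
    effect_mean = beta_sum / n_keep,
    stringsAsFactors = FALSE
  )
  structure(out, phi = phi_sum / n_keep, sigma2 = sigma2_sum / n_keep,
            n_draws = n_keep, params = params,
            class = c("cs_posterior", "data.frame"))
}

#' @export
print.cs_posterior <- function(x, ...) {
  cat(sprintf(
    "Continuous-shrinkage posterior effects: %d variants, %d draws\n",
    nrow(x), attr(x, "n_draws")))
  cat(sprintf("  posterior mean phi = %.3g, sigma2 = %.3g\n",
              attr(x, "phi"), attr(x, "sigma2")))
  cat(sprintf("  sum |effect| = %.4g\n", sum(abs(x$effect_mean))))
  invisible(x)
}

#' Score individuals with posterior effects
#'
#' \code{PGS_i = sum_j effect_j * standardized dosage_ij} over the variants
#' shared between the genotype matrix and the effect table. Effect-allele
#' orientation is harmonized by flipping dosages \code{d -> 2 - d} where the
#' effect table's effect allele is the genotype table's other allele;
#' variants matching neither allele are dropped. Dosages are standardized
#' within the scored cohort (mean-imputed first).
#'
#' @param G samples x variants dosage matrix.
#' @param variants variant table aligned to \code{G}'s columns.
#' @param effects a \code{cs_posterior} (or any data.frame with
#'   \code{variant_id, allele_effect, effect_mean}).
#' @return numeric vector of raw (unstandardized) scores, named by sample.
#' @export
score_individuals <- function(G, variants, effects) {
  idx <- match(effects$variant_id, variants$variant_id)
  use <- which(!is.na(idx))
  assert_that(length(use) > 0L,
              "no overlap between genotypes and effect table")
  gi <- idx[use]
  eff <- effects$effect_mean[use]
  ea <- effects$allele_effect[use]
  same <- is.na(ea) | ea == variants$allele_effect[gi]
  flipped <- !same & ea == variants$allele_other[gi]
  keep <- same | flipped
  gi <- gi[keep]; eff <- eff[keep]; flipped <- flipped[keep]
  assert_that(length(gi) > 0L, "no allele-consistent variants to score")
  Gs <- G[, gi, drop = FALSE]
  Gs[, flipped] <- 2 - Gs[, flipped, drop = FALSE]
  X <- standardize_dosages(Gs)
  drop(X %*% eff)
}

#' Seeded balanced fold assignment
#'
#' Random partition of \code{n} samples into \code{k} folds with sizes
#' differing by at most one (remainder to the lowest-numbered folds);
#' optionally stratified by an outcome so every fold keeps both classes.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param strata optional vector (length n) to stratify on.
#' @return integer vector of fold labels 1..k.
#' @export
make_folds <- function(n, k, seed, strata = NULL) {
  set.seed(seed)
  fold <- integer(n)
  if (is.null(strata)) {
    fold[sample.int(n)] <- rep(seq_len(k), balanced_sizes(n, k))
  } else {
    for (s in unique(strata)) {
      rows <- which(strata == s)
      lab <- rep(seq_len(k), length.out = length(rows))
      fold[rows[sample.int(length(rows))]] <- lab
    }
  }
  fold
}

#' Leave-one-group-out cross-fitted polygenic scores
#'
#' Partitions the cohort into \code{k} seeded folds; for each fold, runs the
#' association scan on the remaining folds, converts to standardized
#' marginal effects, draws posterior effects under the continuous-shrinkage
#' prior, and scores the held-out fold. Every sample is scored exactly once,
#' never by a model trained on it; the assembled score vector is
#' z-standardized across the cohort.
#'
#' @param G,variants cohort genotypes (post-QC).
#' @param y outcome vector aligned to rows of \code{G}.
#' @param covariates covariate matrix for the per-fold scans (or NULL).
#' @param blocks LD reference (\code{\link{build_ld_blocks}}).
#' @param params \code{\link{cs_prior_params}}.
#' @param k number of folds.
#' @param seed fold-assignment seed (per-fold sampler seeds derive from
#'   it).
#' @param outcome_type \code{"binary"} or \code{"continuous"}.
#' @param stratified stratify folds by the binary outcome.
#' @return data.frame \code{sample_id, pgs, fold} in cohort order, with the
#'   fold assignment as attribute \code{"folds"}.
#' @export
log_crossfit <- function(G, variants, y, covariates = NULL, blocks, params,
                         k = 5L, seed,
                         outcome_type = c("binary", "continuous"),
                         stratified = FALSE) {
  outcome_type <- match.arg(outcome_type)
  n <- nrow(G)
  strata <- NULL
  if (stratified && outcome_type == "binary") {
    strata <- .as_binary_outcome(y)
  }
  fold <- make_folds(n, k, seed, strata)
  pgs <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    disc <- which(fold != f)
    targ <- which(fold == f)
    if (outcome_type == "binary") {
      yy <- .as_binary_outcome(y[disc])
      if (length(unique(yy[!is.na(yy)])) < 2L) {
        stop_lipgs(paste0("fold %d discovery set lost an outcome class; ",
                          "use stratified = TRUE"), f)
      }
    }
    stats <- run_gwas(G[disc, , drop = FALSE], variants, y[disc],
                      covariates[disc, , drop = FALSE],
                      outcome_type = outcome_type)
    bstd <- standardize_betas(stats)
    fold_params <- params
    fold_params$seed <- params$seed + f
    eff <- gibbs_cs(bstd, blocks, n_gwas = length(disc), params = fold_params,
                    variant_id = variants$variant_id,
                    allele_effect = variants$allele_effect)
    pgs[targ] <- score_individuals(G[targ, , drop = FALSE], variants, eff)
  }
  assert_that(!anyNA(pgs), "cross-fitting left unscored samples")
  out <- data.frame(
    sample_id = rownames(G) %||% sprintf("S%05d", seq_len(n)),
    pgs = as.numeric(scale(pgs)),
    fold = fold,
    stringsAsFactors = FALSE
  )
  attr(out, "folds") <- fold
  out
}

#' Score an external cohort from full-cohort summary statistics
#'
#' Draws posterior effects from the discovery cohort's summary statistics
#' and scores a disjoint target cohort; scores are z-standardized within
#' the target.
#'
#' @param stats discovery summary statistics (full cohort).
#' @param blocks LD reference aligned to \code{stats} rows.
#' @param params \code{\link{cs_prior_params}}.
#' @param G_target,variants_target target cohort genotypes.
#' @return data.frame \code{sample_id, pgs}.
#' @export
external_score <- function(stats, blocks, params, G_target,
                           variants_target) {
  assert_that(nrow(G_target) > 0L, "external_score: empty target cohort")
  bstd <- standardize_betas(stats)
  eff <- gibbs_cs(bstd, blocks, n_gwas = max(stats$n), params = params,
                  variant_id = stats$variant_id,
                  allele_effect = stats$allele_effect)
  raw <- score_individuals(G_target, variants_target, eff)
  data.frame(
    sample_id = rownames(G_target) %||%
      sprintf("T%05d", seq_len(nrow(G_target))),
    pgs = as.numeric(scale(raw)),
    stringsAsFactors = FALSE
  )
}
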