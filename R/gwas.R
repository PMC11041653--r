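## Per-variant association scans and genotype principal components.
##
## The scan engines are written against a fixed numerical contract: linear
## associations are OLS with two-sided t tests; logistic associations are
## maximum-likelihood fits by iteratively reweighted least squares,
## converged when the largest score component falls below 1e-8 (25
## iterations max), with Wald tests and an explicit separation flag when
## |beta| diverges past 15. Missing dosages are mean-imputed per variant at
## fit time only.

.as_binary_outcome <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    assert_that(all(y %in% c("good", "poor", NA)),
                "binary outcome must be coded good/poor or 0/1")
    y <- as.numeric(y == "good")
  }
  y <- as.numeric(y)
  assert_that(all(y %in% c(0, 1) | is.na(y)),
              "binary outcome must be coded good/poor or 0/1")
  y
}

#' Covariate matrix for association models
#'
#' Builds the standard covariate set: age, a female-sex indicator, one-hot
#' chip indicators with the reference (first) level dropped, and the leading
#' genotype PCs. Rows with any missing covariate are dropped and counted.
#'
#' @param phenos phenotype data.frame.
#' @param pcs samples x k PC score matrix aligned to \code{phenos} rows, or
#'   NULL.
#' @param include_chip include chip indicator columns (the GWAS covariate
#'   set includes chip; the PGS-association set does not).
#' @return list \code{X} (numeric matrix), \code{rows} (kept row indices),
#'   \code{n_dropped}.
#' @export
build_covariates <- function(phenos, pcs = NULL, include_chip = TRUE) {
  X <- cbind(age_years = phenos$age_years,
             sex_female = as.numeric(phenos$sex == "female"))
  if (include_chip) {
    lev <- sort(unique(phenos$chip[!is.na(phenos$chip)]))
    if (length(lev) > 1L) {
      for (l in lev[-1L]) {
        X <- cbind(X, as.numeric(phenos$chip == l))
        colnames(X)[ncol(X)] <- paste0("chip_", l)
      }
    }
  }
  if (!is.null(pcs) && ncol(pcs) > 0L) {
    colnames(pcs) <- paste0("pc", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
  }
  rows <- which(stats::complete.cases(X))
  list(X = X[rows, , drop = FALSE], rows = rows,
       n_dropped = nrow(X) - length(rows))
}

## Greedy LD pruning: scan variants in order, keep a variant only if its
## squared correlation with every already-retained variant in the trailing
## window stays at or below r2_max.
prune_variants <- function(X, r2_max = 0.2, window = 50L) {
  m <- ncol(X)
  keep <- logical(m)
  kept_idx <- integer(0)
  for (j in seq_len(m)) {
    near <- kept_idx[kept_idx > j - window]
    ok <- TRUE
    if (length(near) > 0L) {
      r <- suppressWarnings(stats::cor(X[, j], X[, near, drop = FALSE]))
      r[is.na(r)] <- 0
      ok <- all(r^2 <= r2_max)
    }
    if (ok && stats::sd(X[, j]) > 0) {
      keep[j] <- TRUE
      kept_idx <- c(kept_idx, j)
    }
  }
  keep
}

#' Genotype principal components
#'
#' LD-prunes the variants (greedy, trailing window), mean-imputes and
#' standardizes dosages, and returns the top-\code{k} left singular vectors
#' scaled to unit variance. Signs are fixed so the largest-magnitude variant
#' loading of each component is positive.
#'
#' @param G samples x variants dosage matrix (post-QC).
#' @param k number of components.
#' @param prune_r2 maximum squared correlation between retained variants
#'   within the pruning window.
#' @param prune_window pruning window, in retained-variant index distance.
#' @return samples x k matrix of PC scores (unit variance per column).
#' @export
compute_pcs <- function(G, k = 4L, prune_r2 = 0.2, prune_window = 50L) {
  if (k == 0L) {
    return(matrix(numeric(0), nrow = nrow(G), ncol = 0L))
  }
  X <- standardize_dosages(G)
  keep <- prune_variants(X, prune_r2, prune_window)
  X <- X[, keep, drop = FALSE]
  sv <- svd(X, nu = min(nrow(X), ncol(X)), nv = min(nrow(X), ncol(X)))
  rank <- sum(sv$d > sv$d[1L] * 1e-8)
  assert_that(k <= rank, "k = %d exceeds the genotype matrix rank (%d)",
              k, rank)
  scores <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
    scores[, j] <- scores[, j] / stats::sd(scores[, j])
  }
  colnames(scores) <- paste0("pc", seq_len(k))
  scores
}

#' Per-variant linear association
#'
#' OLS of a continuous outcome on \code{[1, g, X]} with a two-sided t test
#' for the dosage coefficient. A constant dosage is a degenerate fit:
#' \code{beta = 0, p = 1}, flagged.
#'
#' @param y continuous outcome (complete for the rows supplied).
#' @param g variant dosage (missing values mean-imputed).
#' @param X covariate matrix or NULL.
#' @return list \code{beta}, \code{se}, \code{p}, \code{flag}.
#' @export
assoc_linear <- function(y, g, X = NULL) {
  g <- impute_dosage_mean(g)
  if (stats::sd(g) < .Machine$double.eps) {
    return(list(beta = 0, se = NA_real_, p = 1, flag = "degenerate"))
  }
  D <- cbind(1, g, X)
  n <- length(y)
  XtX <- crossprod(D)
  Xty <- crossprod(D, y)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                flag = "singular"))
  }
  inv <- chol2inv(ch)
  coefs <- inv %*% Xty
  resid <- y - D %*% coefs
  df <- n - ncol(D)
  sigma2 <- sum(resid^2) / df
  beta <- unname(coefs[2L])
  se <- sqrt(sigma2 * inv[2L, 2L])
  tval <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), flag = "ok")
}

#' Per-variant logistic association
#'
#' Maximum-likelihood logistic fit of a binary outcome on \code{[1, g, X]}
#' by IRLS; convergence when \code{max |score| < 1e-8} or after 25
#' iterations. Wald z test for the dosage coefficient. Perfect separation
#' (any |coefficient| diverging beyond 15) is flagged with a missing p.
#'
#' @param y binary outcome (\code{good}/\code{poor}, 0/1 or logical).
#' @param g variant dosage (missing values mean-imputed).
#' @param X covariate matrix or NULL.
#' @return list \code{beta} (log-OR), \code{se}, \code{p}, \code{flag}.
#' @export
assoc_logistic <- function(y, g, X = NULL) {
  y <- .as_binary_outcome(y)
  assert_that(length(unique(y)) == 2L,
              "logistic association needs both outcome classes")
  g <- impute_dosage_mean(g)
  if (stats::sd(g) < .Machine$double.eps) {
    return(list(beta = 0, se = NA_real_, p = NA_real_, flag = "degenerate"))
  }
  D <- cbind(1, g, X)
  fit <- irls_logistic(y, D)
  if (fit$flag == "separation") {
    return(list(beta = unname(fit$beta[2L]), se = NA_real_, p = NA_real_,
                flag = "separation"))
  }
  beta <- unname(fit$beta[2L])
  se <- unname(fit$se[2L])
  z <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE), flag = fit$flag)
}

## Core IRLS on an explicit design matrix.
irls_logistic <- function(y, D, tol = 1e-8, max_iter = 25L) {
  beta <- numeric(ncol(D))
  flag <- "no_convergence"
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(D %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    score <- crossprod(D, y - mu)
    if (max(abs(score)) < tol) {
      flag <- "ok"
      break
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- tryCatch(
      solve(crossprod(D, w * D), crossprod(D, w * z)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(beta = beta, se = NULL,
                                  flag = "singular"))
    beta <- drop(fit)
    if (max(abs(beta)) > 15) {
      return(list(beta = beta, se = NULL, flag = "separation"))
    }
  }
  eta <- pmin(pmax(drop(D %*% beta), -30), 30)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(D, w * D)
  se <- sqrt(diag(solve(info)))
  list(beta = beta, se = se, flag = flag)
}

#' Genome-wide association scan
#'
#' One covariate-adjusted association per variant. The default covariate set
#' is the full GWAS set (age, sex, chip, first four PCs) passed in via
#' \code{covariates}; degenerate or separated fits carry a flag instead of
#' fabricated numbers.
#'
#' @param G samples x variants dosage matrix.
#' @param variants variant table aligned to columns of \code{G}.
#' @param y outcome vector aligned to rows of \code{G} (binary or
#'   continuous; rows with missing outcome are dropped).
#' @param covariates numeric covariate matrix aligned to rows of \code{G},
#'   or NULL.
#' @param outcome_type \code{"binary"} or \code{"continuous"}.
#' @return summary-statistics data.frame (fixed column set plus
#'   \code{flag}), one row per input variant, in input order.
#' @export
run_gwas <- function(G, variants, y, covariates = NULL,
                     outcome_type = c("binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  assert_that(ncol(G) > 0L, "run_gwas: zero variants")
  assert_that(ncol(G) == nrow(variants), "G / variant table shape mismatch")
  if (outcome_type == "binary") y <- .as_binary_outcome(y)
  rows <- which(!is.na(y))
  if (!is.null(covariates)) {
    rows <- intersect(rows, which(stats::complete.cases(covariates)))
    Xc <- covariates[rows, , drop = FALSE]
  } else {
    Xc <- NULL
  }
  yy <- y[rows]
  n_used <- length(rows)

  res <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[rows, j]
    res[[j]] <- if (outcome_type == "binary") {
      assoc_logistic(yy, g, Xc)
    } else {
      assoc_linear(yy, g, Xc)
    }
  }
  beta <- vapply(res, `[[`, numeric(1L), "beta")
  se <- vapply(res, `[[`, numeric(1L), "se")
  p <- vapply(res, `[[`, numeric(1L), "p")
  flag <- vapply(res, `[[`, character(1L), "flag")
  freq <- colMeans(G[rows, , drop = FALSE], na.rm = TRUE) / 2
  stats_df <- data.frame(
    variant_id = variants$variant_id,
    chrom = variants$chrom,
    pos_bp = variants$pos_bp,
    allele_effect = variants$allele_effect,
    allele_other = variants$allele_other,
    freq = freq,
    beta = beta,
    se = se,
    z = beta / se,
    p = p,
    n = n_used,
    flag = flag,
    stringsAsFactors = FALSE
  )
  rownames(stats_df) <- NULL
  stats_df
}

#' Genomic inflation factor
#'
#' Median chi-square of the scan divided by the null median (0.4549).
#'
#' @param p vector of two-sided p-values.
#' @return lambda_GC.
#' @export
genomic_inflation <- function(p) {
  chisq <- stats::qchisq(p[!is.na(p)], df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
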