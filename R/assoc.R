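## PGS-response association: logistic model for the categorical outcome,
## two-limit Tobit for the continuous outcome, decile stratification, and
## incremental pseudo-R2. The association covariate set is age, sex and the
## leading genotype PCs (chip type belongs to the per-variant scan only).

#' Nagelkerke pseudo-R-squared of a binomial glm
#'
#' @param fit,fit_null fitted \code{glm} objects (full and intercept-only or
#'   reduced), same samples.
#' @return fraction in [0, 1].
#' @export
nagelkerke_r2 <- function(fit, fit_null) {
  n <- stats::nobs(fit)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit_null))
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  cox_snell / (1 - exp(2 * ll0 / n))
}

#' Logistic PGS-response association
#'
#' Maximum-likelihood logistic regression of responder status on
#' \code{[1, PGS, covariates]} with Wald confidence intervals
#' \code{exp(b +/- 1.96 se)}, Nagelkerke pseudo-R2 for the full and
#' covariate-only models, and their incremental difference (the variance
#' attributable to the PGS).
#'
#' @param pgs standardized polygenic score vector.
#' @param y responder status (\code{good}/\code{poor}, 0/1 or logical).
#' @param covariates covariate matrix or NULL.
#' @return object of class \code{pgs_assoc} (model \code{"logistic"}) with
#'   \code{effect} (log-OR per SD of PGS), \code{se}, \code{p},
#'   \code{or_ci95}, \code{r2_full}, \code{r2_cov}, \code{r2_incremental},
#'   \code{n_used}.
#' @export
fit_logistic_pgs <- function(pgs, y, covariates = NULL) {
  y <- .as_binary_outcome(y)
  df <- data.frame(y = y, pgs = pgs)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  assert_that(length(unique(df$y)) == 2L,
              "fit_logistic_pgs: both outcome classes required")
  full <- stats::glm(y ~ ., data = df, family = stats::binomial())
  cf_all <- stats::coef(full)[-1L]
  if (!full$converged || any(abs(cf_all[!is.na(cf_all)]) > 15)) {
    stop_lipgs(paste0("fit_logistic_pgs: separation or non-convergence ",
                      "(max |coef| = %.2f)"),
               max(abs(cf_all[!is.na(cf_all)])))
  }
  red <- stats::glm(y ~ . - pgs, data = df, family = stats::binomial())
  null <- stats::glm(y ~ 1, data = df, family = stats::binomial())
  b <- stats::coef(full)["pgs"]
  se <- if (is.na(b)) NA_real_ else sqrt(stats::vcov(full)["pgs", "pgs"])
  if (is.na(b)) b <- 0  # constant PGS carries no information
  r2f <- nagelkerke_r2(full, null)
  r2c <- nagelkerke_r2(red, null)
  structure(list(
    model = "logistic",
    effect = unname(b),
    se = unname(se),
    p = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE),
    or = exp(unname(b)),
    or_ci95 = exp(unname(b) + c(-1, 1) * 1.96 * unname(se)),
    r2_full = r2f, r2_cov = r2c,
    r2_incremental = max(r2f - r2c, 0),
    n_used = nrow(df),
    fit = full
  ), class = "pgs_assoc")
}

#' Tobit PGS-response association
#'
#' Two-limit Tobit regression of the continuous ALDA outcome on
#' \code{[1, PGS, covariates]} (see \code{\link{fit_tobit}}), with
#' McKelvey-Zavoina pseudo-R2 on the latent scale for the incremental
#' computation.
#'
#' @inheritParams fit_logistic_pgs
#' @param y continuous outcome in \code{[lower, upper]} (excluded samples
#'   NA).
#' @param lower,upper censoring limits.
#' @return object of class \code{pgs_assoc} (model \code{"tobit"});
#'   \code{effect} is the latent-scale slope per SD of PGS.
#' @export
fit_tobit_pgs <- function(pgs, y, covariates = NULL, lower = 0,
                          upper = 10) {
  X <- cbind(pgs = pgs, covariates)
  rows <- which(stats::complete.cases(X) & !is.na(y))
  full <- fit_tobit(y[rows], X[rows, , drop = FALSE], lower, upper)
  r2f <- mckelvey_zavoina_r2(full)
  r2c <- if (is.null(covariates)) 0 else {
    red <- fit_tobit(y[rows],
                     X[rows, -1L, drop = FALSE], lower, upper)
    mckelvey_zavoina_r2(red)
  }
  structure(list(
    model = "tobit",
    effect = unname(full$coefficients["pgs"]),
    se = unname(full$se["pgs"]),
    p = unname(full$p["pgs"]),
    or = exp(unname(full$coefficients["pgs"])),
    or_ci95 = exp(unname(full$coefficients["pgs"]) +
                    c(-1, 1) * 1.96 * unname(full$se["pgs"])),
    r2_full = r2f, r2_cov = r2c,
    r2_incremental = max(r2f - r2c, 0),
    n_used = full$n,
    fit = full
  ), class = "pgs_assoc")
}

#' @export
print.pgs_assoc <- function(x, ...) {
  lab <- if (x$model == "logistic") "OR per SD" else "exp(slope) per SD"
  cat(sprintf("PGS association (%s), n = %d\n", x$model, x$n_used))
  cat(sprintf("  %s = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              lab, x$or, x$or_ci95[1L], x$or_ci95[2L], x$p))
  cat(sprintf("  R2 full = %.4f, covariates only = %.4f, incremental = %.4f\n",
              x$r2_full, x$r2_cov, x$r2_incremental))
  invisible(x)
}

#' Incremental pseudo-R-squared
#'
#' Difference in the model-appropriate pseudo-R2 between a full and a
#' reduced (nested, same-sample) fit: binomial glms use Nagelkerke, Tobit
#' fits use McKelvey-Zavoina.
#'
#' @param full,reduced fitted models of the same class over the same
#'   samples.
#' @return nonnegative fraction.
#' @export
incremental_r2 <- function(full, reduced) {
  if (inherits(full, "glm")) {
    assert_that(stats::nobs(full) == stats::nobs(reduced),
                "incremental_r2: different sample sizes")
    df <- data.frame(y = full$y)
    null <- stats::glm(y ~ 1, data = df, family = stats::binomial())
    return(max(nagelkerke_r2(full, null) - nagelkerke_r2(reduced, null), 0))
  }
  if (inherits(full, "lipgs_tobit")) {
    assert_that(full$n == reduced$n, "incremental_r2: different sample sizes")
    return(max(mckelvey_zavoina_r2(full) - mckelvey_zavoina_r2(reduced), 0))
  }
  stop_lipgs("incremental_r2: unsupported model class")
}

#' Odds ratio of a decile against the reference decile
#'
#' The unadjusted 2x2 cross-product ratio
#' \code{(R_d / (N_d - R_d)) / (R_ref / (N_ref - R_ref))} with Wald 95%
#' confidence interval; zero cells receive the 0.5 continuity correction and
#' a flag.
#'
#' @param n_resp responders in the decile.
#' @param n_total decile size.
#' @param n_resp_ref,n_total_ref the reference decile's counts.
#' @return list \code{or}, \code{ci}, \code{p}, \code{corrected}.
#' @export
decile_or <- function(n_resp, n_total, n_resp_ref, n_total_ref) {
  a <- n_resp; b <- n_total - n_resp
  c_ <- n_resp_ref; d <- n_total_ref - n_resp_ref
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  log_or <- log(a / b) - log(c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = exp(log_or),
       ci = exp(log_or + c(-1, 1) * 1.96 * se),
       p = 2 * stats::pnorm(abs(log_or / se), lower.tail = FALSE),
       corrected = corrected)
}

#' Decile stratification of the PGS-response relationship
#'
#' Ranks samples by PGS into ten groups (stable order for ties; sizes
#' differing by at most one, remainder to the lowest deciles), then reports
#' per decile the responder counts, the unadjusted odds ratio against the
#' first (lowest-score) decile from the 2x2 table, and the
#' covariate-adjusted odds ratio from a logistic model with decile
#' indicators.
#'
#' @param pgs polygenic score vector.
#' @param y responder status.
#' @param covariates covariate matrix for the adjusted model, or NULL.
#' @param n_groups number of strata (10 = deciles).
#' @return data.frame of class \code{decile_table}: one row per decile with
#'   \code{n_responders, n_total, or_unadj, or_unadj_lo, or_unadj_hi,
#'   or_adj, or_adj_lo, or_adj_hi, p_adj, corrected}.
#' @export
decile_analysis <- function(pgs, y, covariates = NULL, n_groups = 10L) {
  y <- .as_binary_outcome(y)
  n <- length(pgs)
  assert_that(n >= n_groups, "decile_analysis: n < number of groups")
  sizes <- balanced_sizes(n, n_groups)
  decile <- integer(n)
  decile[order(pgs)] <- rep(seq_len(n_groups), sizes)

  n_resp <- tapply(y, decile, sum)
  n_tot <- tapply(y, decile, length)

  unadj <- lapply(seq_len(n_groups), function(d) {
    if (d == 1L) {
      list(or = 1, ci = c(NA_real_, NA_real_), p = NA_real_,
           corrected = FALSE)
    } else {
      decile_or(n_resp[[d]], n_tot[[d]], n_resp[[1L]], n_tot[[1L]])
    }
  })

  dec_f <- factor(decile)
  df <- data.frame(y = y, decile = dec_f)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  adj <- lapply(seq_len(n_groups), function(d) {
    if (d == 1L) return(list(or = 1, ci = c(NA_real_, NA_real_),
                             p = NA_real_))
    nm <- paste0("decile", d)
    b <- cf[[nm]]
    se <- sqrt(vc[nm, nm])
    list(or = exp(b), ci = exp(b + c(-1, 1) * 1.96 * se),
         p = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE))
  })

  out <- data.frame(
    decile = seq_len(n_groups),
    n_responders = as.integer(n_resp),
    n_total = as.integer(n_tot),
    or_unadj = vapply(unadj, `[[`, numeric(1L), "or"),
    or_unadj_lo = vapply(unadj, function(u) u$ci[1L], numeric(1L)),
    or_unadj_hi = vapply(unadj, function(u) u$ci[2L], numeric(1L)),
    or_adj = vapply(adj, `[[`, numeric(1L), "or"),
    or_adj_lo = vapply(adj, function(u) u$ci[1L], numeric(1L)),
    or_adj_hi = vapply(adj, function(u) u$ci[2L], numeric(1L)),
    p_adj = vapply(adj, `[[`, numeric(1L), "p"),
    corrected = vapply(unadj, `[[`, logical(1L), "corrected")
  )
  class(out) <- c("decile_table", "data.frame")
  out
}

#' @export
print.decile_table <- function(x, ...) {
  cat("PGS decile stratification (decile 1 = lowest score, reference)\n")
  show <- data.frame(
    decile = x$decile,
    `R/N` = sprintf("%d/%d", x$n_responders, x$n_total),
    `OR unadj` = sprintf("%.2f", x$or_unadj),
    `OR adj` = sprintf("%.2f", x$or_adj),
    check.names = FALSE
  )
  print(show, row.names = FALSE)
  invisible(x)
}
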