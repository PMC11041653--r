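## ALDA-scale phenotype derivation.
##
## The ALDA scale rates long-term lithium response: subscale A (0-10)
## measures symptomatic improvement on lithium; the five B items (0-2 each)
## rate confounders of that improvement (prior episode count/frequency,
## treatment duration, adherence, co-medication). The working total is
## A minus the B sum, floored at zero; patients with total >= 7 are "good"
## responders. For the continuous outcome, records with a B total above 4 or
## any missing subscale are excluded rather than imputed.

#' ALDA total score
#'
#' \code{max(alda_a - sum(b), 0)}, elementwise over vectors. Any missing
#' subscore yields \code{NA} (missingness is a signal, not a zero).
#'
#' @param alda_a integer vector, subscale A in 0..10.
#' @param b matrix or data.frame with five columns (B1..B5 in 0..2), or a
#'   length-5 vector for a single record.
#' @return integer vector of totals in 0..10 (NA where any subscore missing).
#' @export
compute_alda_total <- function(alda_a, b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  b <- as.matrix(b)
  assert_that(ncol(b) == 5L, "ALDA B must have five subscores, got %d",
              ncol(b))
  assert_that(length(alda_a) == nrow(b),
              "alda_a length (%d) does not match B rows (%d)",
              length(alda_a), nrow(b))
  assert_that(all(is.na(alda_a) | (alda_a >= 0 & alda_a <= 10)),
              "alda_a outside 0..10")
  assert_that(all(is.na(b) | (b >= 0 & b <= 2)), "ALDA B item outside 0..2")
  total <- pmax(alda_a - rowSums(b), 0)
  total[is.na(alda_a) | apply(is.na(b), 1L, any)] <- NA
  as.integer(total)
}

#' Categorical response from the ALDA total
#'
#' @param alda_total integer vector in 0..10.
#' @param threshold responder cut-off; totals at or above it are "good".
#' @return character vector, \code{"good"} or \code{"poor"} (NA propagated).
#' @export
classify_response <- function(alda_total, threshold = 7L) {
  assert_that(all(is.na(alda_total) |
                    (alda_total >= 0 & alda_total <= 10)),
              "alda_total outside 0..10")
  ifelse(is.na(alda_total), NA_character_,
         ifelse(alda_total >= threshold, "good", "poor"))
}

#' Continuous outcome with exclusion rules
#'
#' Derives the continuous response value per record, excluding records whose
#' B total exceeds 4 or with any missing A/B subscale. Exclusion is a value
#' (reported in \code{excluded_reason}), not an error.
#'
#' @param phenos phenotype data.frame (see \code{\link{read_phenotypes}}).
#' @param definition \code{"total"} for the floored A-minus-B total (default)
#'   or \code{"subscale_a"} for subscale A alone.
#' @param b_max maximum allowed B total (records above it are excluded).
#' @return data.frame \code{sample_id, alda_total, responder,
#'   continuous_value, excluded_reason}; \code{continuous_value} is NA
#'   whenever \code{excluded_reason != "none"}.
#' @export
derive_continuous_outcome <- function(phenos,
                                      definition = c("total", "subscale_a"),
                                      b_max = 4L) {
  definition <- match.arg(definition)
  b_cols <- paste0("alda_b", 1:5)
  check_columns(phenos, c("sample_id", "alda_a", b_cols), "phenotype table")
  b <- as.matrix(phenos[, b_cols])
  b_sum <- rowSums(b)
  total <- compute_alda_total(phenos$alda_a, b)
  missing_any <- is.na(phenos$alda_a) | apply(is.na(b), 1L, any)
  reason <- rep("none", nrow(phenos))
  reason[!missing_any & b_sum > b_max] <- "b_gt_4"
  reason[missing_any] <- "missing_subscale"
  value <- switch(definition,
                  total = as.numeric(total),
                  subscale_a = as.numeric(phenos$alda_a))
  value[reason != "none"] <- NA_real_
  data.frame(sample_id = phenos$sample_id,
             alda_total = total,
             responder = classify_response(total),
             continuous_value = value,
             excluded_reason = reason,
             stringsAsFactors = FALSE)
}

#' Apply the minimum treatment-duration inclusion rule
#'
#' Removes samples treated for less than \code{min_months} months (or with
#' missing duration); the boundary itself is retained.
#'
#' @param phenos phenotype data.frame with \code{months_on_lithium}.
#' @param min_months inclusion threshold in months.
#' @return filtered phenotype data.frame with attribute \code{"n_removed"}.
#' @export
apply_inclusion <- function(phenos, min_months = 6) {
  check_columns(phenos, "months_on_lithium", "phenotype table")
  keep <- !is.na(phenos$months_on_lithium) &
    phenos$months_on_lithium >= min_months
  out <- phenos[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Full phenotype derivation for a cohort
#'
#' Applies the duration inclusion rule, then derives the ALDA total, the
#' categorical responder status, and the continuous outcome with its
#' exclusion bookkeeping.
#'
#' @inheritParams derive_continuous_outcome
#' @inheritParams apply_inclusion
#' @return list with \code{outcomes} (one row per included sample) and
#'   \code{phenos} (the included phenotype rows, same order).
#' @export
derive_outcomes <- function(phenos, definition = "total", min_months = 6) {
  phenos <- apply_inclusion(phenos, min_months)
  out <- derive_continuous_outcome(phenos, definition)
  list(outcomes = out, phenos = phenos)
}
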