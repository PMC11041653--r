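## Pre- and post-imputation genotype quality control and cross-cohort merge.
##
## Pre-imputation variant filters (applied to hard calls, in order): call
## rate >= 95%, no strand-ambiguous A/T-C/G pairs, MAF >= 1%, exact
## Hardy-Weinberg p >= 1e-6. Sample filters: call rate, genetic relatedness
## (kinship from a standardized-genotype relationship matrix), recorded-vs-
## genetic sex consistency. Post-imputation: MAF >= 10% and imputation info
## R-square >= 0.6.

new_qc_report <- function(stage, thresholds) {
  structure(list(stage = stage, thresholds = thresholds,
                 steps = data.frame(filter = character(0),
                                    removed = integer(0),
                                    kept = integer(0),
                                    stringsAsFactors = FALSE)),
            class = "qc_report")
}

add_qc_step <- function(report, filter, removed, kept) {
  report$steps <- rbind(report$steps,
                        data.frame(filter = filter, removed = removed,
                                   kept = kept, stringsAsFactors = FALSE))
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%s stage)\n", x$stage))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %-22s removed %6d, kept %6d\n",
                x$steps$filter[i], x$steps$removed[i], x$steps$kept[i]))
  }
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Preferred over the
#' chi-square approximation because the QC threshold (1e-6) sits in the far
#' tail.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return two-sided exact p-value; \code{NA} for an all-missing variant
#'   (zero total count).
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  assert_that(all(c(n_AA, n_Aa, n_aa) >= 0), "negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) return(NA_real_)
  n_a <- 2L * n_aa + n_Aa            # rare-or-not, conditioning handles it
  n_A <- 2L * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0L) return(1)          # monomorphic: single possible table
  ## feasible heterozygote counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  ## log P(n_Aa = h | n, allele counts), up to a common constant
  logp <- lgamma(n + 1) - lgamma((n_A - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((n_a - hets) / 2 + 1) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

.hard_call_counts <- function(g) {
  g <- g[!is.na(g)]
  c(n_AA = sum(g == 2), n_Aa = sum(g == 1), n_aa = sum(g == 0))
}

#' Pre-imputation variant filters
#'
#' Keeps a variant iff (in order): call rate >= \code{call_rate_min}, allele
#' pair not strand-ambiguous (A/T, C/G), MAF >= \code{maf_min}, and exact
#' HWE p >= \code{hwe_p_min}. Each step's removals are attributed in the
#' report in that order.
#'
#' @param G samples x variants hard-call dosage matrix.
#' @param variants variant table aligned to \code{G}'s columns.
#' @param call_rate_min,maf_min,hwe_p_min,drop_ambiguous thresholds.
#' @return list \code{G}, \code{variants}, \code{report}.
#' @export
filter_variants_pre <- function(G, variants, call_rate_min = 0.95,
                                maf_min = 0.01, hwe_p_min = 1e-6,
                                drop_ambiguous = TRUE) {
  assert_that(ncol(G) == nrow(variants), "G / variant table shape mismatch")
  report <- new_qc_report("pre-imputation",
                          list(call_rate_min = call_rate_min,
                               maf_min = maf_min, hwe_p_min = hwe_p_min,
                               drop_ambiguous = drop_ambiguous))
  keep <- rep(TRUE, ncol(G))

  call_rate <- colMeans(!is.na(G))
  fail <- call_rate < call_rate_min
  report <- add_qc_step(report, "variant_call_rate", sum(fail & keep),
                        sum(keep & !fail))
  keep <- keep & !fail

  if (drop_ambiguous) {
    fail <- is_ambiguous_pair(variants$allele_effect, variants$allele_other)
    report <- add_qc_step(report, "strand_ambiguity", sum(fail & keep),
                          sum(keep & !fail))
    keep <- keep & !fail
  }

  maf <- compute_maf(G)
  fail <- is.na(maf) | maf < maf_min
  report <- add_qc_step(report, "maf", sum(fail & keep), sum(keep & !fail))
  keep <- keep & !fail

  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    if (!keep[j]) return(NA_real_)
    cc <- .hard_call_counts(G[, j])
    hwe_exact_test(cc[1L], cc[2L], cc[3L])
  }, numeric(1L))
  fail <- keep & !is.na(hwe_p) & hwe_p < hwe_p_min
  report <- add_qc_step(report, "hwe_exact", sum(fail), sum(keep & !fail))
  keep <- keep & !fail

  list(G = G[, keep, drop = FALSE],
       variants = {
         v <- variants[keep, , drop = FALSE]
         v$maf <- maf[keep]
         rownames(v) <- NULL
         v
       },
       report = report)
}

#' Kinship matrix from standardized genotypes
#'
#' \code{X X' / (2 M)} with \code{X} the mean-imputed, column-standardized
#' dosage matrix; diagonal ~ 0.5, duplicates/MZ twins ~ 0.5 off-diagonal,
#' full sibs ~ 0.25, third-degree ~ 0.0625.
#'
#' @param G samples x variants dosage matrix.
#' @return symmetric samples x samples kinship matrix.
#' @export
kinship_matrix <- function(G) {
  X <- standardize_dosages(G)
  tcrossprod(X) / (2 * ncol(X))
}

#' Sample-level QC filters
#'
#' Removes (in order) samples with call rate below \code{call_rate_min},
#' samples whose recorded sex disagrees with the genetic sex (when
#' \code{check_sex} and a \code{genetic_sex} column is available -- with
#' array data this would be derived from X heterozygosity; the simulator
#' provides it directly), and one member of each pair with estimated kinship
#' above \code{kinship_max} (the member with the lower call rate; ties broken
#' by removing the lexicographically later id).
#'
#' @param G samples x variants dosage matrix.
#' @param samples character vector of sample ids aligned to rows of \code{G}.
#' @param phenos phenotype table (used for the sex check), or NULL.
#' @param call_rate_min,kinship_max,check_sex thresholds.
#' @return list \code{G}, \code{samples}, \code{report}.
#' @export
filter_samples <- function(G, samples, phenos = NULL, call_rate_min = 0.95,
                           kinship_max = 0.125, check_sex = TRUE) {
  assert_that(nrow(G) == length(samples), "G / sample id length mismatch")
  report <- new_qc_report("sample",
                          list(call_rate_min = call_rate_min,
                               kinship_max = kinship_max,
                               check_sex = check_sex))
  keep <- rep(TRUE, length(samples))

  call_rate <- rowMeans(!is.na(G))
  fail <- call_rate < call_rate_min
  report <- add_qc_step(report, "sample_call_rate", sum(fail),
                        sum(!fail))
  keep <- keep & !fail

  if (check_sex && !is.null(phenos) && "genetic_sex" %in% names(phenos)) {
    gx <- phenos$genetic_sex[match(samples, phenos$sample_id)]
    rx <- phenos$sex[match(samples, phenos$sample_id)]
    fail <- keep & !is.na(gx) & !is.na(rx) & gx != rx
    report <- add_qc_step(report, "sex_mismatch", sum(fail),
                          sum(keep & !fail))
    keep <- keep & !fail
  }

  idx <- which(keep)
  if (length(idx) > 1L) {
    K <- kinship_matrix(G[idx, , drop = FALSE])
    pairs <- which(upper.tri(K) & K > kinship_max, arr.ind = TRUE)
    if (nrow(pairs) > 0L) {
      ord <- order(K[pairs], decreasing = TRUE)
      pairs <- pairs[ord, , drop = FALSE]
      dropped <- logical(length(idx))
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        if (dropped[i] || dropped[j]) next
        cr_i <- call_rate[idx[i]]; cr_j <- call_rate[idx[j]]
        if (cr_i < cr_j) {
          dropped[i] <- TRUE
        } else if (cr_j < cr_i) {
          dropped[j] <- TRUE
        } else {
          # tie: drop the lexicographically later id
          if (samples[idx[i]] > samples[idx[j]]) dropped[i] <- TRUE
          else dropped[j] <- TRUE
        }
      }
      keep[idx[dropped]] <- FALSE
      report <- add_qc_step(report, "relatedness", sum(dropped), sum(keep))
    } else {
      report <- add_qc_step(report, "relatedness", 0L, sum(keep))
    }
  }

  list(G = G[keep, , drop = FALSE], samples = samples[keep],
       report = report)
}

#' Post-imputation variant filters
#'
#' Keeps variants with MAF >= \code{maf_min} and imputation info R-square
#' >= \code{info_min}; both boundaries inclusive.
#'
#' @param variants variant table with \code{maf} and \code{info_r2}.
#' @param maf_min,info_min thresholds.
#' @return list \code{variants} (filtered), \code{keep} (logical index into
#'   the input), \code{report}.
#' @export
filter_variants_post <- function(variants, maf_min = 0.10, info_min = 0.6) {
  report <- new_qc_report("post-imputation",
                          list(maf_min = maf_min, info_min = info_min))
  if (!is.null(info_min) && all(is.na(variants$info_r2))) {
    stop_lipgs("info_r2 is missing for all variants but info_min = %g is set",
               info_min)
  }
  keep <- !is.na(variants$maf) & variants$maf >= maf_min
  report <- add_qc_step(report, "maf_post", sum(!keep), sum(keep))
  if (!is.null(info_min)) {
    fail <- keep & (is.na(variants$info_r2) | variants$info_r2 < info_min)
    report <- add_qc_step(report, "info_r2", sum(fail), sum(keep & !fail))
    keep <- keep & !fail
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(variants = out, keep = keep, report = report)
}

#' Merge cohorts on their common variants
#'
#' Intersects cohorts on (chrom, pos, unordered allele pair), drops position
#' matches whose allele pairs disagree, harmonizes the effect-allele
#' orientation of every cohort to the first (flipping dosages d -> 2 - d
#' where the recorded effect allele is the first cohort's other allele), and
#' row-binds the samples.
#'
#' @param cohorts list of >= 2 lists, each with \code{G}, \code{variants},
#'   and optionally \code{samples}.
#' @return list \code{G}, \code{variants} (first cohort's orientation),
#'   \code{samples}, \code{report}.
#' @export
merge_cohorts <- function(cohorts) {
  assert_that(length(cohorts) >= 2L, "merge_cohorts needs >= 2 cohorts")
  keys <- lapply(cohorts, function(co) {
    v <- co$variants
    paste(v$chrom, v$pos_bp, sep = ":")
  })
  common_pos <- Reduce(intersect, keys)
  report <- new_qc_report("merge", list(n_cohorts = length(cohorts)))

  ref <- cohorts[[1L]]$variants
  ref_idx <- match(common_pos, keys[[1L]])
  ref_pair <- variant_key(ref$chrom[ref_idx], ref$pos_bp[ref_idx],
                          ref$allele_effect[ref_idx],
                          ref$allele_other[ref_idx])
  ok <- rep(TRUE, length(common_pos))
  for (c_i in seq_along(cohorts)[-1L]) {
    v <- cohorts[[c_i]]$variants
    i <- match(common_pos, keys[[c_i]])
    pair <- variant_key(v$chrom[i], v$pos_bp[i], v$allele_effect[i],
                        v$allele_other[i])
    ok <- ok & pair == ref_pair
  }
  report <- add_qc_step(report, "allele_pair_mismatch", sum(!ok), sum(ok))
  common_pos <- common_pos[ok]
  if (length(common_pos) == 0L) {
    stop_lipgs("merge_cohorts: no common variants across cohorts")
  }
  ref_idx <- match(common_pos, keys[[1L]])

  blocks <- vector("list", length(cohorts))
  samples <- character(0)
  n_flipped <- 0L
  for (c_i in seq_along(cohorts)) {
    co <- cohorts[[c_i]]
    i <- match(common_pos, keys[[c_i]])
    Gc <- co$G[, i, drop = FALSE]
    flip <- co$variants$allele_effect[i] != ref$allele_effect[ref_idx]
    if (any(flip)) {
      Gc[, flip] <- 2 - Gc[, flip, drop = FALSE]
      if (c_i > 1L) n_flipped <- n_flipped + sum(flip)
    }
    blocks[[c_i]] <- Gc
    samples <- c(samples, co$samples %||% rownames(co$G) %||%
                   paste0("cohort", c_i, "_s", seq_len(nrow(co$G))))
  }
  report <- add_qc_step(report, "allele_flip", n_flipped,
                        length(common_pos))
  G <- do.call(rbind, blocks)
  variants <- ref[ref_idx, , drop = FALSE]
  variants$maf <- compute_maf(G)
  rownames(variants) <- NULL
  rownames(G) <- samples
  list(G = G, variants = variants, samples = samples, report = report)
}
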