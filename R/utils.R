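## Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lipgs <- function(fmt, ..., class = "lipgs_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_lipgs(fmt, ...)
  invisible(TRUE)
}

## Column presence check that names the first missing column.
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop_lipgs("%s is missing required column '%s'", what, miss[[1L]])
  }
  invisible(TRUE)
}

## Deterministic row order for tabular outputs: chrom, pos, id.
order_variants <- function(df) {
  df[order(df$chrom, df$pos_bp, df$variant_id), , drop = FALSE]
}

## Mean-impute missing dosages per variant (columns of G). Never persisted.
impute_dosage_mean <- function(g) {
  if (anyNA(g)) {
    m <- mean(g, na.rm = TRUE)
    if (is.nan(m)) m <- 0
    g[is.na(g)] <- m
  }
  g
}

## Column-standardize a dosage matrix after mean imputation; zero-variance
## columns become all-zero rather than NaN.
standardize_dosages <- function(G) {
  G <- apply(G, 2L, impute_dosage_mean)
  mu <- colMeans(G)
  sdv <- apply(G, 2L, stats::sd)
  sdv[sdv < .Machine$double.eps] <- Inf
  sweep(sweep(G, 2L, mu, "-"), 2L, sdv, "/")
}

## Balanced partition of n items into k groups: sizes differ by <= 1,
## remainder assigned to the lowest-numbered groups.
balanced_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + as.integer(seq_len(k) <= rem)
}

is_ambiguous_pair <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(a1) & !is.na(a2) & nchar(a1) == 1L & nchar(a2) == 1L &
    comp[a1] == a2
}

## Stable key for a variant position + unordered allele pair.
variant_key <- function(chrom, pos, a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  paste(chrom, pos, lo, hi, sep = ":")
}
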