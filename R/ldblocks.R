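## Block-diagonal LD references for summary-statistics posterior inference.

#' Build block LD correlation matrices from reference genotypes
#'
#' Computes the Pearson correlation of standardized dosages within each
#' block. Blocks must partition the variants. Near-singular blocks are
#' repaired by an eigenvalue floor: a ridge shift \code{lambda I} followed by
#' diagonal renormalization, sized so the smallest eigenvalue reaches the
#' floor.
#'
#' @param G_reference samples x variants reference dosage matrix.
#' @param block_index integer vector (length = n variants) assigning each
#'   variant to a block; blocks are the runs of equal values in order.
#' @param eig_floor smallest admissible eigenvalue after repair.
#' @return object of class \code{ld_blocks}: list of blocks, each with
#'   \code{idx} (variant indices) and \code{R} (unit-diagonal correlation
#'   matrix).
#' @export
build_ld_blocks <- function(G_reference, block_index, eig_floor = 1e-3) {
  m <- ncol(G_reference)
  assert_that(length(block_index) == m,
              "block_index length (%d) != number of variants (%d)",
              length(block_index), m)
  sdv <- apply(G_reference, 2L, function(g) stats::sd(g, na.rm = TRUE))
  zero <- which(is.na(sdv) | sdv < .Machine$double.eps)
  if (length(zero) > 0L) {
    nm <- colnames(G_reference)[zero] %||% as.character(zero)
    stop_lipgs("zero-variance variant(s) in LD reference: %s",
               paste(utils::head(nm, 5L), collapse = ", "))
  }
  X <- standardize_dosages(G_reference)
  groups <- split(seq_len(m), block_index)
  ## preserve variant order of the blocks
  groups <- groups[order(vapply(groups, min, integer(1L)))]
  blocks <- lapply(groups, function(idx) {
    R <- if (length(idx) == 1L) matrix(1, 1, 1)
    else stats::cor(X[, idx, drop = FALSE])
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    lo <- min(ev)
    if (lo < eig_floor) {
      shift <- (eig_floor - lo) / (1 - eig_floor) + 1e-12
      R <- (R + diag(shift, nrow(R))) / (1 + shift)
    }
    list(idx = idx, R = R)
  })
  structure(blocks, class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  sizes <- vapply(x, function(b) length(b$idx), integer(1L))
  cat(sprintf("LD reference: %d blocks over %d variants (sizes %d..%d)\n",
              length(x), sum(sizes), min(sizes), max(sizes)))
  invisible(x)
}
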