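## Gene-based multi-marker association and pathway overrepresentation.
##
## The gene test follows the multi-marker principal-components-regression
## idea: the standardized dosages of a gene's variants are reduced to the
## components carrying 99.9% of their variance (absorbing LD and rank
## deficiency), entered jointly into a linear model next to the covariates,
## and judged by the F test of the joint null. Pathway enrichment is the
## one-sided Fisher exact (hypergeometric) test against a reference gene
## list with Bonferroni correction over the tested pathways.

#' Assign variants to genes
#'
#' A variant belongs to every gene whose window
#' \code{[start_bp - window_up_bp, end_bp + window_down_bp]} contains its
#' position (1-based inclusive, same chromosome). Multi-assignment is
#' allowed.
#'
#' @param variants variant table.
#' @param genes gene table from \code{\link{read_gene_annotation}}.
#' @param window_up_bp,window_down_bp flanking windows in bp.
#' @return named list (gene_id -> integer vector of variant indices);
#'   genes without variants map to an empty vector.
#' @export
map_snps_to_genes <- function(variants, genes, window_up_bp = 0L,
                              window_down_bp = 0L) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    which(variants$chrom == genes$chrom[i] &
            variants$pos_bp >= genes$start_bp[i] - window_up_bp &
            variants$pos_bp <= genes$end_bp[i] + window_down_bp)
  })
  names(out) <- genes$gene_id
  out
}

#' Multi-marker gene association test
#'
#' Principal components of the gene's standardized dosage submatrix
#' retaining 99.9% of variance (components with eigenvalue < 1e-8 dropped)
#' are tested jointly against the outcome by the F test of the full linear
#' model (covariates + gene components) versus the covariate-only model.
#' Binary outcomes are coded 0/1 and fit on the linear scale.
#'
#' @param y outcome (binary good/poor or continuous).
#' @param G_gene samples x variants dosage submatrix for the gene.
#' @param covariates covariate matrix or NULL.
#' @param var_keep fraction of variance the retained components must carry.
#' @return list \code{p}, \code{n_components}, \code{flag}.
#' @export
gene_test <- function(y, G_gene, covariates = NULL, var_keep = 0.999) {
  if (is.character(y) || is.factor(y) || is.logical(y)) {
    y <- .as_binary_outcome(y)
  }
  rows <- which(!is.na(y) &
                  (if (is.null(covariates)) TRUE
                   else stats::complete.cases(covariates)))
  y <- y[rows]
  G_gene <- G_gene[rows, , drop = FALSE]
  X <- standardize_dosages(G_gene)
  X <- X[, apply(X, 2L, stats::sd) > 0, drop = FALSE]
  if (ncol(X) == 0L) {
    return(list(p = NA_real_, n_components = 0L, flag = "no_usable_variants"))
  }
  sv <- svd(X)
  ev <- sv$d^2 / nrow(X)
  keep <- ev >= 1e-8
  cum <- cumsum(ev[keep]) / sum(ev[keep])
  k <- min(which(cum >= var_keep))
  PC <- sv$u[, seq_len(k), drop = FALSE]

  C <- cbind(rep(1, length(y)),
             if (is.null(covariates)) NULL else covariates[rows, ,
                                                           drop = FALSE])
  fit0 <- stats::lm.fit(C, y)
  fit1 <- stats::lm.fit(cbind(C, PC), y)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  df1 <- k
  df2 <- length(y) - ncol(C) - k
  if (df2 <= 0L || rss1 <= 0) {
    return(list(p = NA_real_, n_components = k, flag = "saturated"))
  }
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(p = stats::pf(f, df1, df2, lower.tail = FALSE),
       n_components = k, flag = "ok")
}

#' Gene-level scan over an annotation
#'
#' Runs \code{\link{gene_test}} for every gene with at least one assigned
#' variant.
#'
#' @param G,variants cohort genotypes.
#' @param genes gene table.
#' @param y outcome.
#' @param covariates covariate matrix or NULL.
#' @param window_up_bp,window_down_bp assignment windows.
#' @return data.frame \code{gene_id, n_variants, n_components, p, flag}.
#' @export
run_gene_scan <- function(G, variants, genes, y, covariates = NULL,
                          window_up_bp = 0L, window_down_bp = 0L) {
  assign <- map_snps_to_genes(variants, genes, window_up_bp,
                              window_down_bp)
  res <- lapply(names(assign), function(g) {
    idx <- assign[[g]]
    if (length(idx) == 0L) {
      return(data.frame(gene_id = g, n_variants = 0L, n_components = 0L,
                        p = NA_real_, flag = "no_variants"))
    }
    r <- gene_test(y, G[, idx, drop = FALSE], covariates)
    data.frame(gene_id = g, n_variants = length(idx),
               n_components = r$n_components, p = r$p, flag = r$flag)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select genes passing the gene-level threshold in either outcome
#'
#' Union of genes with gene-level p strictly below \code{p_threshold} in
#' any of the supplied scans, deduplicated and sorted.
#'
#' @param ... one or more gene-scan data.frames (e.g. the categorical and
#'   the continuous outcome scans).
#' @param p_threshold strict upper bound on the gene p-value.
#' @return sorted character vector of gene ids.
#' @export
select_genes <- function(..., p_threshold = 0.001) {
  scans <- list(...)
  hits <- unlist(lapply(scans, function(s) {
    s$gene_id[!is.na(s$p) & s$p < p_threshold]
  }))
  sort(unique(hits))
}

#' Pathway overrepresentation by the one-sided Fisher exact test
#'
#' For each pathway, tests whether the input genes over-represent the
#' pathway relative to the reference list, from the 2x2 table
#' (in-set/out-of-set x input/non-input); p-values are the hypergeometric
#' upper tail, Bonferroni-corrected over the tested pathways, flagged
#' significant at corrected p < 0.05.
#'
#' @param input_genes character vector (must be a subset of
#'   \code{reference_genes}).
#' @param pathways named list of gene sets (see \code{\link{read_gmt}});
#'   sets are intersected with the reference.
#' @param reference_genes the reference gene universe.
#' @param alpha significance level on the corrected p.
#' @return data.frame \code{pathway, k_in, K_set, n_in, N_ref, p_fisher,
#'   p_bonferroni, significant}, ordered by \code{p_fisher}.
#' @export
fisher_enrichment <- function(input_genes, pathways, reference_genes,
                              alpha = 0.05) {
  assert_that(length(input_genes) > 0L, "fisher_enrichment: empty input")
  assert_that(all(input_genes %in% reference_genes),
              "fisher_enrichment: input genes outside the reference list")
  input_genes <- unique(input_genes)
  N <- length(unique(reference_genes))
  n_in <- length(input_genes)
  m <- length(pathways)
  rows <- lapply(names(pathways), function(nm) {
    set <- intersect(pathways[[nm]], reference_genes)
    K <- length(set)
    k <- length(intersect(set, input_genes))
    ## hypergeometric upper tail P(X >= k)
    p <- stats::phyper(k - 1L, K, N - K, n_in, lower.tail = FALSE)
    data.frame(pathway = nm, k_in = k, K_set = K, n_in = n_in, N_ref = N,
               p_fisher = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_fisher * m)
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p_fisher, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
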