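## Tabular I/O: GWAS summary statistics, phenotype/covariate tables,
## BED-like gene annotation, and GMT pathway sets.

SUMMARY_STATS_COLUMNS <- c("variant_id", "chrom", "pos_bp", "allele_effect",
                           "allele_other", "freq", "beta", "se", "z", "p",
                           "n")

#' Validate a summary-statistics table
#'
#' Checks the fixed column set, \code{p} in (0, 1], positive \code{n}, and
#' consistency of \code{z} with \code{beta / se}.
#'
#' @param stats data.frame of per-variant association results.
#' @return invisibly, the validated table.
#' @export
validate_summary_stats <- function(stats) {
  check_columns(stats, SUMMARY_STATS_COLUMNS, "summary statistics")
  ok_p <- is.na(stats$p) | (stats$p > 0 & stats$p <= 1)
  assert_that(all(ok_p), "summary statistics: p outside (0, 1] at variant %s",
              stats$variant_id[which(!ok_p)[1L]])
  ok_n <- is.na(stats$n) | stats$n > 0
  assert_that(all(ok_n), "summary statistics: nonpositive n at variant %s",
              stats$variant_id[which(!ok_n)[1L]])
  invisible(stats)
}

#' Write / read GWAS summary statistics as TSV
#'
#' Fixed header \code{variant_id, chrom, pos_bp, allele_effect, allele_other,
#' freq, beta, se, z, p, n}; numbers serialized at 15 significant digits so a
#' write/read cycle is stable to at least 12 significant digits. Rows are
#' written in deterministic (chrom, pos, id) order.
#'
#' @param stats summary-statistics data.frame.
#' @param path output TSV path.
#' @return \code{write_summary_stats}: invisibly, the path;
#'   \code{read_summary_stats}: the validated data.frame.
#' @export
write_summary_stats <- function(stats, path) {
  validate_summary_stats(stats)
  out <- order_variants(stats)[, SUMMARY_STATS_COLUMNS]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.15g", x))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  assert_that(file.exists(path), "summary statistics file not found: %s",
              path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(variant_id = "character",
                                         chrom = "character",
                                         allele_effect = "character",
                                         allele_other = "character"))
  validate_summary_stats(df)
  df
}

#' Read a phenotype/covariate table
#'
#' TSV with columns \code{sample_id, alda_a, alda_b1..alda_b5,
#' months_on_lithium, age_years, sex, chip, cohort} (extra columns such as
#' \code{genetic_sex} are carried through). Subscale ranges are enforced on
#' load; missing values must be encoded as empty fields or \code{NA}, never
#' as sentinel numbers.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample.
#' @export
read_phenotypes <- function(path) {
  assert_that(file.exists(path), "phenotype file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param phenos in-memory phenotype data.frame to validate.
#' @export
validate_phenotypes <- function(phenos) {
  check_columns(phenos,
                c("sample_id", "alda_a", paste0("alda_b", 1:5),
                  "months_on_lithium", "age_years", "sex", "chip", "cohort"),
                "phenotype table")
  assert_that(anyDuplicated(phenos$sample_id) == 0L,
              "phenotype table: duplicate sample_id")
  rng <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  assert_that(rng(phenos$alda_a, 0, 10),
              "phenotype table: alda_a outside 0..10")
  for (b in paste0("alda_b", 1:5)) {
    assert_that(rng(phenos[[b]], 0, 2),
                "phenotype table: %s outside 0..2", b)
  }
  assert_that(rng(phenos$months_on_lithium, 0, Inf),
              "phenotype table: negative months_on_lithium")
  assert_that(all(is.na(phenos$sex) | phenos$sex %in% c("female", "male")),
              "phenotype table: sex must be 'female' or 'male'")
  phenos
}

#' Write a phenotype table as TSV
#' @param phenos phenotype data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_phenotypes <- function(phenos, path) {
  utils::write.table(phenos, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read gene annotation (BED-like TSV)
#'
#' Input columns \code{chrom, start, end, gene_id} in 0-based half-open BED
#' convention; converted on load to 1-based inclusive coordinates
#' (\code{start_bp = start + 1, end_bp = end}) to match the bim convention
#' used everywhere else in the package.
#'
#' @param path TSV path (with header).
#' @return data.frame \code{gene_id, chrom, start_bp, end_bp}.
#' @export
read_gene_annotation <- function(path) {
  assert_that(file.exists(path), "gene annotation file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_columns(df, c("chrom", "start", "end", "gene_id"),
                sprintf("gene annotation %s", path))
  assert_that(all(df$start < df$end),
              "gene annotation: start must be < end (0-based half-open)")
  out <- data.frame(gene_id = df$gene_id,
                    chrom = as.character(df$chrom),
                    start_bp = as.integer(df$start) + 1L,
                    end_bp = as.integer(df$end),
                    stringsAsFactors = FALSE)
  assert_that(anyDuplicated(out$gene_id) == 0L,
              "gene annotation: duplicate gene_id")
  out
}

#' Read pathway sets in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated fields \code{name},
#' \code{description}, then member gene symbols. Duplicate genes within a
#' set are dropped with a warning; pathway names must be unique.
#'
#' @param path GMT file path.
#' @return named list of character vectors (pathway name -> unique genes).
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(), names = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1L)) < 3L)
  if (length(short) > 0L) {
    stop_lipgs("GMT line %d in %s has fewer than 3 tab-separated fields",
               short[[1L]], path)
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  assert_that(anyDuplicated(nm) == 0L, "GMT %s: duplicate pathway name '%s'",
              path, nm[duplicated(nm)][1L])
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes) > 0L) {
      warning(sprintf("GMT set '%s': duplicate genes deduplicated", nm[i]))
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nm
  sets
}

#' Write pathway sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
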