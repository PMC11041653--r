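## PLINK 1 binary (bed/bim/fam) and dosage-TSV genotype I/O.
##
## Conventions: coordinates are 1-based (bim convention); dosages count
## copies of the effect allele, which is bim allele 1 (the "A1" column);
## missing hard calls are NA, never a sentinel value.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

## 2-bit genotype codes in a SNP-major bed, mapped to dosage of allele 1:
## 00 -> 2 copies of A1, 01 -> missing, 10 -> het, 11 -> 0 copies of A1.
.bed_code_to_dosage <- c(2, NA, 1, 0)

## 256 x 4 lookup: dosages of the four samples packed in one byte.
.bed_byte_lut <- local({
  m <- matrix(NA_real_, nrow = 256L, ncol = 4L)
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      m[b + 1L, s + 1L] <- .bed_code_to_dosage[code + 1L]
    }
  }
  m
})

.dosage_to_bed_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  code
}

#' Read genotypes from PLINK 1 binary or a dosage TSV
#'
#' Reads an \code{N x M} dosage matrix together with its variant metadata and
#' sample identifiers. For \code{format = "plink1"}, \code{path} is the file
#' prefix of a \code{.bed}/\code{.bim}/\code{.fam} triplet in SNP-major
#' layout; dosages count copies of bim allele 1 (the effect allele).
#' For \code{format = "dosage_tsv"}, \code{path} is a single TSV with columns
#' \code{variant_id, chrom, pos_bp, allele_effect, allele_other} followed by
#' one column per sample holding dosages in \code{[0, 2]} (empty/NA =
#' missing).
#'
#' @param path file prefix (plink1) or file path (dosage_tsv).
#' @param format one of \code{"plink1"}, \code{"dosage_tsv"}.
#' @return list with \code{G} (samples x variants dosage matrix, dimnames
#'   set), \code{variants} (variant table: \code{variant_id, chrom, pos_bp,
#'   allele_effect, allele_other, maf, info_r2}), and \code{samples}
#'   (character vector of sample ids). Variant and sample order are preserved
#'   from the files.
#' @export
read_genotypes <- function(path, format = c("plink1", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "plink1") .read_plink1(path) else .read_dosage_tsv(path)
}

.read_plink1 <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    assert_that(file.exists(f), "genotype file not found: %s", f)
  }
  bim_df <- utils::read.table(bim, header = FALSE, sep = "\t",
                              colClasses = c("character", "character",
                                             "numeric", "integer",
                                             "character", "character"))
  names(bim_df) <- c("chrom", "variant_id", "cm", "pos_bp",
                     "allele1", "allele2")
  fam_df <- utils::read.table(fam, header = FALSE,
                              colClasses = "character")
  assert_that(ncol(fam_df) >= 2L, "fam file %s has fewer than 2 columns", fam)
  samples <- fam_df[[2L]]
  n <- length(samples)
  m <- nrow(bim_df)
  assert_that(anyDuplicated(bim_df$variant_id) == 0L,
              "duplicate variant_id in %s", bim)

  bad <- !grepl("^[ACGT]+$", bim_df$allele1) |
    !grepl("^[ACGT]+$", bim_df$allele2)
  if (any(bad)) {
    stop_lipgs("unknown allele codes in %s for variants: %s", bim,
               paste(utils::head(bim_df$variant_id[bad], 10L),
                     collapse = ", "))
  }

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  assert_that(length(raw) >= 3L && identical(raw[1:3], BED_MAGIC),
              "%s is not a PLINK 1 bed file (bad magic bytes)", bed)
  bpv <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpv * m) {
    stop_lipgs(paste0("bed/bim/fam dimension mismatch in %s: ",
                      "%d bytes found, %d expected for %d samples x %d ",
                      "variants"),
               bed, length(body), bpv * m, n, m)
  }
  bytes <- matrix(as.integer(body), nrow = bpv, ncol = m)
  G <- matrix(NA_real_, nrow = n, ncol = m)
  for (s in 1:4) {
    rows <- seq.int(s, n, by = 4L)
    if (length(rows) > 0L) {
      G[rows, ] <- .bed_byte_lut[bytes[seq_along(rows), , drop = FALSE] + 1L,
                                 s]
    }
  }
  dimnames(G) <- list(samples, bim_df$variant_id)
  variants <- data.frame(
    variant_id = bim_df$variant_id,
    chrom = bim_df$chrom,
    pos_bp = bim_df$pos_bp,
    allele_effect = bim_df$allele1,
    allele_other = bim_df$allele2,
    maf = compute_maf(G),
    info_r2 = NA_real_,
    stringsAsFactors = FALSE
  )
  list(G = G, variants = variants, samples = samples)
}

.read_dosage_tsv <- function(path) {
  assert_that(file.exists(path), "genotype file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos_bp", "allele_effect",
                 "allele_other")
  check_columns(df, meta_cols, sprintf("dosage TSV %s", path))
  samp_cols <- setdiff(names(df), c(meta_cols, "info_r2"))
  assert_that(length(samp_cols) > 0L, "dosage TSV %s has no sample columns",
              path)
  D <- as.matrix(df[, samp_cols, drop = FALSE])
  storage.mode(D) <- "double"
  bad <- which(!is.na(D) & (D < 0 | D > 2), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_lipgs(
      "dosage out of [0, 2] in %s at variant '%s', sample column '%s'",
      path, df$variant_id[bad[1L, 1L]], samp_cols[bad[1L, 2L]])
  }
  G <- t(D)
  dimnames(G) <- list(samp_cols, df$variant_id)
  variants <- data.frame(
    variant_id = df$variant_id,
    chrom = as.character(df$chrom),
    pos_bp = as.integer(df$pos_bp),
    allele_effect = df$allele_effect,
    allele_other = df$allele_other,
    maf = compute_maf(G),
    info_r2 = if ("info_r2" %in% names(df)) df$info_r2 else NA_real_,
    stringsAsFactors = FALSE
  )
  list(G = G, variants = variants, samples = samp_cols)
}

#' Write genotypes to PLINK 1 binary files
#'
#' Writes hard-call dosages (values 0/1/2/NA) as a SNP-major
#' \code{.bed}/\code{.bim}/\code{.fam} triplet. Dosages are interpreted as
#' counts of \code{allele_effect}, stored as bim allele 1.
#'
#' @param G samples x variants dosage matrix with 0/1/2/NA entries.
#' @param variants variant table (\code{variant_id, chrom, pos_bp,
#'   allele_effect, allele_other}).
#' @param samples character vector of sample ids.
#' @param prefix output file prefix.
#' @return invisibly, the prefix.
#' @export
write_genotypes <- function(G, variants, samples, prefix) {
  assert_that(ncol(G) == nrow(variants),
              "G has %d variants but variant table has %d rows",
              ncol(G), nrow(variants))
  assert_that(nrow(G) == length(samples),
              "G has %d samples but %d sample ids given",
              nrow(G), length(samples))
  ok <- is.na(G) | G %in% c(0, 1, 2)
  assert_that(all(ok), "write_genotypes requires hard calls (0/1/2/NA)")
  n <- nrow(G)
  m <- ncol(G)
  bpv <- ceiling(n / 4)
  codes <- matrix(1L, nrow = 4L * bpv, ncol = m)  # pad with missing
  codes[seq_len(n), ] <- matrix(.dosage_to_bed_code(G), nrow = n)
  idx <- seq.int(1L, 4L * bpv, by = 4L)
  packed <- codes[idx, , drop = FALSE] +
    bitwShiftL(codes[idx + 1L, , drop = FALSE], 2L) +
    bitwShiftL(codes[idx + 2L, , drop = FALSE], 4L) +
    bitwShiftL(codes[idx + 3L, , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(as.vector(packed)), con)

  bim <- data.frame(variants$chrom, variants$variant_id, 0,
                    variants$pos_bp, variants$allele_effect,
                    variants$allele_other)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(samples, samples, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Minor allele frequency per variant
#'
#' @param G samples x variants dosage matrix (dosages of the effect allele).
#' @return numeric vector of per-variant MAF in \code{[0, 0.5]} (NA for
#'   all-missing variants).
#' @export
compute_maf <- function(G) {
  f <- colMeans(G, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}
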