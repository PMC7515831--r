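#' Construct a genotype matrix object
#'
#' Light container for a subjects x SNPs additive genotype matrix
#' (minor-allele counts 0/1/2, `NA` for missing calls) together with SNP
#' metadata and subject ids. This is the substrate for QC, biclustering and
#' kernel association tests.
#'
#' @param values integer matrix, subjects in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param snp_meta tibble with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `allele1` (minor), `allele2` (major). Generated if omitted.
#' @param subject_ids character vector of unique subject labels. Generated
#'   if omitted.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snp_meta = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  bad <- values[!is.na(values)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype values must be 0, 1, 2 or NA")
  }
  n <- nrow(values); m <- ncol(values)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values) %||% sprintf("S%04d", seq_len(n))
  }
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (is.null(snp_meta)) {
    snp_meta <- tibble::tibble(
      snp_id = colnames(values) %||% sprintf("rs%05d", seq_len(m)),
      chrom = 1L, pos = seq_len(m), allele1 = "A", allele2 = "B"
    )
  }
  snp_meta <- tibble::as_tibble(snp_meta)
  if (nrow(snp_meta) != m) stop("snp_meta rows must match ncol(values)")
  if (anyDuplicated(snp_meta$snp_id)) stop("snp ids must be unique")
  rownames(values) <- subject_ids
  colnames(values) <- snp_meta$snp_id
  structure(
    list(values = values, snp_meta = snp_meta, subject_ids = subject_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf(
    "<genotype_matrix> %d subjects x %d SNPs (%.2f%% missing)\n",
    nrow(x$values), ncol(x$values), 100 * miss
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by subjects and/or SNPs
#'
#' @param g a [genotype_matrix()].
#' @param subjects subject ids or indices (default all).
#' @param snps SNP ids or indices (default all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, subjects = NULL, snps = NULL) {
  i <- if (is.null(subjects)) seq_along(g$subject_ids) else {
    if (is.character(subjects)) match(subjects, g$subject_ids) else subjects
  }
  j <- if (is.null(snps)) seq_len(ncol(g$values)) else {
    if (is.character(snps)) match(snps, g$snp_meta$snp_id) else snps
  }
  if (anyNA(i)) stop("unknown subject id in `subjects`")
  if (anyNA(j)) stop("unknown SNP id in `snps`")
  genotype_matrix(
    g$values[i, j, drop = FALSE],
    snp_meta = g$snp_meta[j, , drop = FALSE],
    subject_ids = g$subject_ids[i]
  )
}

#' Per-SNP summary statistics
#'
#' Minor-allele frequency, call rate and genotype counts per SNP, computed
#' on non-missing calls.
#'
#' @param g a [genotype_matrix()].
#' @return A tibble with one row per SNP: `snp_id`, `maf`, `call_rate`,
#'   `n_aa`, `n_ab`, `n_bb` (aa = homozygous minor).
#' @export
snp_stats <- function(g) {
  v <- g$values
  called <- !is.na(v)
  n_called <- colSums(called)
  n2 <- colSums(v == 2L, na.rm = TRUE)
  n1 <- colSums(v == 1L, na.rm = TRUE)
  n0 <- n_called - n1 - n2
  af <- ifelse(n_called > 0, (2 * n2 + n1) / (2 * n_called), NA_real_)
  tibble::tibble(
    snp_id = g$snp_meta$snp_id,
    maf = pmin(af, 1 - af),
    call_rate = n_called / nrow(v),
    n_aa = as.integer(n2), n_ab = as.integer(n1), n_bb = as.integer(n0)
  )
}

# mean-impute missing genotypes (per SNP); used only inside PCA / kernels /
# factorization, never in per-SNP inference
impute_genotypes <- function(g) {
  v <- g$values
  storage.mode(v) <- "double"
  mu <- colMeans(v, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- mu[idx[, 2L]]
  v
}

## ---- PLINK binary trio -----------------------------------------------------
## The .bed format packs 4 genotypes per byte, SNP-major: 00 = homozygous
## minor (2 copies of allele1), 01 = missing, 10 = heterozygous, 11 =
## homozygous major. Magic bytes 0x6c 0x1b 0x01.

#' Write genotypes as a PLINK binary trio
#'
#' @param g a [genotype_matrix()].
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  v <- g$values
  n <- nrow(v); m <- ncol(v)
  # map dosage of allele1 -> 2-bit codes
  code <- matrix(3L, n, m)           # 11 homozygous major (dosage 0)
  code[v == 1L] <- 2L                # 10 het
  code[v == 2L] <- 0L                # 00 homozygous minor
  code[is.na(v)] <- 1L               # 01 missing
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4L - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, m))
  shifts <- rep(c(1L, 4L, 16L, 64L), bytes_per_snp)
  grp <- rep(seq_len(bytes_per_snp), each = 4L)
  packed <- vapply(seq_len(m), function(j) {
    as.raw(rowsum(code[, j] * shifts, grp)[, 1L])
  }, raw(bytes_per_snp))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(packed), con)
  fam <- data.frame(
    fid = g$subject_ids, iid = g$subject_ids, pat = 0L, mat = 0L,
    sex = 0L, pheno = -9L
  )
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(
    chrom = g$snp_meta$chrom, snp_id = g$snp_meta$snp_id, cm = 0,
    pos = g$snp_meta$pos, allele1 = g$snp_meta$allele1,
    allele2 = g$snp_meta$allele2
  )
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK binary trio into a genotype matrix
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` files.
#' @return A [genotype_matrix()]; values are counts of the `.bim` allele1.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
    colClasses = c("character", "character", "NULL", "NULL", "NULL", "NULL"))
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
    col.names = c("chrom", "snp_id", "cm", "pos", "allele1", "allele2"),
    colClasses = c("integer", "character", "numeric", "integer",
                   "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + bytes_per_snp * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  }
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes; lookup by code value -> dosage of allele1
  dosage_of <- c(2L, NA_integer_, 1L, 0L)  # codes 0,1,2,3
  v <- matrix(NA_integer_, n, m)
  for (s in 0:3) {
    bits <- bitwAnd(bitwShiftR(body, 2L * s), 3L)
    rows <- seq.int(s + 1L, bytes_per_snp * 4L, by = 4L)
    keep <- rows <= n
    dim(bits) <- c(bytes_per_snp, m)
    v[rows[keep], ] <- dosage_of[bits[keep, , drop = FALSE] + 1L]
  }
  meta <- tibble::as_tibble(bim)[, c("snp_id", "chrom", "pos",
                                     "allele1", "allele2")]
  genotype_matrix(v, snp_meta = meta, subject_ids = fam[[2L]])
}

#' Write a genotype matrix as TSV
#'
#' Plain-text alternative to the PLINK trio: one row per subject, one
#' column per SNP, missing as `NA`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes_tsv <- function(g, path) {
  df <- tibble::as_tibble(g$values, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(subject_id = g$subject_ids), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a genotype TSV written by [write_genotypes_tsv()]
#'
#' @param path input file; first column `subject_id`, remaining columns SNPs.
#' @param snp_meta optional SNP metadata tibble.
#' @return A [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path, snp_meta = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  genotype_matrix(v, snp_meta = snp_meta, subject_ids = df[[1L]])
}
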