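# Interchange with the GCTA/PLINK ecosystem: binary GRM triplets,
# PLINK bed/bim/fam genotypes, and FID/IID-keyed phenotype/covariate
# tables. Layouts are bit-exact so files round-trip with the upstream
# tools.

#' Write a relationship matrix as a GCTA binary GRM triplet
#'
#' Produces `<prefix>.grm.bin` (lower triangle including the diagonal,
#' row-wise, 4-byte little-endian floats), `<prefix>.grm.N.bin` (same
#' layout, per-pair marker counts) and `<prefix>.grm.id` (tab-separated
#' FID IID, one line per sample).
#'
#' @param grm A [relmat()].
#' @param prefix Path prefix (directories must exist).
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "relmat"))
  n <- nrow(grm$values)
  lower <- grm$values[upper.tri(grm$values, diag = TRUE)]
  # upper.tri by column of a symmetric matrix == lower triangle row-wise
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L, endian = "little")
  close(con)
  counts <- grm$pair_counts
  if (is.null(counts)) counts <- matrix(1, n, n)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(counts[upper.tri(counts, diag = TRUE)]), con,
           size = 4L, endian = "little")
  close(con)
  utils::write.table(
    data.frame(FID = grm$sample_ids, IID = grm$sample_ids),
    paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM triplet
#'
#' @param prefix Path prefix of the `.grm.bin`/`.grm.N.bin`/`.grm.id`
#'   triplet.
#' @param kind Kind tag for the returned matrix.
#' @return A [relmat()].
#' @export
read_grm <- function(prefix, kind = "G") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")
  n <- nrow(ids)
  n_el <- n * (n + 1) / 2
  read_tri <- function(path) {
    sz <- file.info(path)$size
    if (is.na(sz) || sz != 4 * n_el)
      stop(sprintf("%s: expected %d bytes for %d samples, found %s",
                   path, 4 * n_el, n, format(sz)), call. = FALSE)
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = n_el, size = 4L, endian = "little")
  }
  vals <- read_tri(paste0(prefix, ".grm.bin"))
  m <- matrix(0, n, n)
  m[upper.tri(m, diag = TRUE)] <- vals
  m <- m + t(m) - diag(diag(m))
  counts <- NULL
  npath <- paste0(prefix, ".grm.N.bin")
  if (file.exists(npath)) {
    cn <- read_tri(npath)
    counts <- matrix(0, n, n)
    counts[upper.tri(counts, diag = TRUE)] <- cn
    counts <- counts + t(counts) - diag(diag(counts))
  }
  relmat(m, ids[[2]], kind = kind, pair_counts = counts)
}

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' SNP-major bed layout (magic bytes 0x6c 0x1b 0x01), two bits per
#' genotype: 00 = two copies of the counted (A1) allele, 10 = one copy,
#' 11 = zero copies, 01 = missing. Alleles are written as A1 = "A",
#' A2 = "B" placeholders with dummy positions.
#'
#' @param genotypes A `genotypes` object or 0/1/2 count matrix.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  if (inherits(genotypes, "genotypes")) {
    counts <- genotypes$counts
    sample_ids <- genotypes$sample_ids
    snp_ids <- genotypes$snp_ids
  } else {
    counts <- as.matrix(genotypes)
    sample_ids <- rownames(counts) %||% sprintf("id%d", seq_len(nrow(counts)))
    snp_ids <- colnames(counts) %||% sprintf("snp%d", seq_len(ncol(counts)))
  }
  n <- nrow(counts); m <- ncol(counts)
  code <- c(`2` = 0L, `NA` = 1L, `1` = 2L, `0` = 3L)
  bytes_per_snp <- ceiling(n / 4)
  out <- raw(3 + bytes_per_snp * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pad <- bytes_per_snp * 4
  for (j in seq_len(m)) {
    x <- counts[, j]
    two_bit <- integer(pad)
    two_bit[seq_len(n)] <- ifelse(is.na(x), 1L, code[as.character(x)])
    b <- two_bit[seq(1, pad, 4)] + 4L * two_bit[seq(2, pad, 4)] +
      16L * two_bit[seq(3, pad, 4)] + 64L * two_bit[seq(4, pad, 4)]
    out[3 + (j - 1) * bytes_per_snp + seq_len(bytes_per_snp)] <- as.raw(b)
  }
  writeBin(out, paste0(prefix, ".bed"))
  utils::write.table(
    data.frame(chr = 1L, id = snp_ids, cm = 0, pos = seq_len(m),
               a1 = "A", a2 = "B"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(fid = sample_ids, iid = sample_ids, pat = 0L, mat = 0L,
               sex = 0L, phe = -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset into a genotype matrix
#'
#' Counts the A1 allele, mirroring [write_plink()].
#'
#' @param prefix Path prefix.
#' @return A `genotypes`-classed list (no sib-pair bookkeeping).
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw_all <- readBin(paste0(prefix, ".bed"), "raw",
                     n = 3 + bytes_per_snp * m)
  if (length(raw_all) < 3 + bytes_per_snp * m ||
      !identical(raw_all[1:3], as.raw(c(0x6c, 0x1b, 0x01))))
    stop("not a SNP-major PLINK bed file (bad magic or truncated)",
         call. = FALSE)
  decode <- c(2L, NA_integer_, 1L, 0L)  # two-bit codes 0..3
  counts <- matrix(NA_integer_, n, m)
  body <- as.integer(raw_all[-(1:3)])
  for (j in seq_len(m)) {
    b <- body[(j - 1) * bytes_per_snp + seq_len(bytes_per_snp)]
    two_bit <- c(rbind(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, b %/% 64))
    counts[, j] <- decode[two_bit[seq_len(n)] + 1L]
  }
  structure(list(counts = counts, sample_ids = fam[[2]], snp_ids = bim[[2]],
                 allele_freqs = colMeans(counts, na.rm = TRUE) / 2,
                 sib_pairs = matrix(integer(0), 0, 2)),
            class = "genotypes")
}

#' Write a GCTA-style phenotype or covariate table
#'
#' Whitespace-delimited, no header, FID and IID leading columns
#' (FID = IID here).
#'
#' @param values Numeric vector or matrix/data.frame of values.
#' @param ids Sample ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gcta_table <- function(values, ids, path) {
  df <- data.frame(FID = ids, IID = ids, as.data.frame(values))
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GCTA-style phenotype or covariate table
#'
#' @param path Input path.
#' @return Data frame with `FID`, `IID` and the value column(s).
#' @export
read_gcta_table <- function(path) {
  df <- utils::read.table(path, header = FALSE)
  names(df)[1:2] <- c("FID", "IID")
  df$FID <- as.character(df$FID)
  df$IID <- as.character(df$IID)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
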