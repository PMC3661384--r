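# PLINK 1 binary genotype I/O (.bed / .bim / .fam), SNP-major v1.00.
#
# Two-bit codes in a SNP-major .bed, least significant bits first within a
# byte: 00 = homozygous allele1, 01 = missing, 10 = heterozygous,
# 11 = homozygous allele2.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)

## one row per byte value 0..255, the four allele1-counts (NA = missing code)
bed_decode_table <- function() {
  codes <- c(2, NA, 1, 0)  # 00, 01, 10, 11 -> count of allele1
  tab <- matrix(NA_real_, 256L, 4L)
  for (byte in 0:255) {
    q <- bitwAnd(bitwShiftR(byte, c(0L, 2L, 4L, 6L)), 3L)
    tab[byte + 1L, ] <- codes[q + 1L]
  }
  tab
}

#' Read PLINK 1 binary genotypes
#'
#' Reads a SNP-major `.bed`/`.bim`/`.fam` trio and returns minor-allele
#' counts.  The minor allele of each SNP is determined from the observed
#' allele frequencies among non-missing calls; an exact 50/50 tie is resolved
#' toward allele1 of the `.bim` record.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must exist.
#' @return object of class `mvgwas_genotypes`: a list with
#'   * `samples`: data.frame `fid`, `iid` (from `.fam`),
#'   * `snps`: data.frame `chromosome`, `snp_id`, `genetic_distance`,
#'     `position`, `allele1`, `allele2`, `minor_allele`, `maf`,
#'   * `counts`: n x m matrix of minor-allele counts in {0, 1, 2, NA}.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "))
  fam <- utils::read.table(paths[3], header = FALSE, colClasses = "character")
  if (ncol(fam) < 2L) stop("malformed .fam: fewer than 2 columns")
  samples <- data.frame(fid = fam[[1]], iid = fam[[2]], stringsAsFactors = FALSE)
  if (anyDuplicated(paste(samples$fid, samples$iid)))
    stop("duplicate (FID, IID) pairs in .fam")
  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chromosome", "snp_id", "genetic_distance", "position",
                  "allele1", "allele2")
  n <- nrow(samples); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC))
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1])
  if (raw[3] != BED_SNP_MAJOR)
    stop("unsupported .bed mode byte (only SNP-major v1.00 is supported): ", paths[1])
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * m)
    stop(sprintf(".bed payload is %d bytes but .bim/.fam imply %d (corrupt trio?)",
                 length(payload), bytes_per_snp * m))
  tab <- bed_decode_table()
  ## decode all bytes at once, then reshape: 4 genotypes per byte
  decoded <- tab[as.integer(payload) + 1L, , drop = FALSE]
  full <- matrix(t(decoded), nrow = 4L * bytes_per_snp, ncol = m)
  a1_counts <- full[seq_len(n), , drop = FALSE]  # drop pad genotypes

  ## orient to minor-allele counts per SNP
  freq_a1 <- colMeans(a1_counts, na.rm = TRUE) / 2
  freq_a1[is.nan(freq_a1)] <- 0  # all-missing SNP: keep allele1 orientation
  flip <- freq_a1 > 0.5
  counts <- a1_counts
  counts[, flip] <- 2 - a1_counts[, flip, drop = FALSE]
  bim$minor_allele <- ifelse(flip, bim$allele2, bim$allele1)
  bim$maf <- pmin(freq_a1, 1 - freq_a1)
  structure(list(samples = samples, snps = bim, counts = counts),
            class = "mvgwas_genotypes")
}

#' @export
print.mvgwas_genotypes <- function(x, ...) {
  cat(sprintf("PLINK genotypes: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$counts), ncol(x$counts), 100 * mean(is.na(x$counts))))
  invisible(x)
}

## Write a PLINK trio from an allele1-count matrix.  counts: n x m in
## {0, 1, 2, NA}, counting allele1.  Internal; used by write_fixture.
write_plink <- function(counts, samples, snps, prefix) {
  n <- nrow(counts); m <- ncol(counts)
  stopifnot(nrow(samples) == n, nrow(snps) == m)
  ## counts -> 2-bit codes: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code_of <- function(v) {
    q <- integer(length(v))
    q[is.na(v)] <- 1L
    q[!is.na(v) & v == 2] <- 0L
    q[!is.na(v) & v == 1] <- 2L
    q[!is.na(v) & v == 0] <- 3L
    q
  }
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4L * bytes_per_snp - n
  q <- code_of(as.vector(counts))            # column-major: SNP-major layout
  q <- matrix(q, nrow = n)
  if (pad > 0) q <- rbind(q, matrix(0L, pad, m))
  q <- matrix(q, nrow = 4L)                   # 4 genotypes per byte
  bytes <- as.raw(q[1, ] + bitwShiftL(q[2, ], 2L) +
                    bitwShiftL(q[3, ], 4L) + bitwShiftL(q[4, ], 6L))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR), con)
  writeBin(bytes, con)
  fam <- data.frame(samples$fid, samples$iid, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(snps$chromosome, snps$snp_id, snps$genetic_distance,
                    snps$position, snps$allele1, snps$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}
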