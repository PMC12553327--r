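.PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte -> four 2-bit PLINK genotype codes (LSB first),
# mapped to A1-allele counts (00 -> 2, 01 -> missing, 10 -> 1, 11 -> 0).
.plinkDecodeTable <- local({
  code2count <- c(2L, NA_integer_, 1L, 0L)
  tab <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255)
    for (k in 0:3)
      tab[b + 1, k + 1] <- code2count[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
  tab
})

#' Read PLINK 1 binary genotypes
#'
#' Reads a `.bed`/`.bim`/`.fam` triple (SNP-major `.bed`). Counts are
#' oriented to the minor allele: SNPs whose counted (A1) allele has
#' frequency above 0.5 are flipped (`x -> 2 - x`) and their allele labels
#' swapped, so `alt` is always the minor allele and `maf` its frequency
#' among non-missing genotypes.
#'
#' @param prefix path prefix (without extension).
#' @return a [GenotypeMatrix-class].
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)

  famt <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bimt <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "numeric",
                                           "integer", "character", "character"))
  n <- nrow(famt)
  m <- nrow(bimt)
  bps <- ceiling(n / 4)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .PLINK_MAGIC))
    stop("not a SNP-major PLINK .bed file (bad magic bytes): ", bed)
  body <- raw[-(1:3)]
  if (length(body) != bps * m)
    stop("PLINK .bed size inconsistent with .bim/.fam dimensions: ", bed)

  bytes <- matrix(as.integer(body), nrow = bps, ncol = m)
  counts <- matrix(NA_integer_, nrow = n, ncol = m)
  for (k in 0:3) {
    rows <- seq.int(1L + k, by = 4L, length.out = bps)
    rows <- rows[rows <= n]
    counts[rows, ] <- .plinkDecodeTable[bytes[seq_along(rows), , drop = FALSE] + 1L,
                                        k + 1L]
  }
  rownames(counts) <- as.character(famt[[2]])

  variants <- data.frame(id = bimt[[2]], chrom = bimt[[1]], pos = bimt[[4]],
                         ref = bimt[[6]], alt = bimt[[5]],
                         stringsAsFactors = FALSE)
  .orientMinor(counts, variants)
}

# Flip columns whose counted-allele frequency exceeds 0.5 and swap labels.
.orientMinor <- function(counts, variants) {
  f <- colMeans(counts, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  flip <- which(f > 0.5)
  if (length(flip)) {
    counts[, flip] <- 2L - counts[, flip]
    tmp <- variants$ref[flip]
    variants$ref[flip] <- variants$alt[flip]
    variants$alt[flip] <- tmp
  }
  variants$maf <- pmin(f, 1 - f)
  GenotypeMatrix(counts, variants)
}

#' Write PLINK 1 binary genotypes
#'
#' Inverse of [readPlink()]: the stored minor (`alt`) allele is written as
#' A1, the `ref` allele as A2, phenotype column is set to the PLINK missing
#' code -9.
#'
#' @param x a [GenotypeMatrix-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(x, prefix) {
  cts <- genotypes(x)
  v <- as.data.frame(variantInfo(x))
  n <- nrow(cts)
  m <- ncol(cts)

  fam <- data.frame(fid = sampleIds(x), iid = sampleIds(x), pid = 0L,
                    mid = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = v$chrom, id = v$id, cm = 0, pos = v$pos,
                    a1 = v$alt, a2 = v$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  # count -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, nrow = n, ncol = m)
  code[cts == 1L] <- 2L
  code[cts == 2L] <- 0L
  code[is.na(cts)] <- 1L
  bps <- ceiling(n / 4)
  pad <- bps * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, nrow = pad, ncol = m))
  k0 <- code[seq.int(1L, by = 4L, length.out = bps), , drop = FALSE]
  k1 <- code[seq.int(2L, by = 4L, length.out = bps), , drop = FALSE]
  k2 <- code[seq.int(3L, by = 4L, length.out = bps), , drop = FALSE]
  k3 <- code[seq.int(4L, by = 4L, length.out = bps), , drop = FALSE]
  bytes <- k0 + 4L * k1 + 16L * k2 + 64L * k3
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
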