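#' Clumping parameters
#'
#' @param r2_cutoff LD r-squared cutoff in (0, 1]; SNPs with pairwise
#'   r-squared strictly above the cutoff are removed from an index SNP's
#'   neighbourhood.
#' @param window_bp clumping window in base pairs (inclusive distance).
#' @param p_threshold p-value threshold in (0, 1] (strict `<`).
#' @return a named list of validated parameters.
#' @export
clumpParams <- function(r2_cutoff = 0.5, window_bp = 250000L,
                        p_threshold = 1) {
  stopifnot(r2_cutoff > 0, r2_cutoff <= 1,
            p_threshold > 0, p_threshold <= 1, window_bp >= 0)
  list(r2_cutoff = as.numeric(r2_cutoff), window_bp = as.integer(window_bp),
       p_threshold = as.numeric(p_threshold))
}

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of the two SNPs' allele-count vectors;
#' invariant to allele flips (x vs 2 - x).
#'
#' @param G a [GenotypeMatrix-class].
#' @param i,j SNP indices or ids.
#' @return r-squared in [0, 1].
#' @export
pairwiseR2 <- function(G, i, j) {
  x <- genotypes(G)
  if (is.character(i)) i <- match(i, snpIds(G))
  if (is.character(j)) j <- match(j, snpIds(G))
  a <- x[, i]
  b <- x[, j]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("r-squared undefined for a monomorphic SNP")
  stats::cor(a, b)^2
}

#' Greedy LD clumping
#'
#' PLINK-style greedy clumping: repeatedly take the smallest-p unassigned
#' SNP as an index SNP and discard all unassigned SNPs on the same
#' chromosome within `window_bp` base pairs whose r-squared with the index
#' exceeds `r2_cutoff` (strict `>`). Discarded SNPs never seed their own
#' clump. Ties in p break by (chrom, pos, id). LD is computed from `G` —
#' in the pipeline, always the target training samples.
#'
#' @param stats a [SummaryStats-class]; ids must be present in `G`.
#' @param G a [GenotypeMatrix-class] supplying the LD.
#' @param params a [clumpParams()] list.
#' @return character vector of retained (index) SNP ids, p-ascending.
#' @export
clumpSnps <- function(stats, G, params = clumpParams()) {
  s <- as.data.frame(statsTable(stats))
  if (!nrow(s)) return(character(0))
  gi <- match(s$id, snpIds(G))
  if (anyNA(gi)) stop("summary-statistics ids missing from genotype matrix")
  v <- variantInfo(G)
  ord <- order(s$p, v$chrom[gi], v$pos[gi], s$id, method = "radix")
  x <- genotypes(G)

  pos <- v$pos[gi]
  chrom <- v$chrom[gi]
  alive <- rep(TRUE, nrow(s))
  retained <- integer(0)
  for (k in ord) {
    if (!alive[k]) next
    retained <- c(retained, k)
    alive[k] <- FALSE
    near <- which(alive & chrom == chrom[k] &
                  abs(pos - pos[k]) <= params$window_bp)
    if (!length(near)) next
    xk <- x[, gi[k]]
    if (stats::sd(xk) == 0) next  # monomorphic index: no defined LD
    r2 <- suppressWarnings(as.vector(stats::cor(xk, x[, gi[near], drop = FALSE]))^2)
    r2[is.na(r2)] <- 0
    alive[near[r2 > params$r2_cutoff]] <- FALSE
  }
  s$id[retained]
}

#' p-value thresholding
#'
#' Retains SNPs with p strictly below the threshold, preserving the order
#' of `ids` (or of the stats table when `ids` is NULL).
#'
#' @param stats a [SummaryStats-class].
#' @param p_threshold threshold in (0, 1].
#' @param ids optional SNP id subset/order to filter (e.g. clump output).
#' @return character vector of retained SNP ids.
#' @export
thresholdSnps <- function(stats, p_threshold, ids = NULL) {
  s <- statsTable(stats)
  if (is.null(ids)) ids <- s$id
  p <- s$p[match(ids, s$id)]
  ids[!is.na(p) & p < p_threshold]
}
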