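#' @describeIn GenotypeMatrix-class the samples x SNPs integer count matrix.
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@counts)

#' @describeIn GenotypeMatrix-class per-SNP metadata DataFrame.
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) x@variants)

#' @describeIn GenotypeMatrix-class SNP identifiers.
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) x@variants$id)

#' @describeIn GenotypeMatrix-class sample identifiers.
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@counts))

#' @describeIn GenotypeMatrix-class sample count.
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@counts))

#' @describeIn GenotypeMatrix-class SNP count.
#' @export
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@counts))

#' @describeIn GenotypeMatrix-class per-SNP minor-allele frequencies.
#' @export
setMethod("maf", "GenotypeMatrix", function(x) {
  setNames(x@variants$maf, x@variants$id)
})

#' @describeIn GenotypeMatrix-class subset by sample (i) and/or SNP (j)
#'   index, logical mask, or id.
#' @param i,j,...,drop sample / SNP subscripts (drop is ignored).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  cts <- x@counts
  v <- x@variants
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, v$id)
    cts <- cts[, j, drop = FALSE]
    v <- v[j, , drop = FALSE]
  }
  if (!missing(i)) {
    if (is.character(i)) i <- match(i, rownames(x@counts))
    cts <- cts[i, , drop = FALSE]
  }
  new("GenotypeMatrix", counts = cts, variants = v)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nSamples(object), "samples x", nSnps(object),
      "SNPs\n")
  nmiss <- sum(is.na(object@counts))
  cat("  missing entries:", nmiss, "\n")
  mafs <- object@variants$maf
  if (length(mafs))
    cat(sprintf("  MAF range: [%.3f, %.3f]\n",
                min(mafs, na.rm = TRUE), max(mafs, na.rm = TRUE)))
})

#' @describeIn outcome the binary 0/1 outcome vector.
#' @export
setMethod("outcome", "PhenotypeTable", function(x) setNames(x@y, x@samples))

#' @describeIn outcome the samples x p covariate matrix.
#' @export
setMethod("covariates", "PhenotypeTable", function(x) x@covariates)

#' @describeIn outcome sample identifiers.
#' @export
setMethod("sampleIds", "PhenotypeTable", function(x) x@samples)

setMethod("show", "PhenotypeTable", function(object) {
  cat("PhenotypeTable:", length(object@samples), "samples,",
      sum(object@y), "cases /", sum(1L - object@y), "controls,",
      ncol(object@covariates), "covariates\n")
})

#' @describeIn statsTable association table accessor.
#' @export
setMethod("statsTable", "SummaryStats", function(x) x@stats)

#' @describeIn statsTable SNP identifiers.
#' @export
setMethod("snpIds", "SummaryStats", function(x) x@stats$id)

setMethod("show", "SummaryStats", function(object) {
  s <- object@stats
  cat("SummaryStats:", nrow(s), "SNPs; min p =",
      format(suppressWarnings(min(s$p)), digits = 4), ";",
      sum(s$flag), "flagged\n")
})

setMethod("show", "GrsForest", function(object) {
  cat("GrsForest:", length(object@trees), "trees over",
      sum(object@is_snp), "SNPs +", sum(!object@is_snp),
      "covariates;", object@n_train, "training samples\n")
})

setMethod("show", "GrsModel", function(object) {
  cat("GrsModel:", object@method, "(", object@mode, ")\n")
  cat("  retained SNPs:", length(object@snps), "\n")
  h <- object@hyper
  if (length(h))
    cat("  hyperparameters:",
        paste(names(h), unlist(h), sep = "=", collapse = ", "), "\n")
  cat("  tuning objective (NR2):", format(object@objective, digits = 4), "\n")
})

#' Subset a PhenotypeTable by sample
#' @param x a PhenotypeTable; `i` sample indices or ids.
#' @param i,...,drop subscripts (drop ignored).
#' @export
setMethod("[", "PhenotypeTable", function(x, i, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@samples)
  new("PhenotypeTable", samples = x@samples[i], y = x@y[i],
      covariates = x@covariates[i, , drop = FALSE])
})

#' Subset a SummaryStats by SNP
#' @param x a SummaryStats; `i` SNP indices or ids.
#' @param i,...,drop subscripts (drop ignored).
#' @export
setMethod("[", "SummaryStats", function(x, i, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@stats$id)
  new("SummaryStats", stats = x@stats[i, , drop = FALSE])
})

#' Replace missing genotypes by the per-SNP modal count
#'
#' Downstream modules (association scans, clumping, forests) require
#' complete genotypes; this utility is applied explicitly by the caller.
#' Ties in the mode resolve to the smaller count.
#'
#' @param x a [GenotypeMatrix-class].
#' @return a GenotypeMatrix with no missing entries.
#' @export
imputeMode <- function(x) {
  cts <- x@counts
  nmiss <- colSums(is.na(cts))
  for (j in which(nmiss > 0L)) {
    tab <- tabulate(cts[, j] + 1L, nbins = 3L)
    cts[is.na(cts[, j]), j] <- which.max(tab) - 1L
  }
  initialize(x, counts = cts)
}
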