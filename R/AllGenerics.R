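#' @rdname GenotypeMatrix-class
#' @param x,object a GenotypeMatrix.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("maf", function(x) standardGeneric("maf"))

#' Per-SNP association table of a SummaryStats object
#' @param x a SummaryStats.
#' @return [S4Vectors::DataFrame] with one row per SNP.
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))

#' Phenotype accessors
#' @param x a PhenotypeTable.
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname outcome
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
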