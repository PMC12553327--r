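#' @useDynLib forestGRS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Assemble the numeric feature matrix: SNP columns (categorical 0/1/2)
# first, covariates after, in the forest's stored order.
.featureMatrix <- function(G, covariates = NULL, feature_names = NULL) {
  x <- genotypes(G)
  if (anyNA(x)) stop("forests require complete genotypes; see imputeMode()")
  storage.mode(x) <- "double"
  cv <- covariates
  if (is.null(cv)) cv <- matrix(numeric(0), nrow = nrow(x), ncol = 0)
  cv <- as.matrix(cv)
  feat <- cbind(x, cv)
  if (!is.null(feature_names)) {
    miss <- setdiff(feature_names, colnames(feat))
    if (length(miss))
      stop("feature mismatch: missing ", paste(head(miss, 5), collapse = ", "))
    feat <- feat[, feature_names, drop = FALSE]
  }
  feat
}

#' Fit a probability-machine random forest
#'
#' Grows `ntree` trees, each on a bootstrap sample of size n drawn with
#' replacement (or the full data when `bootstrap` is off). At each node,
#' `mtry` candidate features are sampled without replacement — uniformly,
#' or with probability proportional to `split_weights` over the SNP
#' features (covariates then receive the maximum SNP weight so they remain
#' samplable; weight-0 features are never sampled). SNP features split by
#' the best one-category-vs-rest partition by Gini impurity decrease;
#' covariates split at the best midpoint threshold. A node becomes terminal
#' when pure, smaller than `min_node_size`, or when no candidate split
#' reduces impurity; terminal nodes store the in-bag disease proportion.
#' Deterministic given `config@seed`.
#'
#' @param G a [GenotypeMatrix-class] of training genotypes (complete).
#' @param pheno a [PhenotypeTable-class]; its covariates enter as numeric
#'   features.
#' @param config a [ForestConfig-class]; `split_weights`, when non-empty,
#'   must align with `G`'s SNP columns.
#' @return a [GrsForest-class].
#' @export
fitForest <- function(G, pheno, config) {
  stopifnot(is(config, "ForestConfig"))
  validObject(config)
  feat <- .featureMatrix(G, covariates(pheno))
  y <- as.integer(unname(outcome(pheno)))
  n_snp <- nSnps(G)
  n_feat <- ncol(feat)
  if (config@mtry > n_feat)
    stop("mtry (", config@mtry, ") exceeds feature count (", n_feat, ")")
  sw <- config@split_weights
  if (length(sw)) {
    if (length(sw) != n_snp)
      stop("split_weights must have one entry per SNP")
    if (n_feat > n_snp) sw <- c(sw, rep(max(sw), n_feat - n_snp))
  }
  fit <- .withSeed(config@seed,
    .growForestCpp(feat, y, c(rep(TRUE, n_snp), rep(FALSE, n_feat - n_snp)),
                   config@ntree, config@mtry, config@min_node_size,
                   sw, config@bootstrap))
  new("GrsForest", trees = fit$trees, inbag = fit$inbag,
      feature_names = colnames(feat),
      is_snp = c(rep(TRUE, n_snp), rep(FALSE, n_feat - n_snp)),
      config = config, n_train = length(y))
}

#' Predict disease probabilities from a fitted forest
#'
#' Routes each sample down every tree to its terminal node and averages
#' the stored disease proportions across the `ntree` trees.
#'
#' @param forest a [GrsForest-class].
#' @param G a [GenotypeMatrix-class] covering the forest's SNP features.
#' @param covariates covariate matrix matching the forest's covariate
#'   features (if any).
#' @return per-sample probabilities in [0, 1], named by sample id.
#' @export
predictProba <- function(forest, G, covariates = NULL) {
  feat <- .featureMatrix(G, covariates, forest@feature_names)
  setNames(.predictForestCpp(forest@trees, feat), rownames(feat))
}

#' Out-of-bag disease probabilities
#'
#' Per training sample, averages terminal proportions over only the trees
#' whose bootstrap sample excluded it. Samples in-bag for every tree get
#' `NA` and are excluded from downstream tuning statistics.
#'
#' @param forest a [GrsForest-class] fitted with `bootstrap = TRUE`.
#' @param G the training [GenotypeMatrix-class].
#' @param covariates the training covariate matrix (if the forest used one).
#' @return per-sample OOB probabilities (NA where undefined).
#' @export
oobProba <- function(forest, G, covariates = NULL) {
  if (!forest@config@bootstrap)
    stop("OOB probabilities require a forest fitted with bootstrap = TRUE")
  if (nSamples(G) != forest@n_train)
    stop("OOB prediction needs the forest's own training samples")
  feat <- .featureMatrix(G, covariates, forest@feature_names)
  setNames(.oobForestCpp(forest@trees, forest@inbag, feat), rownames(feat))
}
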