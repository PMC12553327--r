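#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Sentinel for missing genotypes
#'
#' Missing allele counts are stored as `NA_integer_` in the count matrix.
#' @keywords internal
.MISSING <- NA_integer_

#' GenotypeMatrix: samples x SNPs minor-allele counts
#'
#' Central genotype container: an integer matrix of minor-allele counts
#' (0, 1, 2, or `NA` for missing) with one row per sample and one column per
#' SNP, together with per-SNP metadata (id, chromosome, 1-based base-pair
#' position, reference/alternate allele, minor-allele frequency).
#'
#' @slot counts integer matrix, samples x SNPs, entries in \{0,1,2,NA\}.
#' @slot variants [S4Vectors::DataFrame] with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`; one row per SNP column.
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(counts = "matrix", variants = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  cts <- object@counts
  v <- object@variants
  if (!is.integer(cts)) msg <- c(msg, "counts must be an integer matrix")
  bad <- cts[!is.na(cts)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    msg <- c(msg, "non-missing counts must be in {0,1,2}")
  if (nrow(v) != ncol(cts))
    msg <- c(msg, "variants rows must equal count matrix columns")
  need <- c("id", "chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% colnames(v)))
    msg <- c(msg, paste("variants needs columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(v$id)) msg <- c(msg, "SNP ids must be unique")
    if (any(v$pos < 1L)) msg <- c(msg, "positions must be >= 1")
    mafs <- v$maf[!is.na(v$maf)]
    if (length(mafs) && (any(mafs < 0) || any(mafs > 0.5 + 1e-9)))
      msg <- c(msg, "maf must lie in [0, 0.5]")
  }
  if (is.null(rownames(cts)))
    msg <- c(msg, "counts must carry sample ids as rownames")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param counts samples x SNPs matrix of minor-allele counts (coerced to
#'   integer); rownames are sample ids.
#' @param variants data.frame or DataFrame of per-SNP metadata (`id`,
#'   `chrom`, `pos`, `ref`, `alt`, optionally `maf`).
#' @param samples optional sample ids (overrides rownames).
#' @return A [GenotypeMatrix-class] object. `maf` is computed from the
#'   non-missing counts when not supplied.
#' @export
GenotypeMatrix <- function(counts, variants, samples = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(samples)) rownames(counts) <- samples
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  variants <- as(as.data.frame(variants, stringsAsFactors = FALSE), "DataFrame")
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (is.null(variants$maf))
    variants$maf <- .empiricalMaf(counts)
  colnames(counts) <- variants$id
  new("GenotypeMatrix", counts = counts, variants = variants)
}

.empiricalMaf <- function(counts) {
  f <- colMeans(counts, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' PhenotypeTable: binary outcome plus covariates
#'
#' @slot samples character sample ids.
#' @slot y integer 0/1 outcome, one per sample.
#' @slot covariates numeric matrix, samples x p (p may be 0).
#' @exportClass PhenotypeTable
setClass("PhenotypeTable",
  representation(samples = "character", y = "integer", covariates = "matrix"))

setValidity("PhenotypeTable", function(object) {
  msg <- character()
  if (length(object@y) != length(object@samples))
    msg <- c(msg, "y length must match samples")
  if (!all(object@y %in% c(0L, 1L)))
    msg <- c(msg, "y must be binary 0/1")
  if (nrow(object@covariates) != length(object@samples))
    msg <- c(msg, "covariate rows must match samples")
  if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeTable
#' @param samples sample ids.
#' @param y binary outcome (0/1), one per sample.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @export
PhenotypeTable <- function(samples, y, covariates = NULL) {
  samples <- as.character(samples)
  y <- as.integer(y)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = length(samples), ncol = 0)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  rownames(covariates) <- samples
  new("PhenotypeTable", samples = samples, y = y, covariates = covariates)
}

#' SummaryStats: per-SNP association results
#'
#' Per-SNP marginal association results — effect allele, log-odds `beta`,
#' standard error, two-sided p-value in (0, 1], the derived z-value
#' \eqn{z = |\Phi^{-1}(p/2)|}, and a flag for degenerate fits
#' (monomorphic SNPs, non-convergence).
#'
#' @slot stats [S4Vectors::DataFrame] with columns `id`, `effect_allele`,
#'   `beta`, `se`, `p`, `z`, `flag`.
#' @exportClass SummaryStats
setClass("SummaryStats", representation(stats = "DataFrame"))

setValidity("SummaryStats", function(object) {
  s <- object@stats
  msg <- character()
  need <- c("id", "effect_allele", "beta", "se", "p", "z", "flag")
  if (!all(need %in% colnames(s)))
    return(paste("stats needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$id)) msg <- c(msg, "SNP ids must be unique")
  if (any(s$p <= 0 | s$p > 1)) msg <- c(msg, "p must lie in (0, 1]")
  if (any(s$z < 0, na.rm = TRUE)) msg <- c(msg, "z must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SummaryStats object
#' @param id SNP ids.
#' @param effect_allele allele whose count `beta` refers to.
#' @param beta per-allele log-odds.
#' @param p two-sided p-values in (0, 1].
#' @param se optional standard errors.
#' @param z optional z-values; computed as [pToZ()] of `p` when missing.
#' @param flag logical; marks degenerate fits.
#' @export
SummaryStats <- function(id, effect_allele, beta, p, se = NA_real_,
                         z = NULL, flag = FALSE) {
  n <- length(id)
  if (is.null(z)) z <- pToZ(p)
  stats <- DataFrame(id = as.character(id),
                     effect_allele = as.character(effect_allele),
                     beta = as.numeric(beta),
                     se = rep_len(as.numeric(se), n),
                     p = as.numeric(p),
                     z = as.numeric(z),
                     flag = rep_len(as.logical(flag), n))
  new("SummaryStats", stats = stats)
}

#' LDBlockSpec: blockwise-LD genotype generator settings
#'
#' Latent-Gaussian LD emulation: within each block a standard-normal AR(1)
#' process with adjacent-SNP correlation `rho` is thresholded at the
#' Hardy-Weinberg genotype quantiles of a MAF drawn uniformly from
#' `maf_range`; blocks are independent. Positions are block-contiguous at
#' `bp_spacing` base pairs.
#'
#' @slot block_sizes integer SNPs per block.
#' @slot rho latent adjacent-SNP correlation in [0, 1).
#' @slot maf_range numeric(2) in [0.01, 0.5].
#' @slot bp_spacing integer base pairs between adjacent SNPs.
#' @slot chrom chromosome label for generated variants.
#' @exportClass LDBlockSpec
setClass("LDBlockSpec",
  representation(block_sizes = "integer", rho = "numeric",
                 maf_range = "numeric", bp_spacing = "integer",
                 chrom = "character"))

setValidity("LDBlockSpec", function(object) {
  msg <- character()
  if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho must be in [0, 1)")
  mr <- object@maf_range
  if (length(mr) != 2 || mr[1] > mr[2] || mr[1] < 0.01 || mr[2] > 0.5)
    msg <- c(msg, "maf_range must be (low, high) within [0.01, 0.5]")
  if (any(object@block_sizes < 1L)) msg <- c(msg, "block sizes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an LDBlockSpec
#' @param n_snps total SNP count (used with `block_size` when `block_sizes`
#'   is not given).
#' @param block_size SNPs per block; the last block absorbs the remainder.
#' @param block_sizes explicit block sizes (overrides `n_snps`/`block_size`).
#' @param rho latent adjacent-SNP correlation in [0, 1).
#' @param maf_range MAF sampling range, within [0.01, 0.5].
#' @param bp_spacing base pairs between adjacent SNPs.
#' @param chrom chromosome label.
#' @export
ldBlockSpec <- function(n_snps = 1000L, block_size = 20L, block_sizes = NULL,
                        rho = 0.7, maf_range = c(0.05, 0.3),
                        bp_spacing = 5000L, chrom = "21") {
  if (is.null(block_sizes)) {
    nb <- n_snps %/% block_size
    block_sizes <- rep(block_size, nb)
    rem <- n_snps - nb * block_size
    if (rem > 0) block_sizes <- c(block_sizes, rem)
  }
  new("LDBlockSpec", block_sizes = as.integer(block_sizes),
      rho = as.numeric(rho), maf_range = as.numeric(maf_range),
      bp_spacing = as.integer(bp_spacing), chrom = as.character(chrom))
}

#' EffectModel: a scenario's causal architecture
#'
#' Causal SNP indices and the additive, pairwise-interaction, three-way-
#' interaction and quadratic log-odds terms of one phenotype scenario.
#'
#' @slot scenario one of "1","2","3","4","5a","5b".
#' @slot causal integer indices of the 100 causal SNPs (columns of the
#'   genotype matrix the model was drawn for).
#' @slot beta0 intercept log-odds.
#' @slot main data.frame (snp, beta): additive terms beta * x.
#' @slot pairs data.frame (snp1, snp2, beta): beta * x1 * x2.
#' @slot triples data.frame (snp1, snp2, snp3, beta): beta * x1 * x2 * x3.
#' @slot quads data.frame (snp, beta): beta * x^2.
#' @exportClass EffectModel
setClass("EffectModel",
  representation(scenario = "character", causal = "integer",
                 beta0 = "numeric", main = "data.frame",
                 pairs = "data.frame", triples = "data.frame",
                 quads = "data.frame"))

setValidity("EffectModel", function(object) {
  msg <- character()
  sc <- object@scenario
  nm <- nrow(object@main); np <- nrow(object@pairs)
  nt <- nrow(object@triples); nq <- nrow(object@quads)
  want <- switch(sc,
    "1"  = c(100L, 0L, 0L, 0L),
    "2"  = c(0L, 100L, 0L, 0L),
    "3"  = c(50L, 100L, 0L, 0L),
    "4"  = c(0L, 0L, 30L, 0L),
    "5a" = c(0L, 0L, 0L, 100L),
    "5b" = c(0L, 0L, 0L, 100L),
    NULL)
  if (is.null(want)) return("scenario must be one of 1, 2, 3, 4, 5a, 5b")
  if (!identical(c(nm, np, nt, nq), want))
    msg <- c(msg, sprintf(
      "scenario %s needs %d main / %d pair / %d triple / %d quad terms",
      sc, want[1], want[2], want[3], want[4]))
  if (length(object@causal) != 100L || anyDuplicated(object@causal))
    msg <- c(msg, "causal must hold 100 distinct SNP indices")
  cz <- object@causal
  if (np) {
    if (!all(object@pairs$snp1 %in% cz[1:50]) ||
        !all(object@pairs$snp2 %in% cz[51:100]))
      msg <- c(msg, "pair terms must link causal SNPs 1-50 with 51-100")
  }
  if (nt) {
    g <- list(cz[1:33], cz[34:66], cz[67:99])
    if (!all(object@triples$snp1 %in% g[[1]]) ||
        !all(object@triples$snp2 %in% g[[2]]) ||
        !all(object@triples$snp3 %in% g[[3]]))
      msg <- c(msg, "triple terms must draw one SNP per 33-SNP group")
  }
  if (length(msg)) msg else TRUE
})

#' SimConfig: simulation study settings
#'
#' @slot n_target target-cohort sample count.
#' @slot n_base base-cohort sample count.
#' @slot n_snps SNP count.
#' @slot q causal SNPs shared between base and target architectures.
#' @slot mu_main mean log-odds-ratio of main (and quadratic) effects.
#' @slot mu_int mean log-odds-ratio of interaction effects.
#' @slot sd effect-size standard deviation.
#' @slot beta0 intercept log-odds.
#' @slot seed default random seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(n_target = "integer", n_base = "integer", n_snps = "integer",
                 q = "integer", mu_main = "numeric", mu_int = "numeric",
                 sd = "numeric", beta0 = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@q > 100L) msg <- c(msg, "q must be <= 100")
  if (object@n_snps < 100L) msg <- c(msg, "need at least 100 SNPs")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults are the desk-scale study conditions: 1000 target samples, 2000
#' base samples, 1000 SNPs, full causal overlap (q = 100), effect-size
#' standard deviation 0.1 and a zero intercept.
#'
#' @param n_target,n_base,n_snps cohort and panel sizes.
#' @param q shared causal SNP count (100, 70, 50 or 30 in the study design;
#'   other values are accepted).
#' @param mu_main,mu_int mean log-odds-ratios for main/quadratic and
#'   interaction effect sizes.
#' @param sd effect-size standard deviation.
#' @param beta0 intercept log-odds.
#' @param seed default seed.
#' @export
simConfig <- function(n_target = 1000L, n_base = 2000L, n_snps = 1000L,
                      q = 100L, mu_main = log(1.5), mu_int = log(2),
                      sd = 0.1, beta0 = 0, seed = 1L) {
  if (!q %in% c(100L, 70L, 50L, 30L))
    warning("q = ", q, " is outside the study design {100, 70, 50, 30}")
  new("SimConfig", n_target = as.integer(n_target),
      n_base = as.integer(n_base), n_snps = as.integer(n_snps),
      q = as.integer(q), mu_main = as.numeric(mu_main),
      mu_int = as.numeric(mu_int), sd = as.numeric(sd),
      beta0 = as.numeric(beta0), seed = as.integer(seed))
}

#' ForestConfig: forest-growing settings
#'
#' @slot ntree tree count.
#' @slot mtry candidate features per split.
#' @slot min_node_size minimum samples in a node to attempt a split.
#' @slot split_weights numeric per-SNP-feature sampling weights in [0, 1]
#'   (length 0 for uniform sampling).
#' @slot bootstrap draw a bootstrap sample per tree.
#' @slot seed integer seed.
#' @exportClass ForestConfig
setClass("ForestConfig",
  representation(ntree = "integer", mtry = "integer",
                 min_node_size = "integer", split_weights = "numeric",
                 bootstrap = "logical", seed = "integer"))

setValidity("ForestConfig", function(object) {
  msg <- character()
  if (object@ntree < 1L) msg <- c(msg, "ntree must be >= 1")
  if (object@mtry < 1L) msg <- c(msg, "mtry must be >= 1")
  if (object@min_node_size < 1L) msg <- c(msg, "min_node_size must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ForestConfig
#' @param ntree tree count.
#' @param mtry candidate features per split.
#' @param min_node_size minimum node size to attempt a split.
#' @param split_weights optional per-SNP weights for split-candidate
#'   sampling (wRF); `NULL` for uniform.
#' @param bootstrap bootstrap per tree (required for OOB predictions).
#' @param seed integer seed.
#' @export
forestConfig <- function(ntree = 500L, mtry, min_node_size = 1L,
                         split_weights = NULL, bootstrap = TRUE, seed = 1L) {
  if (is.null(split_weights)) split_weights <- numeric(0)
  new("ForestConfig", ntree = as.integer(ntree), mtry = as.integer(mtry),
      min_node_size = as.integer(min_node_size),
      split_weights = as.numeric(split_weights),
      bootstrap = as.logical(bootstrap), seed = as.integer(seed))
}

#' GrsForest: a fitted probability-machine forest
#'
#' Ensemble of decision trees over 3-level categorical SNP features and
#' numeric covariates. Terminal nodes carry the in-bag disease proportion;
#' the forest prediction for a sample is the average terminal proportion
#' across trees (a probability, not a majority vote).
#'
#' @slot trees list of tree node tables (parallel vectors `feature`,
#'   `cat_left`, `threshold`, `left`, `right`, `prop`, `n_node`; 0-based
#'   indices, `feature = -1` marks a terminal node).
#' @slot inbag list of per-tree integer in-bag multiplicities (one per
#'   training sample).
#' @slot feature_names feature (SNP then covariate) names, in model order.
#' @slot is_snp logical per feature.
#' @slot config the [ForestConfig-class] used.
#' @slot n_train training-sample count.
#' @exportClass GrsForest
setClass("GrsForest",
  representation(trees = "list", inbag = "list", feature_names = "character",
                 is_snp = "logical", config = "ForestConfig",
                 n_train = "integer"))

setValidity("GrsForest", function(object) {
  msg <- character()
  if (length(object@trees) != object@config@ntree)
    msg <- c(msg, "tree count must equal config ntree")
  if (length(object@is_snp) != length(object@feature_names))
    msg <- c(msg, "is_snp length must match feature_names")
  if (length(msg)) msg else TRUE
})

#' HyperGrid: grid-search space for GRS tuning
#'
#' @slot r2_cutoffs LD-clumping r-squared cutoffs.
#' @slot p_thresholds p-value thresholds.
#' @slot ntrees forest sizes.
#' @slot mtrys candidate-feature counts; length 0 means mtry is derived
#'   from the retained SNP count M by `mtry_rule`.
#' @slot mtry_rule "adaptive" (\{ceil(sqrt(M)), ceil(M/10), ceil(M/3)\}) or
#'   "sqrt" (ceil(sqrt(M)) only); used when `mtrys` is empty.
#' @slot min_node_sizes minimum node sizes.
#' @exportClass HyperGrid
setClass("HyperGrid",
  representation(r2_cutoffs = "numeric", p_thresholds = "numeric",
                 ntrees = "integer", mtrys = "integer",
                 mtry_rule = "character", min_node_sizes = "integer"))

setValidity("HyperGrid", function(object) {
  if (!length(object@r2_cutoffs) || !length(object@p_thresholds) ||
      !length(object@ntrees) || !length(object@min_node_sizes))
    "all grid dimensions except mtrys must be non-empty" else TRUE
})

#' Construct a HyperGrid
#'
#' Default grid: clumping r-squared cutoffs \{0.1, 0.2, 0.5, 0.8, 1\},
#' p-value thresholds \{1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1\}, 500 trees,
#' adaptive mtry and minimum node sizes \{1, 5, 10\}. A cutoff of 1 retains
#' every SNP (clumping removes only pairs with r-squared strictly above the
#' cutoff), so the no-clumping ablations live inside the full grid.
#'
#' @param r2_cutoffs,p_thresholds,ntrees,mtrys,min_node_sizes grid values;
#'   `mtrys = NULL` selects mtry per retained SNP count via `mtry_rule`.
#' @param mtry_rule "adaptive" or "sqrt"; see slots.
#' @export
hyperGrid <- function(r2_cutoffs = c(0.1, 0.2, 0.5, 0.8, 1),
                      p_thresholds = c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1),
                      ntrees = 500L, mtrys = NULL,
                      mtry_rule = c("adaptive", "sqrt"),
                      min_node_sizes = c(1L, 5L, 10L)) {
  if (is.null(mtrys)) mtrys <- integer(0)
  new("HyperGrid", r2_cutoffs = as.numeric(r2_cutoffs),
      p_thresholds = as.numeric(p_thresholds), ntrees = as.integer(ntrees),
      mtrys = as.integer(mtrys), mtry_rule = match.arg(mtry_rule),
      min_node_sizes = as.integer(min_node_sizes))
}

#' Desk-scale tuning grid
#'
#' The reduced grid used by the replicated desk-scale experiments:
#' r-squared cutoffs \{0.1, 0.5, 1\}, p-value thresholds \{0.01, 0.1, 1\},
#' 200 trees, mtry = ceil(sqrt(M)) and minimum node size 5.
#' @export
deskGrid <- function() {
  hyperGrid(r2_cutoffs = c(0.1, 0.5, 1), p_thresholds = c(0.01, 0.1, 1),
            ntrees = 200L, mtry_rule = "sqrt", min_node_sizes = 5L)
}

#' GrsModel: a trained genetic risk scorer
#'
#' @slot method one of "ctRF", "cRF", "tRF", "wRF", "oRF", "oCT".
#' @slot mode "Tonly" (target-derived p-values) or "BT" (base summary
#'   statistics).
#' @slot hyper named list of the chosen hyperparameters.
#' @slot snps retained SNP ids, in scoring order.
#' @slot forest fitted [GrsForest-class] (RF methods) or `NULL` (oCT).
#' @slot weights named per-SNP additive log-odds weights (oCT) or empty.
#' @slot objective training-tuning objective (Nagelkerke R-squared).
#' @slot covariates covariate names used as features.
#' @exportClass GrsModel
setClass("GrsModel",
  representation(method = "character", mode = "character", hyper = "list",
                 snps = "character", forest = "ANY", weights = "numeric",
                 objective = "numeric", covariates = "character"))

setValidity("GrsModel", function(object) {
  msg <- character()
  if (!object@method %in% c("ctRF", "cRF", "tRF", "wRF", "oRF", "oCT"))
    msg <- c(msg, "unknown method")
  if (!object@mode %in% c("Tonly", "BT"))
    msg <- c(msg, "mode must be Tonly or BT")
  if (object@method == "oCT") {
    if (length(object@weights) != length(object@snps))
      msg <- c(msg, "oCT needs one weight per retained SNP")
  } else if (!is(object@forest, "GrsForest")) {
    msg <- c(msg, "RF methods need a fitted GrsForest")
  }
  if (length(msg)) msg else TRUE
})
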