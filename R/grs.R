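#' Source association p-values for GRS construction
#'
#' In "BT" mode, base summary statistics are harmonized to the target
#' training genotypes (intersection on id, effect allele aligned to the
#' target minor allele). In "Tonly" mode, a marginal association scan of
#' the target training split supplies the statistics.
#'
#' @param mode "Tonly" or "BT".
#' @param base a [SummaryStats-class] (required for "BT", ignored for
#'   "Tonly").
#' @param G_train,pheno_train the target training split.
#' @return a [SummaryStats-class] restricted to training SNPs.
#' @export
sourcePvalues <- function(mode, base = NULL, G_train, pheno_train) {
  mode <- match.arg(mode, c("Tonly", "BT"))
  if (mode == "BT") {
    if (is.null(base)) stop("mode 'BT' requires base summary statistics")
    harmonize(G_train, base)$base
  } else {
    marginalScan(G_train, pheno_train)
  }
}

# Deterministic per-grid-point seed: identical settings give identical
# forests regardless of which method visits them, making the grid-superset
# dominance of ctRF over cRF/tRF exact.
.pointSeed <- function(seed, ...) {
  s <- paste(vapply(list(...), function(v) format(v, digits = 15),
                    character(1)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer((seed %% 2147483647 + h) %% 2147483647)
}

.resolveMtry <- function(grid, n_snps, n_feat) {
  vals <- if (length(grid@mtrys)) grid@mtrys
  else if (grid@mtry_rule == "sqrt") ceiling(sqrt(n_snps))
  else unique(ceiling(c(sqrt(n_snps), n_snps / 10, n_snps / 3)))
  sort(unique(pmax(1L, pmin(as.integer(vals), n_feat))))
}

# Effective grid per method. tRF/oRF/wRF disable clumping, which under the
# strict r^2 > cutoff rule is exactly the r2_cutoff = 1 grid line; cRF
# fixes the p-value threshold at 1.
.effectiveGrid <- function(method, grid) {
  switch(method,
    ctRF = expand.grid(r2 = grid@r2_cutoffs, p_thr = grid@p_thresholds),
    cRF  = expand.grid(r2 = grid@r2_cutoffs, p_thr = 1),
    tRF  = expand.grid(r2 = 1, p_thr = grid@p_thresholds),
    oRF  = expand.grid(r2 = 1, p_thr = 1),
    wRF  = expand.grid(r2 = 1, p_thr = 1),
    oCT  = expand.grid(r2 = grid@r2_cutoffs, p_thr = grid@p_thresholds),
    stop("unknown method: ", method))
}

# Strict-improvement comparison with the documented tie-breaks:
# higher objective, then fewer retained SNPs, then smaller ntree, then
# earlier grid order (the incumbent wins remaining ties).
.betterPoint <- function(cand, best) {
  if (is.null(best)) return(TRUE)
  if (cand$objective != best$objective) return(cand$objective > best$objective)
  if (length(cand$snps) != length(best$snps))
    return(length(cand$snps) < length(best$snps))
  ct <- cand$hyper$ntree %||% 0L
  bt <- best$hyper$ntree %||% 0L
  if (ct != bt) return(ct < bt)
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a random-forest genetic risk score
#'
#' Grid search over the method's effective hyperparameter space. ctRF
#' tunes the LD-clumping r-squared cutoff and the p-value threshold
#' jointly (plus ntree, mtry, minimum node size); cRF tunes only the
#' clumping cutoff (threshold fixed at 1); tRF only the threshold (no
#' clumping); oRF neither (all SNPs); wRF applies no filtering but samples
#' split candidates with min-max weights derived from the association
#' z-values. For each grid point, SNPs are selected (clump, then
#' threshold), a forest is fitted on the training split, and the tuning
#' objective is the Nagelkerke R-squared of the out-of-bag GRS against the
#' training outcome (samples without OOB trees are dropped). The
#' objective-maximal point wins; ties break by fewer retained SNPs, then
#' smaller ntree, then grid order.
#'
#' @param method one of "ctRF", "cRF", "tRF", "wRF", "oRF".
#' @param mode "Tonly" or "BT".
#' @param G_train,pheno_train the target training split (complete
#'   genotypes).
#' @param base base [SummaryStats-class] (mode "BT").
#' @param grid a [hyperGrid()].
#' @param seed integer master seed; each grid point derives its forest
#'   seed deterministically from the seed and its settings.
#' @param stats optional precomputed [sourcePvalues()] result (skips the
#'   scan; used by the experiment driver).
#' @param window_bp clumping window in base pairs.
#' @return a [GrsModel-class].
#' @export
trainRfGrs <- function(method, mode, G_train, pheno_train, base = NULL,
                       grid = hyperGrid(), seed = 1L, stats = NULL,
                       window_bp = 250000L) {
  method <- match.arg(method, c("ctRF", "cRF", "tRF", "wRF", "oRF"))
  mode <- match.arg(mode, c("Tonly", "BT"))
  if (is.null(stats)) stats <- sourcePvalues(mode, base, G_train, pheno_train)
  G <- G_train[, intersect(snpIds(G_train), snpIds(stats))]
  stats <- stats[match(snpIds(G), snpIds(stats))]
  y <- unname(outcome(pheno_train))
  cov <- covariates(pheno_train)
  null_mode <- if (ncol(cov)) "incremental" else "marginal"

  weights_all <- NULL
  if (method == "wRF")
    weights_all <- setNames(zToWeights(statsTable(stats)$z), snpIds(stats))

  ct_grid <- .effectiveGrid(method, grid)
  clump_cache <- new.env(parent = emptyenv())
  best <- NULL
  n_skipped <- 0L
  for (gi in seq_len(nrow(ct_grid))) {
    r2 <- ct_grid$r2[gi]
    p_thr <- ct_grid$p_thr[gi]
    key <- format(r2, digits = 15)
    if (is.null(clump_cache[[key]]))
      clump_cache[[key]] <- clumpSnps(stats, G,
        clumpParams(r2_cutoff = r2, window_bp = window_bp))
    retained <- thresholdSnps(stats, p_thr, ids = clump_cache[[key]])
    if (!length(retained)) {
      warning(sprintf("grid point (r2=%g, p=%g) retains 0 SNPs; skipped",
                      r2, p_thr))
      n_skipped <- n_skipped + 1L
      next
    }
    Gr <- G[, retained]
    sw <- if (is.null(weights_all)) NULL else unname(weights_all[retained])
    n_feat <- length(retained) + ncol(cov)
    for (ntree in grid@ntrees) {
      for (mtry in .resolveMtry(grid, length(retained), n_feat)) {
        for (mns in grid@min_node_sizes) {
          pseed <- .pointSeed(seed, r2, p_thr, ntree, mtry, mns)
          cfg <- forestConfig(ntree = ntree, mtry = mtry,
                              min_node_size = mns, split_weights = sw,
                              bootstrap = TRUE, seed = pseed)
          forest <- fitForest(Gr, pheno_train, cfg)
          oob <- oobProba(forest, Gr, cov)
          ok <- !is.na(oob)
          obj <- nagelkerkeR2(y[ok], oob[ok],
                              covariates = cov[ok, , drop = FALSE],
                              null_mode = null_mode)
          cand <- list(objective = as.numeric(obj), snps = retained,
                       forest = forest,
                       hyper = list(r2_cutoff = r2, p_threshold = p_thr,
                                    ntree = ntree, mtry = mtry,
                                    min_node_size = mns))
          if (.betterPoint(cand, best)) best <- cand
        }
      }
    }
  }
  if (is.null(best)) stop("every grid point retained 0 SNPs")
  new("GrsModel", method = method, mode = mode, hyper = best$hyper,
      snps = best$snps, forest = best$forest, weights = numeric(0),
      objective = best$objective, covariates = colnames(cov) %||% character(0))
}

#' Train the additive clumping-and-thresholding baseline (oCT)
#'
#' Classical C+T score: per grid point over (r2_cutoff, p_threshold), the
#' GRS is the weighted allele-count sum \eqn{\sum_m \hat\beta_m x_{im}}
#' over the retained SNPs, with weights taken from the sourced summary
#' statistics. The point maximizing the training Nagelkerke R-squared wins
#' (same tie-breaks as [trainRfGrs()]).
#'
#' @inheritParams trainRfGrs
#' @return a [GrsModel-class] with additive weights and no forest.
#' @export
trainOct <- function(mode, G_train, pheno_train, base = NULL,
                     grid = hyperGrid(), seed = 1L, stats = NULL,
                     window_bp = 250000L) {
  mode <- match.arg(mode, c("Tonly", "BT"))
  if (is.null(stats)) stats <- sourcePvalues(mode, base, G_train, pheno_train)
  G <- G_train[, intersect(snpIds(G_train), snpIds(stats))]
  stats <- stats[match(snpIds(G), snpIds(stats))]
  y <- unname(outcome(pheno_train))
  cov <- covariates(pheno_train)
  null_mode <- if (ncol(cov)) "incremental" else "marginal"
  s <- statsTable(stats)
  betas <- setNames(s$beta, s$id)
  x <- genotypes(G)
  storage.mode(x) <- "double"

  ct_grid <- .effectiveGrid("oCT", grid)
  clump_cache <- new.env(parent = emptyenv())
  best <- NULL
  for (gi in seq_len(nrow(ct_grid))) {
    r2 <- ct_grid$r2[gi]
    p_thr <- ct_grid$p_thr[gi]
    key <- format(r2, digits = 15)
    if (is.null(clump_cache[[key]]))
      clump_cache[[key]] <- clumpSnps(stats, G,
        clumpParams(r2_cutoff = r2, window_bp = window_bp))
    retained <- thresholdSnps(stats, p_thr, ids = clump_cache[[key]])
    if (!length(retained)) {
      warning(sprintf("grid point (r2=%g, p=%g) retains 0 SNPs; skipped",
                      r2, p_thr))
      next
    }
    score <- drop(x[, retained, drop = FALSE] %*% betas[retained])
    obj <- nagelkerkeR2(y, score, covariates = cov, null_mode = null_mode)
    cand <- list(objective = as.numeric(obj), snps = retained,
                 hyper = list(r2_cutoff = r2, p_threshold = p_thr))
    if (.betterPoint(cand, best)) best <- cand
  }
  if (is.null(best)) stop("every grid point retained 0 SNPs")
  new("GrsModel", method = "oCT", mode = mode, hyper = best$hyper,
      snps = best$snps, forest = NULL, weights = betas[best$snps],
      objective = best$objective, covariates = colnames(cov) %||% character(0))
}

#' Score samples with a trained GRS model
#'
#' RF methods return the forest's estimated disease probability over the
#' retained SNPs (plus covariates); oCT returns the additive weighted
#' allele-count sum. Deterministic.
#'
#' @param model a [GrsModel-class].
#' @param G a [GenotypeMatrix-class] covering the model's retained SNPs.
#' @param covariates covariate matrix (RF models trained with covariates).
#' @return named per-sample scores.
#' @export
predictGrs <- function(model, G, covariates = NULL) {
  miss <- setdiff(model@snps, snpIds(G))
  if (length(miss))
    stop("genotypes lack ", length(miss), " retained SNP(s), e.g. ", miss[1])
  Gr <- G[, model@snps]
  if (model@method == "oCT") {
    x <- genotypes(Gr)
    storage.mode(x) <- "double"
    setNames(drop(x %*% model@weights), sampleIds(Gr))
  } else {
    predictProba(model@forest, Gr, covariates)
  }
}

#' Save / load a trained GRS model
#'
#' Serialized as a versioned R list (RDS): version tag, method, mode,
#' hyperparameters, retained SNPs, additive weights, and the full forest
#' node tables, so training and prediction can be separate invocations.
#'
#' @param model a [GrsModel-class].
#' @param path file path.
#' @return `writeGrsModel`: the path, invisibly; `readGrsModel`: the
#'   restored [GrsModel-class].
#' @export
writeGrsModel <- function(model, path) {
  f <- model@forest
  payload <- list(
    format = "forestGRS-model", version = 1L,
    method = model@method, mode = model@mode, hyper = model@hyper,
    snps = model@snps, weights = model@weights,
    objective = model@objective, covariates = model@covariates,
    forest = if (is.null(f)) NULL else list(
      trees = f@trees, inbag = f@inbag, feature_names = f@feature_names,
      is_snp = f@is_snp, n_train = f@n_train,
      config = list(ntree = f@config@ntree, mtry = f@config@mtry,
                    min_node_size = f@config@min_node_size,
                    split_weights = f@config@split_weights,
                    bootstrap = f@config@bootstrap, seed = f@config@seed)))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname writeGrsModel
#' @export
readGrsModel <- function(path) {
  pl <- readRDS(path)
  if (!identical(pl$format, "forestGRS-model"))
    stop("not a forestGRS model file: ", path)
  forest <- NULL
  if (!is.null(pl$forest)) {
    fc <- pl$forest$config
    forest <- new("GrsForest", trees = pl$forest$trees,
                  inbag = pl$forest$inbag,
                  feature_names = pl$forest$feature_names,
                  is_snp = pl$forest$is_snp,
                  config = forestConfig(ntree = fc$ntree, mtry = fc$mtry,
                                        min_node_size = fc$min_node_size,
                                        split_weights = fc$split_weights,
                                        bootstrap = fc$bootstrap,
                                        seed = fc$seed),
                  n_train = pl$forest$n_train)
  }
  new("GrsModel", method = pl$method, mode = pl$mode, hyper = pl$hyper,
      snps = pl$snps, forest = forest, weights = pl$weights,
      objective = pl$objective, covariates = pl$covariates)
}
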