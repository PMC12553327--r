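#' Nagelkerke pseudo R-squared
#'
#' Fits the logistic regression of the outcome on the score (the "full"
#' model) and compares it with a null model by
#' \deqn{NR^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}}
#' with maximized likelihoods \eqn{L_0} (null) and \eqn{L_1} (full).
#' `null_mode = "marginal"` uses an intercept-only null;
#' `"incremental"` adds the covariates to both models, so the statistic
#' measures the score's contribution beyond the covariates. A constant
#' score contributes nothing and returns 0. If the full fit separates
#' (fitted probabilities numerically 0/1), the value is still reported
#' but carries attribute `separation = TRUE`.
#'
#' @param y binary outcome (both classes present).
#' @param score finite numeric per-sample score.
#' @param covariates optional covariate matrix.
#' @param null_mode "marginal" or "incremental".
#' @return NR2 in [0, 1].
#' @export
nagelkerkeR2 <- function(y, score, covariates = NULL,
                         null_mode = c("marginal", "incremental")) {
  null_mode <- match.arg(null_mode)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (any(!is.finite(score))) stop("scores must be finite")
  n <- length(y)
  cv <- covariates
  if (!is.null(cv)) {
    cv <- as.matrix(cv)
    if (ncol(cv) == 0L) cv <- NULL
  }
  use_cov <- !is.null(cv) && null_mode == "incremental"

  if (stats::sd(score) == 0) {
    out <- 0
    attr(out, "separation") <- FALSE
    return(out)
  }
  x_null <- if (use_cov) cbind(1, cv) else matrix(1, n, 1)
  x_full <- cbind(x_null, score = score)
  sep <- FALSE
  loglik <- function(xm) {
    fit <- suppressWarnings(stats::glm.fit(xm, y, family = stats::binomial()))
    mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
    if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10))
      sep <<- TRUE
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  ll0 <- loglik(x_null)
  ll1 <- loglik(x_full)
  cs <- 1 - exp(2 * (ll0 - ll1) / n)      # Cox-Snell
  denom <- 1 - exp(2 * ll0 / n)
  out <- max(0, min(1, cs / denom))
  attr(out, "separation") <- sep
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random case scores
#' above a random control, ties counting one half.
#'
#' @param y binary outcome (both classes present).
#' @param score numeric scores.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(y, score) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random train/test split plan
#'
#' Class-agnostic random assignment of samples to a training fraction
#' (default 80%) and its complementary test set.
#'
#' @param n sample count.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitPlan <- function(n, train_frac = 0.8, seed = 1L) {
  n_train <- round(n * train_frac)
  train <- .withSeed(seed, sort(sample(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

# Fold assignment for k-fold CV; redrawn stratified by class if any fold
# lacks a class.
.foldAssign <- function(y, k, seed) {
  folds <- .withSeed(seed, sample(rep(seq_len(k), length.out = length(y))))
  bad <- any(vapply(seq_len(k), function(f)
    length(unique(y[folds == f])) < 2L, logical(1)))
  if (bad) {
    message("a fold lacked a class; redrawing folds stratified by outcome")
    folds <- integer(length(y))
    folds[y == 1L] <- .withSeed(seed + 1L,
      sample(rep(seq_len(k), length.out = sum(y == 1L))))
    folds[y == 0L] <- .withSeed(seed + 2L,
      sample(rep(seq_len(k), length.out = sum(y == 0L))))
  }
  folds
}

#' Train one GRS method on a training split
#'
#' Dispatch helper shared by the cross-validation and experiment drivers.
#' @inheritParams trainRfGrs
#' @export
trainGrs <- function(method, mode, G_train, pheno_train, base = NULL,
                     grid = hyperGrid(), seed = 1L, stats = NULL,
                     window_bp = 250000L) {
  if (method == "oCT")
    trainOct(mode, G_train, pheno_train, base, grid, seed, stats, window_bp)
  else
    trainRfGrs(method, mode, G_train, pheno_train, base, grid, seed, stats,
               window_bp)
}

#' 5-fold cross-validated Nagelkerke R-squared
#'
#' Splits the samples into `k` disjoint folds; per fold, trains the method
#' on the remaining folds and evaluates NR2 of the predicted scores on the
#' held-out fold. Reports the per-fold values and their mean.
#'
#' @inheritParams trainRfGrs
#' @param G,pheno the full target data.
#' @param k fold count.
#' @return list with `mean`, `per_fold`, and the fold assignment.
#' @export
crossvalNr2 <- function(G, pheno, method, mode = "Tonly", base = NULL,
                        grid = hyperGrid(), seed = 1L, k = 5L,
                        window_bp = 250000L) {
  y <- unname(outcome(pheno))
  if (length(y) < 50L) stop("cross-validation needs at least 50 samples")
  folds <- .foldAssign(y, k, seed)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    model <- trainGrs(method, mode, G[tr, ], pheno[tr], base, grid,
                      seed = seed + 1000L * f, window_bp = window_bp)
    sc <- predictGrs(model, G[te, ], covariates(pheno)[te, , drop = FALSE])
    per_fold[f] <- as.numeric(nagelkerkeR2(
      y[te], sc, covariates = covariates(pheno)[te, , drop = FALSE],
      null_mode = if (ncol(covariates(pheno))) "incremental" else "marginal"))
  }
  list(mean = mean(per_fold), per_fold = per_fold, folds = folds)
}

#' Replicated simulation experiment
#'
#' Reproduces the simulation protocol at configurable scale: per
#' replication, simulate a shared genotype pool with blockwise LD, draw
#' paired base/target causal architectures sharing `config@q` causal SNPs,
#' simulate both cohorts' phenotypes, compute base summary statistics by a
#' marginal scan of the base cohort (when any "BT" mode is requested),
#' split the target cohort 80/20, train every requested (method, mode) on
#' the training split, and record test-set NR2 and AUC. Per-replication
#' seeds derive from the master seed by a fixed counter stream, and grid
#' points are seeded by their settings, so every method sees identical
#' data and removing one method leaves the others' numbers unchanged.
#' Failures in a replication are recorded and the run continues.
#'
#' @param scenarios character vector of scenarios ("1".."5b").
#' @param methods subset of \{"ctRF","cRF","tRF","wRF","oRF","oCT"\}.
#' @param modes subset of \{"Tonly","BT"\}.
#' @param reps replication count.
#' @param config a [SimConfig-class].
#' @param seed master seed.
#' @param grid tuning grid (default [deskGrid()]).
#' @param ld_spec an [LDBlockSpec-class]; defaults to blocks of 20 SNPs
#'   covering `config@n_snps`.
#' @param train_frac training fraction of the target cohort.
#' @param balance_prevalence centre each cohort's intercept via
#'   [centerIntercept()] before drawing phenotypes (default TRUE).
#' @return data.frame with one row per (scenario, method, mode,
#'   replication): test `nr2`, test `auc`, chosen hyperparameters,
#'   retained SNP count and the replication seed. Failed replications
#'   appear with NA metrics and the error message.
#' @export
runExperiment <- function(scenarios = "2", methods = c("ctRF", "oCT"),
                          modes = "Tonly", reps = 10L,
                          config = simConfig(), seed = 1L,
                          grid = deskGrid(), ld_spec = NULL,
                          train_frac = 0.8, balance_prevalence = TRUE) {
  if (is.null(ld_spec)) ld_spec <- ldBlockSpec(n_snps = config@n_snps)
  rows <- list()
  need_base <- "BT" %in% modes
  for (scenario in as.character(scenarios)) {
    for (r in seq_len(reps)) {
      rep_seed <- as.integer((as.numeric(seed) + 104729 * r) %% 2147483647)
      res <- tryCatch(
        .runOneRep(scenario, methods, modes, config, rep_seed, grid,
                   ld_spec, train_frac, need_base, balance_prevalence),
        error = function(e)
          data.frame(method = NA_character_, mode = NA_character_,
                     nr2 = NA_real_, auc = NA_real_,
                     r2_cutoff = NA_real_, p_threshold = NA_real_,
                     ntree = NA_integer_, mtry = NA_integer_,
                     min_node_size = NA_integer_, n_retained = NA_integer_,
                     error = conditionMessage(e)))
      if (is.null(res$error)) res$error <- NA_character_
      res$scenario <- scenario
      res$rep <- r
      res$seed <- rep_seed
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.runOneRep <- function(scenario, methods, modes, config, rep_seed, grid,
                       ld_spec, train_frac, need_base, balance_prevalence) {
  n_pool <- config@n_target + config@n_base
  G_pool <- simulateGenotypes(n_pool, ld_spec, seed = rep_seed)
  mafs <- unname(maf(G_pool))
  models <- makeBaseTarget(scenario, config, seed = rep_seed + 1L, maf = mafs)
  pick <- .withSeed(rep_seed + 2L, sample(n_pool, config@n_target))
  G_target <- G_pool[sort(pick), ]
  G_base <- G_pool[setdiff(seq_len(n_pool), pick), ]

  em_t <- models$target
  em_b <- models$base
  if (balance_prevalence) {
    em_t <- centerIntercept(G_target, em_t)
    em_b <- centerIntercept(G_base, em_b)
  }
  pheno_t <- simulatePhenotype(G_target, em_t, seed = rep_seed + 3L)
  base_stats <- NULL
  if (need_base) {
    pheno_b <- simulatePhenotype(G_base, em_b, seed = rep_seed + 4L)
    base_stats <- marginalScan(G_base, pheno_b)
  }

  sp <- splitPlan(nSamples(G_target), train_frac, seed = rep_seed + 5L)
  G_tr <- G_target[sp$train, ]
  G_te <- G_target[sp$test, ]
  ph_tr <- pheno_t[sp$train]
  y_te <- unname(outcome(pheno_t))[sp$test]

  stats_cache <- list()
  rows <- list()
  for (mode in modes) {
    stats <- stats_cache[[mode]]
    if (is.null(stats)) {
      stats <- suppressWarnings(
        sourcePvalues(mode, base_stats, G_tr, ph_tr))
      stats_cache[[mode]] <- stats
    }
    for (method in methods) {
      model <- suppressWarnings(
        trainGrs(method, mode, G_tr, ph_tr, base_stats, grid,
                 seed = rep_seed, stats = stats))
      sc <- predictGrs(model, G_te)
      h <- model@hyper
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, mode = mode,
        nr2 = as.numeric(nagelkerkeR2(y_te, sc)),
        auc = aucScore(y_te, sc),
        r2_cutoff = h$r2_cutoff %||% NA_real_,
        p_threshold = h$p_threshold %||% NA_real_,
        ntree = h$ntree %||% NA_integer_,
        mtry = h$mtry %||% NA_integer_,
        min_node_size = h$min_node_size %||% NA_integer_,
        n_retained = length(model@snps),
        error = NA_character_)
    }
  }
  do.call(rbind, rows)
}
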