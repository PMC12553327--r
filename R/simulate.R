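#' @importFrom stats rnorm qnorm rbinom plogis pnorm runif setNames
NULL

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Simulate genotypes with blockwise LD
#'
#' Per SNP, a latent standard-normal vector — AR(1) within LD blocks with
#' adjacent correlation `rho`, independent across blocks — is thresholded at
#' the quantiles implied by Hardy-Weinberg genotype frequencies for a MAF
#' drawn uniformly from the block spec's `maf_range`. Counts are then oriented to
#' the empirical minor allele. Positions are block-contiguous multiples of
#' `bp_spacing`. Deterministic given `seed`.
#'
#' @param n sample count.
#' @param spec an [LDBlockSpec-class].
#' @param seed integer seed.
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(n, spec = ldBlockSpec(), seed = 1L) {
  stopifnot(is(spec, "LDBlockSpec"), n >= 1)
  validObject(spec)
  m <- sum(spec@block_sizes)
  .withSeed(seed, {
    mafs <- runif(m, spec@maf_range[1], spec@maf_range[2])
    counts <- matrix(0L, nrow = n, ncol = m)
    col <- 0L
    rho <- spec@rho
    for (bs in spec@block_sizes) {
      z <- matrix(0, nrow = n, ncol = bs)
      z[, 1] <- rnorm(n)
      if (bs > 1) {
        innov <- sqrt(1 - rho^2)
        for (k in 2:bs) z[, k] <- rho * z[, k - 1] + innov * rnorm(n)
      }
      for (k in seq_len(bs)) {
        p <- mafs[col + k]
        q1 <- qnorm((1 - p)^2)           # P(x = 0) under HWE
        q2 <- qnorm((1 - p)^2 + 2 * p * (1 - p))
        counts[, col + k] <- (z[, k] >= q1) + (z[, k] >= q2)
      }
      col <- col + bs
    }
    variants <- data.frame(
      id = sprintf("snp%05d", seq_len(m)), chrom = spec@chrom,
      pos = seq_len(m) * spec@bp_spacing, ref = "A", alt = "B",
      stringsAsFactors = FALSE)
    rownames(counts) <- sprintf("ind%05d", seq_len(n))
    .orientMinor(counts, variants)
  })
}

# Positional architecture shared by drawEffects and makeBaseTarget:
# causal ids in draw order, a +/-1 sign per causal position, and term
# definitions as positions into the causal vector.
.drawArchitecture <- function(scenario, config, maf = NULL) {
  m <- config@n_snps
  pool <- seq_len(m)
  if (scenario == "5b") {
    if (is.null(maf))
      stop("scenario 5b needs per-SNP MAFs to restrict the causal pool")
    pool <- which(maf > 0.3)
    if (length(pool) < 100L)
      stop("scenario 5b needs at least 100 SNPs with MAF > 0.3; have ",
           length(pool))
  }
  causal <- sample(pool, 100L)
  # Exactly half of the signs are flipped within each 50-position half, so
  # scenarios using all 100 positions get 50 negatives and scenario 3
  # (main effects on positions 1-50) gets exactly 25.
  sgn <- c(sample(rep(c(1, -1), each = 25L)),
           sample(rep(c(1, -1), each = 25L)))
  arch <- list(scenario = scenario, causal = as.integer(causal), sign = sgn,
               main_pos = integer(0), pair_pos = NULL, triple_pos = NULL,
               quad_pos = integer(0))
  if (scenario %in% c("1", "3"))
    arch$main_pos <- if (scenario == "1") 1:100 else 1:50
  if (scenario %in% c("2", "3")) {
    grid <- expand.grid(l = 1:50, r = 51:100)
    pick <- sample(nrow(grid), 100L)
    arch$pair_pos <- grid[pick, ]
  }
  if (scenario == "4") {
    grid <- expand.grid(a = 1:33, b = 34:66, c = 67:99)
    pick <- sample(nrow(grid), 30L)
    arch$triple_pos <- grid[pick, ]
  }
  if (scenario %in% c("5a", "5b")) arch$quad_pos <- 1:100
  arch
}

# Draw betas for an architecture. Main and quadratic effects get the
# positional sign pattern (exactly half of the 100 positions are negative);
# interaction effects are drawn unflipped.
.drawBetas <- function(arch, config) {
  list(
    main = rnorm(length(arch$main_pos), config@mu_main, config@sd) *
      arch$sign[arch$main_pos],
    pair = if (is.null(arch$pair_pos)) numeric(0) else
      rnorm(nrow(arch$pair_pos), config@mu_int, config@sd),
    triple = if (is.null(arch$triple_pos)) numeric(0) else
      rnorm(nrow(arch$triple_pos), config@mu_int, config@sd),
    quad = rnorm(length(arch$quad_pos), config@mu_main, config@sd) *
      arch$sign[arch$quad_pos])
}

.architectureToModel <- function(arch, betas, beta0) {
  cz <- arch$causal
  main <- data.frame(snp = cz[arch$main_pos], beta = betas$main)
  pairs <- if (is.null(arch$pair_pos))
    data.frame(snp1 = integer(0), snp2 = integer(0), beta = numeric(0))
  else data.frame(snp1 = cz[arch$pair_pos$l], snp2 = cz[arch$pair_pos$r],
                  beta = betas$pair)
  triples <- if (is.null(arch$triple_pos))
    data.frame(snp1 = integer(0), snp2 = integer(0), snp3 = integer(0),
               beta = numeric(0))
  else data.frame(snp1 = cz[arch$triple_pos$a], snp2 = cz[arch$triple_pos$b],
                  snp3 = cz[arch$triple_pos$c], beta = betas$triple)
  quads <- data.frame(snp = cz[arch$quad_pos], beta = betas$quad)
  new("EffectModel", scenario = arch$scenario, causal = cz,
      beta0 = beta0, main = main, pairs = pairs, triples = triples,
      quads = quads)
}

#' Draw a causal-architecture effect model
#'
#' Samples 100 causal SNPs uniformly without replacement (scenario 5b:
#' only among SNPs with MAF > 0.3) and draws effect sizes from
#' Normal(mu, sd) with exactly half of the main/quadratic effect signs
#' flipped to negative; interaction effects are left unflipped. Scenario
#' structure: 1 = 100 additive terms; 2 = 100 two-way interactions pairing
#' causal SNPs 1-50 with 51-100; 3 = 50 additive + 100 two-way; 4 = 30
#' three-way interactions, one SNP from each of three disjoint groups of
#' 33; 5a/5b = 100 quadratic terms.
#'
#' @param scenario one of "1","2","3","4","5a","5b".
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @param maf per-SNP MAFs (required for scenario "5b").
#' @return an [EffectModel-class].
#' @export
drawEffects <- function(scenario, config = simConfig(), seed = config@seed,
                        maf = NULL) {
  scenario <- as.character(scenario)
  .withSeed(seed, {
    arch <- .drawArchitecture(scenario, config, maf)
    betas <- .drawBetas(arch, config)
    .architectureToModel(arch, betas, config@beta0)
  })
}

#' Linear predictor of an effect model
#'
#' @param G a [GenotypeMatrix-class] (no missing entries among causal SNPs).
#' @param em an [EffectModel-class] whose causal indices refer to columns
#'   of `G`.
#' @return numeric per-sample log-odds eta.
#' @export
linearPredictor <- function(G, em) {
  x <- genotypes(G)
  if (max(em@causal) > ncol(x))
    stop("effect model refers to SNP columns beyond the genotype matrix")
  eta <- rep(em@beta0, nrow(x))
  if (nrow(em@main))
    eta <- eta + x[, em@main$snp, drop = FALSE] %*% em@main$beta
  if (nrow(em@pairs))
    eta <- eta + (x[, em@pairs$snp1, drop = FALSE] *
                  x[, em@pairs$snp2, drop = FALSE]) %*% em@pairs$beta
  if (nrow(em@triples))
    eta <- eta + (x[, em@triples$snp1, drop = FALSE] *
                  x[, em@triples$snp2, drop = FALSE] *
                  x[, em@triples$snp3, drop = FALSE]) %*% em@triples$beta
  if (nrow(em@quads))
    eta <- eta + (x[, em@quads$snp, drop = FALSE]^2) %*% em@quads$beta
  drop(eta)
}

#' Simulate a binary phenotype from an effect model
#'
#' Draws \eqn{y_i \sim Bernoulli(expit(\eta_i))} with \eqn{\eta} the
#' model's log-odds linear predictor. Deterministic given `seed`.
#'
#' @inheritParams linearPredictor
#' @param seed integer seed.
#' @return a [PhenotypeTable-class] with no covariates.
#' @export
simulatePhenotype <- function(G, em, seed = 1L) {
  eta <- linearPredictor(G, em)
  y <- .withSeed(seed, rbinom(length(eta), 1L, plogis(eta)))
  PhenotypeTable(sampleIds(G), y)
}

#' Center an effect model's intercept on a cohort
#'
#' Sets `beta0` to minus the mean log-odds linear predictor over the given
#' genotypes, so the simulated prevalence sits near 0.5. The causal
#' scenarios accumulate all-positive interaction effects with no
#' intercept, so uncentered prevalence drifts with the effect-size mean;
#' centering keeps both outcome classes well represented. Deterministic
#' (no randomness involved).
#'
#' @param G the cohort's [GenotypeMatrix-class].
#' @param em an [EffectModel-class].
#' @return the model with adjusted `beta0`.
#' @export
centerIntercept <- function(G, em) {
  em@beta0 <- em@beta0 - mean(linearPredictor(G, em))
  em
}

#' Draw paired base/target effect models sharing q causal SNPs
#'
#' The target model is drawn first; the base model keeps the same term
#' structure over the causal-position vector. A random set of q causal
#' positions is shared: those positions keep the target's SNPs and every
#' term wholly inside the shared set keeps the target's effect size
#' bitwise. The remaining 100 - q base positions get fresh SNPs (disjoint
#' from all target causal SNPs) and terms touching them get freshly drawn
#' effect sizes by the same Normal(mu, sd) procedure, with the positional
#' sign pattern retained.
#'
#' @param scenario one of "1","2","3","4","5a","5b".
#' @param config a [SimConfig-class]; `config@q` is the shared count.
#' @param seed integer seed.
#' @param maf per-SNP MAFs (scenario "5b").
#' @return list with elements `target` and `base`, both
#'   [EffectModel-class], plus `shared_pos` (shared causal positions).
#' @export
makeBaseTarget <- function(scenario, config = simConfig(),
                           seed = config@seed, maf = NULL) {
  scenario <- as.character(scenario)
  q <- config@q
  .withSeed(seed, {
    arch_t <- .drawArchitecture(scenario, config, maf)
    betas_t <- .drawBetas(arch_t, config)

    shared <- sort(sample(100L, q))
    is_shared <- seq_len(100L) %in% shared

    pool <- seq_len(config@n_snps)
    if (scenario == "5b") pool <- which(maf > 0.3)
    pool <- setdiff(pool, arch_t$causal)
    n_new <- 100L - q
    if (length(pool) < n_new)
      stop("not enough SNPs for disjoint base-unique causal set")
    arch_b <- arch_t
    if (n_new > 0)
      arch_b$causal[!is_shared] <- as.integer(sample(pool, n_new))

    betas_b <- .drawBetas(arch_b, config)
    keep <- is_shared[arch_t$main_pos]
    betas_b$main[keep] <- betas_t$main[keep]
    if (!is.null(arch_t$pair_pos)) {
      keep <- is_shared[arch_t$pair_pos$l] & is_shared[arch_t$pair_pos$r]
      betas_b$pair[keep] <- betas_t$pair[keep]
    }
    if (!is.null(arch_t$triple_pos)) {
      keep <- is_shared[arch_t$triple_pos$a] & is_shared[arch_t$triple_pos$b] &
        is_shared[arch_t$triple_pos$c]
      betas_b$triple[keep] <- betas_t$triple[keep]
    }
    keep <- is_shared[arch_t$quad_pos]
    betas_b$quad[keep] <- betas_t$quad[keep]

    list(target = .architectureToModel(arch_t, betas_t, config@beta0),
         base = .architectureToModel(arch_b, betas_b, config@beta0),
         shared_pos = shared)
  })
}
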