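# Shared fixtures and independent oracles for the test suite.

# Small hand-specified genotype matrix with evenly spaced positions.
toyGenotypes <- function(counts, chrom = "21", spacing = 1000L) {
  m <- ncol(counts)
  GenotypeMatrix(counts, data.frame(
    id = paste0("rs", seq_len(m)), chrom = chrom,
    pos = seq_len(m) * spacing, ref = "A", alt = "B"))
}

# Random complete genotype matrix (not via the package simulator, so io
# round-trips are tested against an independent construction).
randomGenotypes <- function(n, m, seed, p_missing = 0) {
  set.seed(seed)
  counts <- matrix(rbinom(n * m, 2L, runif(m, 0.15, 0.5)[rep(seq_len(m),
                                                             each = n)]),
                   nrow = n)
  if (p_missing > 0)
    counts[runif(n * m) < p_missing] <- NA_integer_
  # orient to the empirical minor allele so io round-trips are identities
  f <- colMeans(counts, na.rm = TRUE) / 2
  flip <- which(!is.nan(f) & f > 0.5)
  counts[, flip] <- 2L - counts[, flip]
  toyGenotypes(counts)
}

# ---- independent oracles -------------------------------------------------

# Route one sample through one stored tree (pure R re-implementation of the
# traversal; shares no code with the C++ prediction path).
routeOracle <- function(tree, xrow) {
  node <- 1L
  repeat {
    f <- tree$feature[node]
    if (f < 0L) return(tree$prop[node])
    goLeft <- if (tree$cat_left[node] >= 0L)
      xrow[f + 1L] == tree$cat_left[node]
    else xrow[f + 1L] <= tree$threshold[node]
    node <- (if (goLeft) tree$left[node] else tree$right[node]) + 1L
  }
}

# Sequential double-precision accumulation in tree order, mirroring the
# arithmetic order of the prediction path so equality can be exact.
predictOracle <- function(forest, featmat) {
  ntree <- length(forest@trees)
  vapply(seq_len(nrow(featmat)), function(i) {
    tot <- 0
    for (tr in forest@trees) tot <- tot + routeOracle(tr, featmat[i, ])
    tot / ntree
  }, numeric(1))
}

# Brute-force greedy clumping oracle: recomputes r^2 from scratch with cor()
# and re-implements the greedy loop independently.
clumpOracle <- function(stats, G, r2_cutoff, window_bp) {
  s <- as.data.frame(statsTable(stats))
  v <- as.data.frame(variantInfo(G))[match(s$id, snpIds(G)), ]
  x <- genotypes(G)[, match(s$id, snpIds(G)), drop = FALSE]
  ord <- order(s$p, v$chrom, v$pos, s$id, method = "radix")
  assigned <- rep(FALSE, nrow(s))
  kept <- character(0)
  for (k in ord) {
    if (assigned[k]) next
    kept <- c(kept, s$id[k])
    assigned[k] <- TRUE
    for (j in seq_len(nrow(s))) {
      if (assigned[j] || v$chrom[j] != v$chrom[k] ||
          abs(v$pos[j] - v$pos[k]) > window_bp) next
      r2 <- suppressWarnings(cor(x[, k], x[, j])^2)
      if (!is.na(r2) && r2 > r2_cutoff) assigned[j] <- TRUE
    }
  }
  kept
}

# From-scratch logistic log-likelihood maximizer (optim, explicit Bernoulli
# log-likelihood) -- independent of glm.fit.
logLikOracle <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) -drop(crossprod(X, y - plogis(drop(X %*% b))))
  fit <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  -fit$value
}

nr2Oracle <- function(y, score) {
  n <- length(y)
  ll0 <- logLikOracle(matrix(1, n, 1), y)
  ll1 <- logLikOracle(cbind(1, score), y)
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

aucOracle <- function(y, score) {
  cases <- score[y == 1]
  ctrls <- score[y == 0]
  tot <- 0
  for (a in cases)
    for (b in ctrls)
      tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# Newton-Raphson logistic fit (independent of glm.fit) for scan checks.
newtonLogistic <- function(X, y, iter = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    mu <- plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, X * W), crossprod(X, y - mu))
    b <- unname(b + drop(step))
    if (max(abs(step)) < 1e-12) break
  }
  list(beta = b, vcov = solve(crossprod(X, X * plogis(drop(X %*% b)) *
                                          (1 - plogis(drop(X %*% b))))))
}

.withSeedTest <- function(seed, expr) {
  set.seed(seed)
  expr
}
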