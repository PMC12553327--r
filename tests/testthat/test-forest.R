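test_that("an unpruned single tree reproduces its training labels", {
  # distinct feature vectors, no conflicting labels -> pure leaves
  G <- randomGenotypes(40, 12, seed = 41)
  expect_equal(anyDuplicated(genotypes(G)), 0L)
  set.seed(42)
  y <- rbinom(40, 1, 0.5)
  ph <- PhenotypeTable(sampleIds(G), y)
  f <- fitForest(G, ph, forestConfig(ntree = 1L, mtry = 12L,
                                     min_node_size = 1L, bootstrap = FALSE,
                                     seed = 1))
  expect_equal(unname(predictProba(f, G)), as.numeric(y))
})

test_that("forests are seed-deterministic", {
  G <- randomGenotypes(60, 10, seed = 43)
  set.seed(44)
  ph <- PhenotypeTable(sampleIds(G), rbinom(60, 1, 0.5))
  cfg <- forestConfig(ntree = 25L, mtry = 3L, min_node_size = 2L, seed = 99)
  f1 <- fitForest(G, ph, cfg)
  f2 <- fitForest(G, ph, cfg)
  expect_identical(f1@trees, f2@trees)
  expect_identical(f1@inbag, f2@inbag)
  f3 <- fitForest(G, ph, forestConfig(ntree = 25L, mtry = 3L,
                                      min_node_size = 2L, seed = 100))
  expect_false(identical(f1@trees, f3@trees))
})

test_that("a single positive split weight forces every split onto that SNP", {
  G <- randomGenotypes(80, 8, seed = 45)
  set.seed(46)
  ph <- PhenotypeTable(sampleIds(G), rbinom(80, 1, 0.5))
  w <- c(0, 0, 0, 1, 0, 0, 0, 0)
  f <- fitForest(G, ph, forestConfig(ntree = 10L, mtry = 3L,
                                     min_node_size = 5L,
                                     split_weights = w, seed = 2))
  used <- unlist(lapply(f@trees, function(tr) tr$feature[tr$feature >= 0]))
  expect_true(all(used == 3L))  # 0-based index of the weighted SNP
})

test_that("prediction equals the brute-force traversal oracle bitwise", {
  G <- randomGenotypes(50, 9, seed = 47)
  set.seed(48)
  cov <- cbind(pc1 = rnorm(50))
  ph <- PhenotypeTable(sampleIds(G), rbinom(50, 1, 0.5), cov)
  f <- fitForest(G, ph, forestConfig(ntree = 30L, mtry = 4L,
                                     min_node_size = 3L, seed = 5))
  Gnew <- randomGenotypes(10, 9, seed = 49)
  set.seed(50)
  covnew <- cbind(pc1 = rnorm(10))
  feat <- cbind(genotypes(Gnew), covnew)
  storage.mode(feat) <- "double"
  colnames(feat) <- f@feature_names
  expect_identical(unname(predictProba(f, Gnew, covnew)),
                   predictOracle(f, feat))

  f1 <- fitForest(G, ph, forestConfig(ntree = 1L, mtry = 4L,
                                      min_node_size = 3L, seed = 5))
  expect_identical(unname(predictProba(f1, Gnew, covnew)),
                   vapply(seq_len(10), function(i)
                     routeOracle(f1@trees[[1]], feat[i, ]), numeric(1)))
})

test_that("an all-case cohort predicts probability one everywhere", {
  G <- randomGenotypes(30, 5, seed = 51)
  ph <- PhenotypeTable(sampleIds(G), rep(1L, 30))
  f <- fitForest(G, ph, forestConfig(ntree = 5L, mtry = 2L, seed = 3))
  expect_equal(unname(predictProba(f, G)), rep(1, 30))
})

test_that("the root split is the Gini argmax over features and partitions", {
  giniDec <- function(x, y, is_cat) {
    n <- length(y); n1 <- sum(y)
    g <- function(a, b) if (b == 0) 0 else 1 - (a / b)^2 - (1 - a / b)^2
    best <- 0
    if (is_cat) {
      for (v in 0:2) {
        nl <- sum(x == v)
        if (nl == 0 || nl == n) next
        nl1 <- sum(y[x == v])
        dec <- g(n1, n) - (nl * g(nl1, nl) + (n - nl) * g(n1 - nl1, n - nl)) / n
        best <- max(best, dec)
      }
    } else {
      sv <- sort(unique(x))
      for (k in seq_len(length(sv) - 1)) {
        thr <- (sv[k] + sv[k + 1]) / 2
        nl <- sum(x <= thr); nl1 <- sum(y[x <= thr])
        dec <- g(n1, n) - (nl * g(nl1, nl) + (n - nl) * g(n1 - nl1, n - nl)) / n
        best <- max(best, dec)
      }
    }
    best
  }
  for (r in 1:5) {
    G <- randomGenotypes(20, 6, seed = 700 + r)
    set.seed(800 + r)
    cov <- cbind(z = rnorm(20))
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    ph <- PhenotypeTable(sampleIds(G), y, cov)
    f <- fitForest(G, ph, forestConfig(ntree = 1L, mtry = 7L,
                                       min_node_size = 1L,
                                       bootstrap = FALSE, seed = r))
    tree <- f@trees[[1]]
    expect_gte(tree$feature[1], 0)
    feat <- cbind(genotypes(G), cov)
    best_all <- max(vapply(seq_len(7), function(j)
      giniDec(feat[, j], y, j <= 6), numeric(1)))
    # decrease achieved by the chosen root split
    fj <- tree$feature[1] + 1L
    chosen <- if (tree$cat_left[1] >= 0) {
      x <- feat[, fj]
      v <- tree$cat_left[1]
      n <- 20; n1 <- sum(y)
      g <- function(a, b) if (b == 0) 0 else 1 - (a / b)^2 - (1 - a / b)^2
      nl <- sum(x == v); nl1 <- sum(y[x == v])
      g(n1, n) - (nl * g(nl1, nl) + (n - nl) * g(n1 - nl1, n - nl)) / n
    } else {
      x <- feat[, fj]
      n <- 20; n1 <- sum(y)
      g <- function(a, b) if (b == 0) 0 else 1 - (a / b)^2 - (1 - a / b)^2
      nl <- sum(x <= tree$threshold[1]); nl1 <- sum(y[x <= tree$threshold[1]])
      g(n1, n) - (nl * g(nl1, nl) + (n - nl) * g(n1 - nl1, n - nl)) / n
    }
    expect_equal(chosen, best_all, tolerance = 1e-12)
  }
})

test_that("OOB probabilities cover almost all samples and lie in [0, 1]", {
  G <- randomGenotypes(100, 8, seed = 53)
  set.seed(54)
  ph <- PhenotypeTable(sampleIds(G), rbinom(100, 1, 0.5))
  f <- fitForest(G, ph, forestConfig(ntree = 200L, mtry = 3L, seed = 6))
  oob <- oobProba(f, G)
  # P(a sample is in-bag for all 200 trees) ~ (1 - e^-1)^200 ~ 1e-40
  expect_false(anyNA(oob))
  expect_true(all(oob >= 0 & oob <= 1))

  fno <- fitForest(G, ph, forestConfig(ntree = 5L, mtry = 3L,
                                       bootstrap = FALSE, seed = 6))
  expect_error(oobProba(fno, G), "bootstrap")
})

test_that("a sample OOB for exactly one tree gets that tree's proportion", {
  G <- randomGenotypes(25, 6, seed = 55)
  set.seed(56)
  ph <- PhenotypeTable(sampleIds(G), rbinom(25, 1, 0.5))
  f <- fitForest(G, ph, forestConfig(ntree = 3L, mtry = 3L, seed = 7))
  inbag <- do.call(cbind, f@inbag)
  oob_count <- rowSums(inbag == 0)
  oob <- oobProba(f, G)
  feat <- genotypes(G)
  storage.mode(feat) <- "double"
  one <- which(oob_count == 1L)
  expect_gt(length(one), 0L)
  for (s in one) {
    t_idx <- which(inbag[s, ] == 0)
    expect_identical(unname(oob[s]), routeOracle(f@trees[[t_idx]], feat[s, ]))
  }
})

test_that("uniform split weights sample candidates like unweighted draws", {
  G <- randomGenotypes(200, 10, seed = 57)
  set.seed(58)
  ph <- PhenotypeTable(sampleIds(G), rbinom(200, 1, 0.5))
  rootFeatures <- function(weights, seed) {
    f <- fitForest(G, ph, forestConfig(ntree = 400L, mtry = 1L,
                                       min_node_size = 150L,
                                       split_weights = weights, seed = seed))
    feats <- vapply(f@trees, function(tr) tr$feature[1], integer(1))
    feats[feats >= 0]
  }
  cu <- tabulate(rootFeatures(NULL, 11) + 1L, 10L)
  cw <- tabulate(rootFeatures(rep(1, 10), 12) + 1L, 10L)
  expect_gt(suppressWarnings(chisq.test(rbind(cu, cw))$p.value), 0.001)
})

test_that("weight-zero SNPs are never split candidates", {
  G <- randomGenotypes(100, 8, seed = 59)
  set.seed(60)
  ph <- PhenotypeTable(sampleIds(G), rbinom(100, 1, 0.5))
  w <- c(0, rep(1, 7))
  f <- fitForest(G, ph, forestConfig(ntree = 50L, mtry = 4L,
                                     split_weights = w, seed = 8))
  used <- unlist(lapply(f@trees, function(tr) tr$feature[tr$feature >= 0]))
  expect_false(0L %in% used)
})

test_that("OOB error vanishes when one SNP determines the outcome", {
  G <- randomGenotypes(500, 20, seed = 61)
  y <- as.integer(genotypes(G)[, 7] >= 1L)
  ph <- PhenotypeTable(sampleIds(G), y)
  f <- fitForest(G, ph, forestConfig(ntree = 200L, mtry = 5L, seed = 9))
  oob <- oobProba(f, G)
  expect_lt(mean(round(oob) != y), 0.02)
})

test_that("mtry larger than the feature count is a config error", {
  G <- randomGenotypes(20, 4, seed = 63)
  ph <- PhenotypeTable(sampleIds(G), rep_len(c(0L, 1L), 20))
  expect_error(fitForest(G, ph, forestConfig(ntree = 2L, mtry = 9L)),
               "mtry")
})

test_that("probability-machine predictions track ranger on shared data", {
  library(ranger)
  G <- simulateGenotypes(400, ldBlockSpec(n_snps = 40, block_size = 5),
                         seed = 64)
  x <- genotypes(G)
  set.seed(65)
  y <- rbinom(400, 1, plogis(0.9 * x[, 5] - 0.9 * x[, 25] +
                             0.6 * x[, 12] * x[, 30] - 0.3))
  ph <- PhenotypeTable(sampleIds(G), y)
  tr <- 1:300
  te <- 301:400
  f <- fitForest(G[tr, ], ph[tr],
                 forestConfig(ntree = 300L, mtry = 7L, min_node_size = 5L,
                              seed = 10))
  mine <- predictProba(f, G[te, ])
  df <- data.frame(y = factor(y[tr]), x[tr, ])
  rf <- ranger(y ~ ., data = df, num.trees = 300, mtry = 7,
               probability = TRUE, respect.unordered.factors = TRUE,
               seed = 11)
  theirs <- predict(rf, data.frame(x[te, ]))$predictions[, "1"]
  expect_gt(cor(mine, theirs), 0.75)
  expect_lt(abs(aucScore(y[te], mine) - aucScore(y[te], theirs)), 0.08)
})
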