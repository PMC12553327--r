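# Small shared training fixture: moderate signal, 120 SNPs.
grsFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    G <- simulateGenotypes(260, ldBlockSpec(n_snps = 120, block_size = 10),
                           seed = 71)
    em <- drawEffects("3", simConfig(n_snps = 120L, mu_main = log(1.5),
                                     mu_int = log(2)), seed = 72)
    em <- centerIntercept(G, em)
    ph <- simulatePhenotype(G, em, seed = 73)
    st <- suppressWarnings(marginalScan(G, ph))
    cache <<- list(G = G, ph = ph, st = st)
    cache
  }
})

smallGrid <- hyperGrid(r2_cutoffs = c(0.5, 1), p_thresholds = c(0.1, 1),
                       ntrees = 50L, mtry_rule = "sqrt",
                       min_node_sizes = 5L)

test_that("p-value sourcing matches its two advertised routes", {
  fx <- grsFixture()
  tonly <- sourcePvalues("Tonly", NULL, fx$G, fx$ph)
  direct <- suppressWarnings(marginalScan(fx$G, fx$ph))
  expect_identical(statsTable(tonly), statsTable(direct))

  base <- SummaryStats(snpIds(fx$G)[1:50], "B", seq(0.01, 0.5, length = 50),
                       p = seq(1e-6, 0.9, length = 50))
  bt <- sourcePvalues("BT", base, fx$G, fx$ph)
  expect_identical(statsTable(bt)$p, statsTable(base)$p)
  expect_identical(statsTable(bt)$beta, statsTable(base)$beta)

  expect_error(sourcePvalues("BT", NULL, fx$G, fx$ph), "requires base")
})

test_that("a single-point grid reproduces a direct fit at those settings", {
  fx <- grsFixture()
  g1 <- hyperGrid(r2_cutoffs = 1, p_thresholds = 1, ntrees = 40L,
                  mtrys = 6L, min_node_sizes = 5L)
  m1 <- trainRfGrs("ctRF", "Tonly", fx$G, fx$ph, grid = g1, seed = 13,
                   stats = fx$st)
  m2 <- trainRfGrs("ctRF", "Tonly", fx$G, fx$ph, grid = g1, seed = 13,
                   stats = fx$st)
  expect_identical(m1@hyper, list(r2_cutoff = 1, p_threshold = 1,
                                  ntree = 40L, mtry = 6L,
                                  min_node_size = 5L))
  expect_identical(m1@forest@trees, m2@forest@trees)
  expect_identical(predictGrs(m1, fx$G), predictGrs(m2, fx$G))
  # the model's forest is reproducible from its recorded config
  refit <- fitForest(fx$G[, m1@snps], fx$ph, m1@forest@config)
  expect_identical(refit@trees, m1@forest@trees)
})

test_that("ctRF's training objective dominates its single-axis ablations", {
  fx <- grsFixture()
  for (s in c(3, 17)) {
    ct <- trainRfGrs("ctRF", "Tonly", fx$G, fx$ph, grid = smallGrid,
                     seed = s, stats = fx$st)
    cr <- trainRfGrs("cRF", "Tonly", fx$G, fx$ph, grid = smallGrid,
                     seed = s, stats = fx$st)
    tr <- trainRfGrs("tRF", "Tonly", fx$G, fx$ph, grid = smallGrid,
                     seed = s, stats = fx$st)
    expect_gte(ct@objective, cr@objective)
    expect_gte(ct@objective, tr@objective)
  }
})

test_that("wRF weights split sampling by association strength", {
  fx <- grsFixture()
  m <- trainRfGrs("wRF", "Tonly", fx$G, fx$ph, grid = smallGrid, seed = 4,
                  stats = fx$st)
  expect_identical(m@hyper$r2_cutoff, 1)
  expect_identical(m@hyper$p_threshold, 1)
  w <- setNames(zToWeights(statsTable(fx$st)$z), snpIds(fx$st))
  # the minimum-z SNP has weight 0 and must never be split on; features
  # are stored in retained (p-ascending) order
  zero_idx <- match(names(w)[w == 0], m@forest@feature_names) - 1L
  used <- unlist(lapply(m@forest@trees,
                        function(tr) tr$feature[tr$feature >= 0]))
  expect_false(any(used %in% zero_idx))
  expect_identical(m@forest@config@split_weights,
                   unname(w[m@forest@feature_names]))
})

test_that("oRF ignores filtering entirely", {
  fx <- grsFixture()
  m <- trainRfGrs("oRF", "Tonly", fx$G, fx$ph, grid = smallGrid, seed = 5,
                  stats = fx$st)
  expect_setequal(m@snps, snpIds(fx$G))
})

test_that("the additive oCT score is the advertised linear functional", {
  counts <- cbind(c(0L, 1L, 2L, 1L), c(2L, 0L, 1L, 2L))
  G <- toyGenotypes(counts)
  ph <- PhenotypeTable(sampleIds(G), c(0L, 0L, 1L, 1L))
  st <- SummaryStats(snpIds(G), "B", beta = c(log(2), 0),
                     p = c(1e-6, 0.9))
  g <- hyperGrid(r2_cutoffs = 1, p_thresholds = 1e-4, ntrees = 10L,
                 mtrys = 1L, min_node_sizes = 1L)
  m <- trainOct("Tonly", G, ph, grid = g, stats = st)
  expect_identical(m@snps, "rs1")
  expect_equal(unname(predictGrs(m, G)), counts[, 1] * log(2))

  # a zero-beta SNP contributes nothing even when retained
  g2 <- hyperGrid(r2_cutoffs = 1, p_thresholds = 1, ntrees = 10L,
                  mtrys = 1L, min_node_sizes = 1L)
  m2 <- trainOct("Tonly", G, ph, grid = g2, stats = st)
  expect_setequal(m2@snps, c("rs1", "rs2"))
  expect_equal(unname(predictGrs(m2, G)), counts[, 1] * log(2))
})

test_that("oCT scores ignore SNPs outside the retained set", {
  fx <- grsFixture()
  m <- trainOct("Tonly", fx$G, fx$ph, grid = smallGrid, stats = fx$st)
  sc_full <- predictGrs(m, fx$G)
  # corrupt a non-retained SNP: scores unchanged
  other <- setdiff(snpIds(fx$G), m@snps)
  if (length(other)) {
    cts <- genotypes(fx$G)
    cts[, other[1]] <- 2L - cts[, other[1]]
    G2 <- GenotypeMatrix(cts, variantInfo(fx$G))
    expect_identical(sc_full, predictGrs(m, G2))
  }
  miss <- fx$G[, setdiff(snpIds(fx$G), m@snps[1])]
  expect_error(predictGrs(m, miss), "lack")
})

test_that("RF scores live in [0,1] and survive serialization bitwise", {
  fx <- grsFixture()
  m <- trainRfGrs("ctRF", "Tonly", fx$G, fx$ph, grid = smallGrid, seed = 6,
                  stats = fx$st)
  sc <- predictGrs(m, fx$G)
  expect_true(all(sc >= 0 & sc <= 1))
  path <- tempfile(fileext = ".rds")
  writeGrsModel(m, path)
  m2 <- readGrsModel(path)
  expect_identical(predictGrs(m2, fx$G), sc)
  expect_identical(m2@hyper, m@hyper)

  oct <- trainOct("Tonly", fx$G, fx$ph, grid = smallGrid, stats = fx$st)
  writeGrsModel(oct, path)
  expect_identical(predictGrs(readGrsModel(path), fx$G),
                   predictGrs(oct, fx$G))
})

test_that("single-tree unbootstrapped scores are terminal proportions", {
  fx <- grsFixture()
  g <- hyperGrid(r2_cutoffs = 1, p_thresholds = 1, ntrees = 1L, mtrys = 5L,
                 min_node_sizes = 10L)
  m <- trainRfGrs("oRF", "Tonly", fx$G, fx$ph, grid = g, seed = 7,
                  stats = fx$st)
  tree <- m@forest@trees[[1]]
  props <- tree$prop[tree$feature < 0]
  sc <- predictGrs(m, fx$G)
  expect_true(all(sc %in% props))
})

test_that("grid points retaining nothing are skipped with a warning", {
  fx <- grsFixture()
  # impossible threshold on one grid line, feasible on the other
  g <- hyperGrid(r2_cutoffs = 1, p_thresholds = c(1e-300, 1), ntrees = 20L,
                 mtrys = 5L, min_node_sizes = 5L)
  expect_warning(m <- trainRfGrs("ctRF", "Tonly", fx$G, fx$ph, grid = g,
                                 seed = 8, stats = fx$st),
                 "retains 0 SNPs")
  expect_identical(m@hyper$p_threshold, 1)
  g_bad <- hyperGrid(r2_cutoffs = 1, p_thresholds = 1e-300, ntrees = 20L,
                     mtrys = 5L, min_node_sizes = 5L)
  expect_error(suppressWarnings(
    trainRfGrs("ctRF", "Tonly", fx$G, fx$ph, grid = g_bad, seed = 8,
               stats = fx$st)), "every grid point")
})
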