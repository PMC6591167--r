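test_that("PCA conserves total variance and detects rank-1 structure", {
  set.seed(51)
  m <- randomSliceMatrix(30, 8)
  res <- pcaSamples(m)
  expect_equal(sum(res@eigenvalues), sum(apply(t(m), 2, var)),
               tolerance = 1e-10)
  expect_true(all(diff(res@eigenvalues) <= 1e-10))
  expect_lte(sum(res@varExplained), 1 + 1e-10)
  # one perfectly collinear direction -> a single nonzero eigenvalue
  v <- rnorm(6)
  rank1 <- outer(rnorm(20), v)
  rownames(rank1) <- sprintf("g%d", 1:20)
  ev <- pcaSamples(rank1)@eigenvalues
  expect_gt(ev[1], 1e-8)
  expect_true(all(ev[-1] < 1e-8))
})

test_that("two-group data separate along leading components", {
  sim <- simulateExpression(dnbSimConfig(nGenes = 200, nDnb = 10,
                                         degEffect = 3, seed = 53))
  res <- pcaSamples(sim$dataset)
  grp <- sampleGroups(sim$dataset)
  s1 <- res@scores[, 1]
  # silhouette-like check: group means on PC1 farther apart than spreads
  gap <- abs(mean(s1[grp == "case"]) - mean(s1[grp == "control"]))
  expect_gt(gap, mean(tapply(s1, grp, sd)))
})

test_that("parallel analysis finds a planted factor and is deterministic", {
  sim <- simulateExpression(dnbSimConfig(nGenes = 150, nDnb = 30,
                                         sdRatio = 4, targetAbsCorr = 0.8,
                                         seed = 57))
  pa1 <- parallelAnalysis(sim$dataset, nShuffles = 30, seed = 5)
  pa2 <- parallelAnalysis(sim$dataset, nShuffles = 30, seed = 5)
  expect_gte(nMeaningful(pa1), 1)
  expect_identical(nMeaningful(pa1), nMeaningful(pa2))
  expect_identical(pa1@nullQuantiles, pa2@nullQuantiles)
})

test_that("pure noise yields few meaningful components", {
  hits <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    m <- randomSliceMatrix(80, 12)
    nMeaningful(parallelAnalysis(m, nShuffles = 30, seed = s))
  }, 0L)
  expect_gte(mean(hits <= 2), 0.9)
})

test_that("correlation clustering resolves perfect two-block structure", {
  v <- rnorm(12)
  m <- rbind(t(sapply(1:5, function(i) i * v + i)),        # r = 1 block
             t(sapply(1:4, function(i) -i * v + i)))       # r = -1 block
  rownames(m) <- sprintf("g%d", 1:9)
  cl <- clusterGenes(m, cutoff = 0.5)
  expect_identical(length(clusterSizes(cl)), 2L)
  expect_identical(clusterSizes(cl), c(5L, 4L))
  expect_length(unique(clusterLabels(cl)[1:5]), 1)
  expect_length(unique(clusterLabels(cl)[6:9]), 1)
  # all genes affine copies of one pattern -> a single cluster
  mm <- t(sapply(1:6, function(i) i * v + i))
  rownames(mm) <- sprintf("g%d", 1:6)
  one <- clusterGenes(mm)
  expect_identical(length(clusterSizes(one)), 1L)
})

test_that("clustering is invariant to gene order and affine rescaling", {
  set.seed(61)
  m <- randomSliceMatrix(20, 10)
  cl <- clusterGenes(m)
  perm <- sample(rownames(m))
  clPerm <- clusterGenes(m[perm, ])
  expect_identical(clusterSizes(clPerm), clusterSizes(cl))
  # same partition: identical co-membership, aligned by gene id
  co <- function(l) outer(l[rownames(m)], l[rownames(m)], `==`)
  expect_identical(co(clusterLabels(clPerm)), co(clusterLabels(cl)))
  scaled <- m * 7 + 2
  expect_identical(clusterLabels(clusterGenes(scaled)), clusterLabels(cl))
  const <- m; const["g01", ] <- 5
  expect_error(clusterGenes(const), "z-scored")
})

test_that("case/control dissimilarity hits its boundary values", {
  s <- sprintf("s%d", 1:5)
  a <- 1:5; b <- 2 * (1:5) + 1          # r = 1
  Xcase <- rbind(g1 = a, g2 = b); colnames(Xcase) <- s
  set.seed(63)
  u <- rnorm(5); w <- residuals(lm(rnorm(5) ~ u))  # r = 0 by construction
  Xctrl <- rbind(g1 = u, g2 = w); colnames(Xctrl) <- s
  d <- dnbDissimilarity(Xcase, Xctrl)
  expect_equal(d["g1", "g2"], 0, tolerance = 1e-10)   # |r|=1, |r'|=0
  dRev <- dnbDissimilarity(Xctrl, Xcase)
  expect_equal(dRev["g1", "g2"], 2, tolerance = 1e-10) # |r|=0, |r'|=1
  dSame <- dnbDissimilarity(Xcase, Xcase)
  expect_equal(dSame["g1", "g2"], 1)                   # cancellation
  expect_equal(unname(diag(d)), c(1, 1))               # d_ii = 1 by formula
  expect_true(all(d >= -1e-12 & d <= 2 + 1e-12))
})

test_that("fluctuation map has the contract shape and planted maxima", {
  sim <- simulateExpression(dnbSimConfig(nGenes = 100, nDnb = 10, seed = 67))
  genes <- c(sim$truth@dnbGenes, setdiff(rownames(sim$dataset),
                                         sim$truth@dnbGenes)[1:5])
  fm <- fluctuationMap(sim$dataset, genes)
  expect_equal(dim(fm), c(length(genes), 10))  # |genes| x (groups x weeks)
  peakCol <- "case:wk5"
  hits <- apply(fm[sim$truth@dnbGenes, ], 1,
                function(r) names(which.max(r)) == peakCol)
  expect_gte(mean(hits), 0.8)
  # a constant gene gives an all-zero row
  m <- exprs(sim$dataset); m["g001", ] <- 3
  x2 <- DNBExperiment(m, group = sampleGroups(sim$dataset),
                      week = sampleWeeks(sim$dataset))
  expect_true(all(fluctuationMap(x2, "g001") == 0))
})
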