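test_that("v-statistics and scores match the naive formula oracle", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(6:20, 1); k <- sample(4:6, 1)
    X <- randomSliceMatrix(n, k); Y <- randomSliceMatrix(n, k)
    expect_equal(unname(varianceRatio(X, Y)), naiveV1(X, Y),
                 tolerance = 1e-10)
    S1 <- sort(sample(rownames(X), max(2, floor(n / 2))))
    expect_equal(unname(correlationGainWithin(X, Y, S1)),
                 unname(naiveV2(X, Y, S1)), tolerance = 1e-10)
    expect_equal(unname(nonspecificGainOutside(X, Y, S1)),
                 unname(naiveV3(X, Y, S1)), tolerance = 1e-10)
    genes <- sample(rownames(X), 4)
    expect_equal(scoreIs(X, genes), naiveIs(X, genes), tolerance = 1e-10)
    c0 <- correctionTerm(k)
    expect_equal(scoreIr(X, genes), naiveIr(X, genes, c0),
                 tolerance = 1e-10)
  }
})

test_that("correction term has its closed-form values and limits", {
  expect_equal(correctionTerm(4), 0.5)
  expect_equal(correctionTerm(5), 4 / (3 * pi))
  expect_equal(round(correctionTerm(5), 2), 0.42)
  expect_equal(correctionTerm(3), 2 / pi)
  cs <- correctionTerm(3:60)
  expect_true(all(diff(cs) < 0))       # strictly decreasing in M
  expect_lt(correctionTerm(10000), 0.01)
  expect_error(correctionTerm(2))
})

test_that("top-fraction selection follows the floor rule and tie-break", {
  s <- setNames(10:1, sprintf("g%02d", 1:10))
  expect_identical(topFraction(s, 10), "g01")      # 10 genes, 10% -> 1
  expect_identical(topFraction(s, 100), names(s))  # everything
  s25 <- setNames(rep(c(2, 1), c(3, 22)), sprintf("g%02d", 1:25))
  expect_identical(topFraction(s25, 10), c("g01", "g02"))  # floor(2.5) = 2
  # ties at the cutoff break by ascending gene id
  tied <- setNames(c(1, 1, 1, 1), c("d", "b", "c", "a"))
  expect_identical(topFraction(tied, 50), c("a", "b"))
  # NA scores are excluded from the ranked universe
  withNA <- setNames(c(5, NA, 3, NA, 1), letters[1:5])
  expect_identical(topFraction(withNA, 34), "a")   # floor(0.34*3) = 1
})

test_that("selection satisfies the set algebra and reports exclusions", {
  set.seed(5)
  X <- randomSliceMatrix(40, 5); Y <- randomSliceMatrix(40, 5)
  X["g03", ] <- 2   # constant gene: undefined SD ratio
  sel <- selectDNB(X, Y = Y, thetas = c(20, 50, 60))
  expect_true(all(sel@S1 %in% sel@S0))
  expect_true(all(sel@S2 %in% sel@S1))
  expect_true(all(sel@S3 %in% sel@S1))
  expect_setequal(sel@sStar, setdiff(sel@S2, sel@S3))
  expect_identical(sel@excluded, "g03")
  expect_false("g03" %in% sel@S0)
  expect_length(sel@S1, floor(0.2 * 39))
})

test_that("identical slices degenerate deterministically", {
  set.seed(6)
  X <- randomSliceMatrix(20, 5)
  sel1 <- selectDNB(X, Y = X)
  sel2 <- selectDNB(X, Y = X)
  expect_true(all(abs(sel1@v1 - 1) < 1e-12))
  expect_true(all(abs(sel1@v2) < 1e-10))
  expect_true(all(abs(sel1@v3) < 1e-10))
  expect_identical(dnbGenes(sel1), dnbGenes(sel2))
})

test_that("statistics are scale-free and permutation-well-behaved", {
  set.seed(7)
  X <- randomSliceMatrix(20, 5); Y <- randomSliceMatrix(20, 5)
  sel <- selectDNB(X, Y = Y)
  # multiplying one gene by a positive constant in both slices changes nothing
  Xs <- X; Ys <- Y
  Xs["g05", ] <- 13 * Xs["g05", ]; Ys["g05", ] <- 13 * Ys["g05", ]
  selScaled <- selectDNB(Xs, Y = Ys)
  expect_equal(selScaled@v1, sel@v1, tolerance = 1e-10)
  expect_identical(dnbGenes(selScaled), dnbGenes(sel))
  # permuting samples within a slice changes nothing
  selPerm <- selectDNB(X[, c(3, 1, 5, 2, 4)], Y = Y)
  expect_identical(dnbGenes(selPerm), dnbGenes(sel))
  # permuting gene rows permutes the statistics identically
  perm <- sample(rownames(X))
  selG <- selectDNB(X[perm, ], Y = Y[perm, ])
  expect_equal(selG@v1[names(sel@v1)], sel@v1)
  expect_setequal(dnbGenes(selG), dnbGenes(sel))
})

test_that("trivial score values are exact", {
  u <- (1:5) / sd(1:5)                  # unit-SD vector
  Z <- rbind(a = u, b = 3 * u)
  colnames(Z) <- sprintf("s%d", 1:5)
  expect_equal(scoreIs(Z, c("a", "b")), 2)   # SDs 1 and 3 -> mean 2
  expect_equal(scoreIs(matrix(5, 2, 4,
                              dimnames = list(c("a", "b"), NULL)),
                       c("a", "b")), 0)  # constants
  # two perfectly correlated genes, 5 samples: I_r = 1 - c(5)
  P <- rbind(a = 1:5, b = 2 * (1:5) + 3)
  colnames(P) <- sprintf("s%d", 1:5)
  expect_equal(scoreIr(P, c("a", "b")), 1 - 4 / (3 * pi))
  # with 4 samples the correction 0.50 is used
  expect_equal(scoreIr(P[, 1:4], c("a", "b")), 1 - 0.5)
})

test_that("score series peaks at the planted week on planted data", {
  sim <- simulateExpression(dnbSimConfig(seed = 301))
  ss <- scoreTable(scoreSeries(sim$dataset, sim$truth@dnbGenes))
  case <- ss[ss$group == "case", ]
  expect_identical(case$week[which.max(case$Is)], "wk5")
  expect_identical(case$week[which.max(case$Ir)], "wk5")
  # control series shows no comparable peak contrast
  ctrl <- ss[ss$group == "control", ]
  casePeakContrast <- max(case$Is) - median(case$Is)
  expect_lt(max(ctrl$Is) - median(ctrl$Is), casePeakContrast)
})

test_that("leave-one-out on duplicated samples returns the reference", {
  set.seed(9)
  base <- randomSliceMatrix(30, 4)
  Xd <- cbind(base, base); colnames(Xd) <- sprintf("x%d", 1:8)
  Yd <- cbind(base + rnorm(120), base + rnorm(120))
  Yd <- Yd[, c(1:4, 1:4)] ; colnames(Yd) <- sprintf("y%d", 1:8)
  x <- DNBExperiment(cbind(Xd, Yd),
                     group = rep(c("case", "control"), each = 8),
                     week = rep("wk1", 16))
  ref <- dnbGenes(selectDNB(x, caseWeek = "wk1"))
  loo <- leaveOneOut(x, caseWeek = "wk1", reference = ref)
  expect_true(all(loo$overlaps == length(ref)))
  expect_equal(loo$sem, 0)
  expect_equal(loo$mean, length(ref))
})

test_that("leave-one-out is stable for a strongly planted module", {
  cfg <- dnbSimConfig(nGenes = 200, nDnb = 20, replicates = 8L,
                      sdRatio = 6, targetAbsCorr = 0.9, seed = 31)
  sim <- simulateExpression(cfg)
  # theta3 = 20 keeps the exclusion step mild so S* is sizable
  loo <- leaveOneOut(sim$dataset, caseWeek = "wk5",
                     thetas = c(10, 50, 20))
  expect_gt(length(loo$reference), 0)
  expect_gte(loo$mean / length(loo$reference), 0.8)
})

test_that("control swap against the original control is the identity", {
  sim <- simulateExpression(dnbSimConfig(nGenes = 150, nDnb = 15, seed = 37))
  ref <- dnbGenes(selectDNB(sim$dataset, caseWeek = "wk5"))
  cs <- controlSwap(sim$dataset, caseWeek = "wk5",
                    altGroup = "control", altWeek = "wk5", reference = ref)
  expect_identical(dnbGenes(cs$selection), ref)
  expect_equal(cs$overlap, length(ref))
})

test_that("swapping to an early case-week control still finds the module", {
  # selection against the case strain at its first week, where the planted
  # module is silent, recovers much of the peak-week signal
  cfg <- dnbSimConfig(nGenes = 200, nDnb = 20, replicates = 10L,
                      sdRatio = 5, targetAbsCorr = 0.8, seed = 41)
  sim <- simulateExpression(cfg)
  cs <- controlSwap(sim$dataset, caseWeek = "wk5",
                    altGroup = "case", altWeek = "wk3",
                    thetas = c(20, 75, 20),
                    reference = sim$truth@dnbGenes)
  got <- dnbGenes(cs$selection)
  expect_gte(length(intersect(got, sim$truth@dnbGenes)) /
               length(sim$truth@dnbGenes), 0.5)
  expect_lt(cs$p, 1e-6)
})

test_that("relative recovery rate scales inversely with variance", {
  set.seed(10)
  Z <- randomSliceMatrix(10, 6)
  r1 <- relativeRecoveryRate(Z, rownames(Z))
  expect_equal(relativeRecoveryRate(sqrt(2) * Z, rownames(Z)), r1 / 2,
               tolerance = 1e-10)
  # identity covariance -> rate exactly 1: build a slice whose sample
  # covariance is the identity via an orthonormal basis of centered space
  k <- 6
  H <- qr.Q(qr(cbind(1, matrix(rnorm(k * (k - 1)), k))))[, 2:4]
  Zi <- t(H) * sqrt(k - 1)
  rownames(Zi) <- c("a", "b", "c"); colnames(Zi) <- sprintf("s%d", 1:k)
  expect_equal(max(abs(cov(t(Zi)) - diag(3))), 0, tolerance = 1e-10)
  expect_equal(relativeRecoveryRate(Zi, c("a", "b", "c")), 1,
               tolerance = 1e-10)
})

test_that("recovery rate is smallest at the planted peak week", {
  sim <- simulateExpression(dnbSimConfig(seed = 43))
  rr <- recoveryRateSeries(sim$dataset, sim$truth@dnbGenes)
  case <- rr[rr$group == "case", ]
  expect_identical(case$week[which.min(case$rate)], "wk5")
})

test_that("parameter sweep ranks sharp-peak triples first", {
  sim <- simulateExpression(dnbSimConfig(seed = 47))
  sw <- sweepParameters(sim$dataset, caseWeek = "wk5",
                        theta1Grid = c(10, 20), theta2Grid = c(50, 75),
                        theta3Grid = c(60, 80))
  expect_equal(nrow(sw), 8)
  expect_identical(sw$rank, 1:8)
  expect_true(all(diff(sw$sharpness[!is.na(sw$sharpness)]) <= 1e-12))
  # a single-triple grid returns that triple at rank 1
  one <- sweepParameters(sim$dataset, caseWeek = "wk5",
                         theta1Grid = 10, theta2Grid = 50, theta3Grid = 80)
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one[1, c("theta1", "theta2", "theta3")]),
               c(theta1 = 10, theta2 = 50, theta3 = 80))
})
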