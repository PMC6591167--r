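makeProbeSet <- function(values, symbols) {
  rownames(values) <- sprintf("p%d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  ProbeExperiment(values,
                  annotation = data.frame(probe_id = rownames(values),
                                          gene_symbol = symbols),
                  group = rep(c("case", "control"),
                              length.out = ncol(values)),
                  week = rep("wk1", ncol(values)))
}

test_that("probe collapsing averages raw intensities per symbol", {
  v <- matrix(c(2, 4, 6, 10), 4, 1)
  pe <- makeProbeSet(v, c("A", "A", "A", "B"))
  out <- collapseProbes(pe)
  expect_equal(assayInt(out)["A", 1], 4)   # mean(2, 4, 6)
  expect_equal(assayInt(out)["B", 1], 10)  # single probe unchanged
})

test_that("unannotated probes are removed; all-unannotated input errors", {
  v <- matrix(1:6, 3, 2)
  pe <- makeProbeSet(v, c("A", "", "B"))
  out <- collapseProbes(pe)
  expect_setequal(rownames(out), c("A", "B"))
  peBad <- makeProbeSet(v, c("", "", ""))
  expect_error(collapseProbes(peBad), "unannotated")
})

test_that("collapsed genes are sorted lexicographically", {
  v <- matrix(1:4, 4, 1)
  pe <- makeProbeSet(v, c("zeta", "alpha", "mid", "beta"))
  expect_identical(rownames(collapseProbes(pe)),
                   sort(c("zeta", "alpha", "mid", "beta")))
})

test_that("2% trimmed mean drops floor(0.02 n) per side", {
  expect_equal(trimmedMean(1:100), mean(3:98))    # drops {1,2} and {99,100}
  expect_equal(mean(3:98), 50.5)
  expect_equal(trimmedMean(1:10), mean(1:10))     # floor(0.2) = 0: plain mean
  expect_equal(trimmedMean(rev(1:100)), 50.5)     # order-free
})

test_that("trimmed-mean normalization rescales every sample to unit mean", {
  set.seed(1)
  m <- matrix(rexp(600, 0.1), 100, 6,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:6)))
  norm <- trimmedMeanNormalize(m)
  expect_equal(apply(norm, 2, trimmedMean), setNames(rep(1, 6), colnames(m)),
               tolerance = 1e-12)
  # constant column: every normalized value is 1
  cm <- matrix(7, 50, 1)
  expect_true(all(trimmedMeanNormalize(cm) == 1))
  expect_error(trimmedMeanNormalize(matrix(0, 10, 1)), "non-positive")
})

test_that("log2 transform checks its domain and names the offender", {
  m <- matrix(c(1, 8), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(log2Transform(m), log2(m))
  expect_equal(log2Transform(m)["a", 1], 0)
  expect_equal(log2Transform(m)["b", 1], 3)
  m["b", 1] <- 0
  expect_error(log2Transform(m), "'b'")
})

test_that("preprocessing commutes with sample permutation", {
  cfg <- dnbSimConfig(nGenes = 40, nDnb = 4, nDegClusters = 1L,
                      degClusterSize = 5L, seed = 8)
  sim <- simulateProbes(cfg)
  x <- preprocessProbes(sim$probes)
  perm <- rev(seq_len(ncol(sim$probes)))
  xPerm <- preprocessProbes(sim$probes[, perm])
  expect_equal(exprs(xPerm), exprs(x)[, perm])
})

test_that("expression TSV + metadata CSV round-trip", {
  sim <- simulateExpression(dnbSimConfig(nGenes = 30, nDnb = 3,
                                         nDegClusters = 1L,
                                         degClusterSize = 5L, seed = 2))
  vp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".csv")
  writeExpressionData(sim$dataset, vp, mp)
  back <- readExpressionData(vp, mp, caseLabel = "case",
                             controlLabel = "control")
  expect_equal(exprs(back), exprs(sim$dataset), tolerance = 1e-12)
  expect_identical(sampleGroups(back), sampleGroups(sim$dataset))
  expect_identical(sampleWeeks(back), sampleWeeks(sim$dataset))
})

test_that("series-matrix reader parses the table and header fields", {
  path <- tempfile()
  writeLines(c(
    "!Series_title\t\"toy\"",
    "!Sample_geo_accession\t\"GSM1\"\t\"GSM2\"",
    "!series_matrix_table_begin",
    "ID_REF\tGSM1\tGSM2",
    "p1\t1.5\t2.5",
    "p2\t3\t4",
    "!series_matrix_table_end"), path)
  out <- readSeriesMatrix(path)
  expect_equal(dim(out$values), c(2, 2))
  expect_equal(out$values["p1", "GSM2"], 2.5)
  expect_true("Sample_geo_accession" %in% out$sampleInfo$field)
  noTable <- tempfile()
  writeLines("!Series_title\t\"toy\"", noTable)
  expect_error(readSeriesMatrix(noTable), "table markers")
})
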