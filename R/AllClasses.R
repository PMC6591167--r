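#' @import methods
#' @importFrom stats cor sd quantile setNames rnorm rpois p.adjust pt phyper
#'   prcomp hclust cutree as.dist cov dhyper
#' @importFrom utils read.delim write.table head
#' @importFrom graphics par matplot axis legend
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' DNBExperiment: normalized expression with group/week sample annotation
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' log2-normalized genes-by-samples expression matrix (assay `"exprs"`)
#' together with per-sample condition labels. Each sample belongs to exactly
#' one (group, week) condition; the pair of labels designating the case and
#' control groups is kept in `metadata()` so that downstream operations
#' (differential expression, DNB selection) know which contrast to form.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]; colData must
#'   contain `group` and `week` columns.
#' @export
setClass("DNBExperiment", contains = "SummarizedExperiment")

setValidity("DNBExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- colData(object)
  if (!all(c("group", "week") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'group' and 'week'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if ("exprs" %in% SummarizedExperiment::assayNames(object) &&
      any(!is.finite(assay(object, "exprs"))))
    msg <- c(msg, "expression values must be finite (no NA/Inf)")
  md <- metadata(object)
  if (is.null(md$caseLabel) || is.null(md$controlLabel))
    msg <- c(msg, "metadata caseLabel/controlLabel are required")
  else if (all(c("group", "week") %in% colnames(cd))) {
    if (!md$caseLabel %in% cd$group)
      msg <- c(msg, "caseLabel not found among sample groups")
    if (!md$controlLabel %in% cd$group)
      msg <- c(msg, "controlLabel not found among sample groups")
  }
  if (length(msg)) msg else TRUE
})

#' ProbeExperiment: raw probe-level intensities with gene annotation
#'
#' Probe-by-sample raw (non-negative) intensity data as produced by array
#' scanners, prior to probe collapsing and normalization. `rowData` carries
#' the probe-to-gene-symbol annotation; an empty or `NA` symbol marks an
#' unannotated probe, which preprocessing removes.
#'
#' @export
setClass("ProbeExperiment", contains = "SummarizedExperiment")

setValidity("ProbeExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    v <- assay(object, "intensity")
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "intensities must be finite and non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be present and unique")
  if (!"gene_symbol" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'gene_symbol'")
  if (!all(c("group", "week") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'group' and 'week'")
  if (length(msg)) msg else TRUE
})

#' DNBSimConfig: parameters of the synthetic-data generator
#'
#' Captures the full design of a simulated study: universe size, the planted
#' DNB module and its activation strength, planted differential-expression
#' clusters, noise scales and probe-level structure. See [dnbSimConfig()] for
#' defaults and the meaning of each parameter.
#'
#' @export
setClass("DNBSimConfig", representation(
  nGenes = "integer", nDnb = "integer",
  caseLabel = "character", controlLabel = "character",
  weeks = "character", replicates = "integer", peakWeek = "character",
  sdRatio = "numeric", targetAbsCorr = "numeric",
  nDegClusters = "integer", degClusterSize = "integer",
  degEffect = "numeric", degOnsetWeek = "character",
  noiseSd = "numeric", baselineMean = "numeric", baselineSd = "numeric",
  probeRedundancy = "numeric", unannotatedFrac = "numeric",
  probeOffsetSd = "numeric", probeNoiseSd = "numeric",
  sampleScaleSd = "numeric", seed = "integer"))

setValidity("DNBSimConfig", function(object) {
  msg <- character()
  if (object@nDnb >= object@nGenes) msg <- c(msg, "nDnb must be < nGenes")
  if (object@sdRatio < 1) msg <- c(msg, "sdRatio must be >= 1")
  if (object@targetAbsCorr < 0 || object@targetAbsCorr >= 1)
    msg <- c(msg, "targetAbsCorr must be in [0, 1)")
  if (any(object@replicates < 3))
    msg <- c(msg, "all replicate counts must be >= 3")
  if (length(object@replicates) != length(object@weeks) * 2L)
    msg <- c(msg, "replicates must have one entry per (group, week)")
  if (!object@peakWeek %in% object@weeks)
    msg <- c(msg, "peakWeek must be one of weeks")
  if (!object@degOnsetWeek %in% object@weeks)
    msg <- c(msg, "degOnsetWeek must be one of weeks")
  if (object@probeRedundancy < 1)
    msg <- c(msg, "probeRedundancy must be >= 1")
  if (object@unannotatedFrac < 0 || object@unannotatedFrac >= 1)
    msg <- c(msg, "unannotatedFrac must be in [0, 1)")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  # single-factor feasibility: loading^2 = rho * (sdRatio*noiseSd)^2 must not
  # exceed the total variance (sdRatio*noiseSd)^2
  if (object@targetAbsCorr * object@sdRatio^2 > object@sdRatio^2 + 1e-12)
    msg <- c(msg, "targetAbsCorr and sdRatio are jointly infeasible")
  if (length(msg)) msg else TRUE
})

#' DNBTruth: ground truth of a simulated dataset
#'
#' Records which genes were planted as the DNB module, the per-cluster
#' differentially expressed genes, the activation week and the latent-factor
#' loadings, for parameter-recovery testing of the selection pipeline.
#'
#' @export
setClass("DNBTruth", representation(
  dnbGenes = "character", degGenes = "list", peakWeek = "character",
  factorLoadings = "numeric"))

setValidity("DNBTruth", function(object) {
  msg <- character()
  if (length(object@factorLoadings) &&
      length(object@factorLoadings) != length(object@dnbGenes))
    msg <- c(msg, "one factor loading per planted DNB gene is required")
  if (any(unlist(object@degGenes) %in% object@dnbGenes))
    msg <- c(msg, "planted DEG clusters must be disjoint from the DNB module")
  if (length(msg)) msg else TRUE
})

#' DNBSelection: result of the three-step DNB gene selection
#'
#' Holds the nested index sets of the selection procedure: `S0` (all ranked
#' genes), `S1` (largest standard-deviation ratios), `S2` (largest
#' within-`S1` correlation gain), `S3` (largest non-specific correlation
#' gain, excluded), and the selected set `S* = S2 \ S3`; plus the per-gene
#' statistics v1 (over `S0`), v2 and v3 (over `S1`) and the percentage
#' thresholds used.
#'
#' @export
setClass("DNBSelection", representation(
  S0 = "character", S1 = "character", S2 = "character", S3 = "character",
  sStar = "character", v1 = "numeric", v2 = "numeric", v3 = "numeric",
  thetas = "numeric", excluded = "character"))

setValidity("DNBSelection", function(object) {
  msg <- character()
  if (!all(object@S1 %in% object@S0)) msg <- c(msg, "S1 must be within S0")
  if (!all(object@S2 %in% object@S1)) msg <- c(msg, "S2 must be within S1")
  if (!all(object@S3 %in% object@S1)) msg <- c(msg, "S3 must be within S1")
  if (!setequal(object@sStar, setdiff(object@S2, object@S3)))
    msg <- c(msg, "sStar must equal S2 \\ S3")
  if (length(object@thetas) != 3L || any(object@thetas <= 0) ||
      any(object@thetas > 100))
    msg <- c(msg, "thetas must be three percentages in (0, 100]")
  if (length(msg)) msg else TRUE
})

#' DNBScoreSeries: I_s and I_r per experimental condition
#'
#' One row per (group, week) condition slice: the sample count M, the average
#' standard deviation I_s of the candidate genes, the average absolute
#' pairwise correlation minus the sample-size correction c, and c itself.
#'
#' @export
setClass("DNBScoreSeries", representation(table = "data.frame"))

setValidity("DNBScoreSeries", function(object) {
  tab <- object@table
  need <- c("group", "week", "M", "Is", "Ir", "c")
  if (!all(need %in% colnames(tab)))
    return(paste("score table needs columns:", paste(need, collapse = ", ")))
  if (any(tab$Is < 0)) return("I_s must be non-negative")
  if (any(tab$c <= 0 | tab$c >= 1)) return("correction c must lie in (0, 1)")
  if (any(tab$Ir < -tab$c - 1e-9 | tab$Ir > 1 - tab$c + 1e-9))
    return("I_r must lie in [-c, 1-c]")
  TRUE
})

#' DEGResult: differentially expressed genes per time point
#'
#' Per-week tables of log2 mean differences, Welch statistics and
#' Benjamini-Hochberg decisions; the per-week DEG sets (fold-change
#' candidates intersected with test rejections), their union, and the
#' gene-by-week 0/1 incidence pattern.
#'
#' @export
setClass("DEGResult", representation(
  perWeek = "list", degSets = "list", union = "character",
  incidence = "matrix", q = "numeric", lfcThreshold = "numeric"))

setValidity("DEGResult", function(object) {
  msg <- character()
  if (!identical(names(object@perWeek), names(object@degSets)))
    msg <- c(msg, "perWeek and degSets must cover the same weeks")
  if (!all(unlist(object@degSets) %in% object@union))
    msg <- c(msg, "every per-week DEG set must be within the union")
  if (length(object@union) &&
      (!is.matrix(object@incidence) ||
       nrow(object@incidence) != length(object@union)))
    msg <- c(msg, "incidence must have one row per union gene")
  if (length(object@union) && any(rowSums(object@incidence) < 1))
    msg <- c(msg, "union genes must appear in at least one week")
  if (length(msg)) msg else TRUE
})

#' PCAResult: sample-space principal components with parallel analysis
#'
#' Sample scores, covariance eigenvalues and explained-variance ratios from
#' mean-centered PCA, and (after [parallelAnalysis()]) the number of
#' components whose eigenvalues exceed the shuffled-data percentile
#' thresholds.
#'
#' @export
setClass("PCAResult", representation(
  scores = "matrix", eigenvalues = "numeric", varExplained = "numeric",
  nMeaningful = "integer", nullQuantiles = "numeric"))

setValidity("PCAResult", function(object) {
  ev <- object@eigenvalues
  if (any(ev < -1e-8)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-8))
    return("eigenvalues must be non-increasing")
  if (sum(object@varExplained) > 1 + 1e-8)
    return("explained-variance ratios must sum to at most 1")
  TRUE
})

#' ClusterResult: correlation-based hierarchical gene clusters
#'
#' Per-gene cluster labels (1 = largest cluster), descending cluster sizes,
#' the average-linkage tree and the z-scored matrix that was clustered.
#'
#' @export
setClass("ClusterResult", representation(
  labels = "integer", sizes = "integer", tree = "ANY", zMatrix = "matrix",
  cutoff = "numeric"))

setValidity("ClusterResult", function(object) {
  if (sum(object@sizes) != length(object@labels))
    return("cluster sizes must sum to the number of genes")
  if (is.unsorted(rev(object@sizes)))
    return("cluster sizes must be reported in descending order")
  TRUE
})
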