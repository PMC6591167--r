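#' Configure the synthetic study generator
#'
#' Builds a validated configuration for [simulateExpression()] /
#' [simulateProbes()]. The defaults emulate the shape of a two-strain,
#' five-week time-course adipose-tissue study: two groups, weekly sampling,
#' five biological replicates per condition, and a planted DNB module that
#' activates at one "pre-disease" week in the case group only.
#'
#' At the peak week the planted genes follow a single shared latent factor:
#' `x = baseline + b*f + e`, with the loading `b` and residual noise solved
#' so that the population standard deviation equals `sdRatio` times the
#' baseline noise and the population pairwise correlation equals
#' `targetAbsCorr` (equicorrelated design). Everywhere else all genes carry
#' independent noise. Planted differential-expression clusters receive a
#' `degEffect` log2 mean shift in the case group from `degOnsetWeek` onward,
#' with alternating sign across clusters.
#'
#' @param nGenes number of genes in the universe.
#' @param nDnb size of the planted DNB module.
#' @param caseLabel,controlLabel group labels.
#' @param weeks ordered time-point labels.
#' @param replicates per-condition sample count: a single integer (all
#'   conditions) or a vector named `"group:week"`; every count must be >= 3.
#' @param peakWeek week at which the planted module activates (case group).
#' @param sdRatio variance-inflation factor of planted genes at the peak
#'   (population SD relative to baseline; > 1 for an active module).
#' @param targetAbsCorr desired population mean absolute pairwise correlation
#'   within the planted module at the peak, in \[0, 1).
#' @param nDegClusters,degClusterSize,degEffect,degOnsetWeek planted
#'   differential-expression clusters: how many, their size, the log2 mean
#'   shift in the case group, and the first affected week.
#' @param noiseSd baseline per-gene noise SD on the log2 scale.
#' @param baselineMean,baselineSd distribution of per-gene baseline log2
#'   expression (log-normal on the raw intensity scale).
#' @param probeRedundancy mean number of probes per gene (>= 1).
#' @param unannotatedFrac fraction of probes carrying no gene symbol.
#' @param probeOffsetSd,probeNoiseSd probe-specific log2 offset SD and
#'   per-measurement probe noise SD (raw-scale generator only).
#' @param sampleScaleSd log2 SD of per-sample array scale factors applied on
#'   the raw intensity scale (removed again by trimmed-mean normalization).
#' @param seed integer seed; generation is fully deterministic given it.
#'
#' @return A [DNBSimConfig-class] object.
#' @export
dnbSimConfig <- function(nGenes = 500L, nDnb = 50L,
                         caseLabel = "case", controlLabel = "control",
                         weeks = paste0("wk", 3:7), replicates = 5L,
                         peakWeek = "wk5", sdRatio = 3,
                         targetAbsCorr = 0.6,
                         nDegClusters = 3L, degClusterSize = 20L,
                         degEffect = 2, degOnsetWeek = weeks[1L],
                         noiseSd = 0.3, baselineMean = 8, baselineSd = 1.5,
                         probeRedundancy = 2, unannotatedFrac = 0.1,
                         probeOffsetSd = 0.3, probeNoiseSd = 0.1,
                         sampleScaleSd = 0.2, seed = 1L) {
  conds <- conditionNames(caseLabel, controlLabel, weeks)
  if (length(replicates) == 1L) {
    replicates <- setNames(rep(as.integer(replicates), length(conds)), conds)
  } else {
    if (is.null(names(replicates)) || !all(conds %in% names(replicates)))
      stop("named replicates must cover every 'group:week' condition")
    replicates <- setNames(as.integer(replicates[conds]), conds)
  }
  new("DNBSimConfig", nGenes = as.integer(nGenes), nDnb = as.integer(nDnb),
      caseLabel = caseLabel, controlLabel = controlLabel,
      weeks = as.character(weeks), replicates = replicates,
      peakWeek = peakWeek, sdRatio = sdRatio, targetAbsCorr = targetAbsCorr,
      nDegClusters = as.integer(nDegClusters),
      degClusterSize = as.integer(degClusterSize),
      degEffect = degEffect, degOnsetWeek = degOnsetWeek,
      noiseSd = noiseSd, baselineMean = baselineMean, baselineSd = baselineSd,
      probeRedundancy = probeRedundancy, unannotatedFrac = unannotatedFrac,
      probeOffsetSd = probeOffsetSd, probeNoiseSd = probeNoiseSd,
      sampleScaleSd = sampleScaleSd, seed = as.integer(seed))
}

conditionNames <- function(caseLabel, controlLabel, weeks) {
  as.vector(outer(c(caseLabel, controlLabel), weeks, paste, sep = ":"))
}

#' Simulate a gene-level expression study with planted structure
#'
#' Generates a log2-scale genes-by-samples matrix under the design in
#' `config` and returns it with the planted ground truth. Values are drawn
#' directly on the normalized log2 scale, so the configured moments (SD
#' inflation, mean |correlation|) hold exactly in the population; use
#' [simulateProbes()] for raw-intensity data that must pass through
#' preprocessing first.
#'
#' @param config a [DNBSimConfig-class] from [dnbSimConfig()].
#' @return A list with elements `dataset` ([DNBExperiment-class]) and
#'   `truth` ([DNBTruth-class]).
#' @examples
#' sim <- simulateExpression(dnbSimConfig(nGenes = 100, nDnb = 10, seed = 7))
#' sim$dataset
#' length(sim$truth@dnbGenes)
#' @export
simulateExpression <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nGenes
  geneIds <- sprintf("g%0*d", nchar(n), seq_len(n))

  dnbIdx <- sort(sample.int(n, config@nDnb))
  pool <- setdiff(seq_len(n), dnbIdx)
  nDegTotal <- config@nDegClusters * config@degClusterSize
  if (nDegTotal > length(pool))
    stop("planted DEG clusters do not fit outside the DNB module")
  degIdx <- sort(sample(pool, nDegTotal))
  degClusters <- split(degIdx, rep(seq_len(config@nDegClusters),
                                   each = config@degClusterSize))

  mu <- rnorm(n, config@baselineMean, config@baselineSd)
  s <- config@noiseSd
  rho <- config@targetAbsCorr
  peakSd <- config@sdRatio * s
  b <- sqrt(rho) * peakSd            # latent-factor loading
  residSd <- peakSd * sqrt(1 - rho)  # peak residual noise

  weeks <- config@weeks
  onsetPos <- match(config@degOnsetWeek, weeks)
  cols <- list(); grp <- character(); wk <- character(); ids <- character()
  for (w in weeks) {
    for (g in c(config@caseLabel, config@controlLabel)) {
      k <- config@replicates[[paste(g, w, sep = ":")]]
      block <- mu + matrix(rnorm(n * k, 0, s), n, k)
      isCase <- g == config@caseLabel
      if (isCase && w == config@peakWeek && config@nDnb > 0) {
        f <- rnorm(k)
        block[dnbIdx, ] <- mu[dnbIdx] +
          outer(rep(b, config@nDnb), f) +
          matrix(rnorm(config@nDnb * k, 0, residSd), config@nDnb, k)
      }
      if (isCase && match(w, weeks) >= onsetPos) {
        for (ci in seq_along(degClusters)) {
          shift <- config@degEffect * ifelse(ci %% 2 == 1, 1, -1)
          block[degClusters[[ci]], ] <- block[degClusters[[ci]], ] + shift
        }
      }
      cols[[length(cols) + 1L]] <- block
      grp <- c(grp, rep(g, k)); wk <- c(wk, rep(w, k))
      ids <- c(ids, paste(g, w, seq_len(k), sep = "_"))
    }
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(geneIds, ids)
  dataset <- DNBExperiment(values, group = grp, week = wk,
                           caseLabel = config@caseLabel,
                           controlLabel = config@controlLabel,
                           weekLevels = weeks)
  truth <- new("DNBTruth", dnbGenes = geneIds[dnbIdx],
               degGenes = lapply(degClusters, function(i) geneIds[i]),
               peakWeek = config@peakWeek,
               factorLoadings = setNames(rep(b, config@nDnb),
                                         geneIds[dnbIdx]))
  list(dataset = dataset, truth = truth)
}

#' Simulate raw probe-level intensities for the preprocessing pipeline
#'
#' Expands the gene-level simulation of [simulateExpression()] to the raw
#' intensity scale: each gene maps to one or more probes (probe-specific
#' log2 offsets plus measurement noise), per-sample array scale factors are
#' applied multiplicatively, and a configurable fraction of unannotated
#' probes is mixed in. Collapsing + trimmed-mean normalization + log2 of the
#' output recovers the gene-level dataset up to probe noise.
#'
#' @param config a [DNBSimConfig-class].
#' @return list with `probes` ([ProbeExperiment-class]), `annotation`
#'   (data.frame probe_id/gene_symbol), `genes` (the underlying gene-level
#'   [DNBExperiment-class]) and `truth` ([DNBTruth-class]).
#' @export
simulateProbes <- function(config) {
  sim <- simulateExpression(config)   # seeds the RNG; keep drawing from it
  g <- exprs(sim$dataset)
  n <- nrow(g); k <- ncol(g)

  nProbes <- 1L + rpois(n, max(config@probeRedundancy - 1, 0))
  gi <- rep(seq_len(n), nProbes)
  offsets <- rnorm(length(gi), 0, config@probeOffsetSd)
  log2val <- g[gi, , drop = FALSE] + offsets +
    matrix(rnorm(length(gi) * k, 0, config@probeNoiseSd), length(gi), k)
  symbols <- rownames(g)[gi]

  nAnn <- length(gi)
  nUn <- round(config@unannotatedFrac * nAnn / (1 - config@unannotatedFrac))
  if (nUn > 0) {
    unMu <- rnorm(nUn, config@baselineMean, config@baselineSd)
    log2val <- rbind(log2val,
                     unMu + matrix(rnorm(nUn * k, 0, config@noiseSd), nUn, k))
    symbols <- c(symbols, rep("", nUn))
  }
  probeIds <- sprintf("p%0*d", nchar(nrow(log2val)), seq_len(nrow(log2val)))
  scale <- 2^rnorm(k, 0, config@sampleScaleSd)   # array effects, raw scale
  raw <- sweep(2^log2val, 2, scale, `*`)
  dimnames(raw) <- list(probeIds, colnames(g))

  annotation <- data.frame(probe_id = probeIds, gene_symbol = symbols,
                           stringsAsFactors = FALSE)
  probes <- ProbeExperiment(raw, annotation,
                            group = sampleGroups(sim$dataset),
                            week = sampleWeeks(sim$dataset),
                            caseLabel = config@caseLabel,
                            controlLabel = config@controlLabel,
                            weekLevels = config@weeks)
  list(probes = probes, annotation = annotation,
       genes = sim$dataset, truth = sim$truth)
}

setMethod("show", "DNBTruth", function(object) {
  cat("DNBTruth:", length(object@dnbGenes), "planted DNB genes (peak",
      object@peakWeek, "),",
      length(unlist(object@degGenes)), "planted DEGs in",
      length(object@degGenes), "clusters\n")
})

setMethod("show", "DNBSimConfig", function(object) {
  cat("DNBSimConfig:", object@nGenes, "genes,", object@nDnb,
      "planted DNB genes; weeks", paste(object@weeks, collapse = ","),
      "; peak", object@peakWeek, "\n")
  cat("  sdRatio =", object@sdRatio, ", target |r| =", object@targetAbsCorr,
      ", noiseSd =", object@noiseSd, ", seed =", object@seed, "\n")
})
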