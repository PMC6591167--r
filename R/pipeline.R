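#' Declarative configuration for an end-to-end run
#'
#' Assembles and validates the flat key-value configuration consumed by
#' [runDNBPipeline()]. Either a synthetic design (`sim`, a list of
#' [dnbSimConfig()] arguments) or input paths (`values`/`meta`, optionally
#' `probes`/`annotation` for raw data) must be given. All analysis defaults
#' mirror the preset pipeline: thresholds theta = (10, 50, 80), DEG level
#' q = 0.05 with log2 fold-change threshold 1, clustering cutoff 0.5, 100
#' shuffles at the 95th percentile for parallel analysis.
#'
#' @param sim list of arguments to [dnbSimConfig()], or NULL when reading
#'   data from files.
#' @param values,meta paths of an expression TSV + metadata CSV
#'   (gene-level input).
#' @param probes,annotation,probeMeta paths of a probe TSV, annotation TSV
#'   and metadata CSV (raw input routed through [preprocessProbes()]).
#' @param caseWeek scored week (default: the synthetic peak week, else the
#'   middle week).
#' @param controlWeek control-slice week (defaults to `caseWeek`).
#' @param thetas,q,lfcThreshold,clusterCutoff,paShuffles,paPercentile
#'   analysis parameters.
#' @param gmt optional path to a GMT collection for enrichment.
#' @param seed integer master seed.
#' @return a validated config list of class `dnbRunConfig`.
#' @export
dnbRunConfig <- function(sim = list(), values = NULL, meta = NULL,
                         probes = NULL, annotation = NULL, probeMeta = NULL,
                         caseWeek = NULL, controlWeek = NULL,
                         thetas = c(10, 50, 80), q = 0.05, lfcThreshold = 1,
                         clusterCutoff = 0.5, paShuffles = 100,
                         paPercentile = 95, gmt = NULL, seed = 1L) {
  cfg <- list(sim = sim, values = values, meta = meta, probes = probes,
              annotation = annotation, probeMeta = probeMeta,
              caseWeek = caseWeek, controlWeek = controlWeek,
              thetas = as.numeric(thetas), q = q,
              lfcThreshold = lfcThreshold, clusterCutoff = clusterCutoff,
              paShuffles = paShuffles, paPercentile = paPercentile,
              gmt = gmt, seed = as.integer(seed))
  if (length(cfg$thetas) != 3 || any(cfg$thetas <= 0 | cfg$thetas > 100))
    stop("thetas must be three percentages in (0, 100]")
  if (cfg$q <= 0 || cfg$q > 1) stop("q must be in (0, 1]")
  for (f in c("values", "meta", "probes", "annotation", "probeMeta", "gmt"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured ", f, " file does not exist: ", cfg[[f]])
  class(cfg) <- "dnbRunConfig"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [dnbRunConfig()].
#' @return a `dnbRunConfig` list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  do.call(dnbRunConfig, yaml::read_yaml(path))
}

#' Run the full DNB analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> differential expression
#' -> DNB selection and scoring -> exploratory statistics -> enrichment
#' from one declarative configuration, writing every stage output plus a
#' machine-readable JSON summary to `outdir`. Runs are deterministic for a
#' fixed config seed.
#'
#' @param config a `dnbRunConfig` (see [dnbRunConfig()]) or the path of a
#'   YAML file.
#' @param outdir output directory, created if needed.
#' @param verbose print stage progress to stderr.
#' @return invisibly, the summary list (also written to
#'   `outdir/summary.json`).
#' @examples
#' \donttest{
#' out <- runDNBPipeline(dnbRunConfig(sim = list(nGenes = 150, nDnb = 15)),
#'                       outdir = tempfile())
#' out$dnb$nStar
#' }
#' @export
runDNBPipeline <- function(config = dnbRunConfig(), outdir = "dnb_run",
                           verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "dnbRunConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (verbose) message("[DNBdetect] ", ...)
  summary <- list(parameters = config[setdiff(names(config), "sim")],
                  seed = config$seed)

  # --- input stage: simulate, or read gene- or probe-level files
  truth <- NULL
  if (!is.null(config$probes)) {
    note("reading probe data")
    pd <- readProbeData(config$probes, config$annotation, config$probeMeta)
    x <- preprocessProbes(pd)
  } else if (!is.null(config$values)) {
    note("reading expression data")
    x <- readExpressionData(config$values, config$meta)
  } else {
    note("simulating dataset")
    simArgs <- config$sim
    if (is.null(simArgs$seed)) simArgs$seed <- config$seed
    simCfg <- do.call(dnbSimConfig, simArgs)
    sim <- simulateExpression(simCfg)
    x <- sim$dataset; truth <- sim$truth
    summary$sim <- list(nGenes = simCfg@nGenes, nDnb = simCfg@nDnb,
                        peakWeek = simCfg@peakWeek, seed = simCfg@seed)
    jsonlite::write_json(
      list(dnbGenes = truth@dnbGenes, degGenes = truth@degGenes,
           peakWeek = truth@peakWeek),
      file.path(outdir, "truth.json"), auto_unbox = TRUE)
  }
  writeExpressionData(x, file.path(outdir, "expression.tsv"),
                      file.path(outdir, "sample_meta.csv"))
  caseWeek <- config$caseWeek %||% truthPeak(truth, x)
  controlWeek <- config$controlWeek %||% caseWeek

  # --- differential expression
  note("extracting DEGs")
  deg <- extractDEGs(x, q = config$q, lfcThreshold = config$lfcThreshold)
  writeDEGResult(deg, outdir)
  summary$deg <- list(perWeek = vapply(degSets(deg), length, 0L),
                      union = length(degUnion(deg)))

  # --- DNB selection and scores
  note("selecting DNB genes (theta = ",
       paste(config$thetas, collapse = "/"), ")")
  sel <- selectDNB(x, caseWeek = caseWeek, controlWeek = controlWeek,
                   thetas = config$thetas)
  genes <- dnbGenes(sel)
  writeLines(genes, file.path(outdir, "dnb_genes.txt"))
  summary$dnb <- list(caseWeek = caseWeek, controlWeek = controlWeek,
                      nS1 = length(sel@S1), nS2 = length(sel@S2),
                      nS3 = length(sel@S3), nStar = length(genes))
  if (length(genes) >= 2) {
    ss <- scoreSeries(x, genes)
    write.table(scoreTable(ss), file.path(outdir, "score_series.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    peak <- peakWeekOf(ss, caseLabel(x))
    rr <- recoveryRateSeries(x, genes)
    write.table(rr, file.path(outdir, "recovery_rate.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$dnb$peakWeek <- peak
    if (!is.null(truth))
      summary$dnb$truthJaccard <- length(intersect(genes, truth@dnbGenes)) /
        length(union(genes, truth@dnbGenes))
  }

  # --- exploratory statistics
  note("parallel analysis (", config$paShuffles, " shuffles)")
  pa <- parallelAnalysis(x, nShuffles = config$paShuffles,
                         percentile = config$paPercentile,
                         seed = config$seed)
  write.table(data.frame(component = seq_along(pa@eigenvalues),
                         eigenvalue = pa@eigenvalues,
                         nullQuantile = pa@nullQuantiles),
              file.path(outdir, "pca_eigenvalues.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$pca <- list(nMeaningful = nMeaningful(pa))
  if (length(degUnion(deg)) >= 2) {
    note("clustering DEG union")
    cl <- clusterGenes(x, genes = degUnion(deg),
                       cutoff = config$clusterCutoff)
    write.table(data.frame(gene = names(clusterLabels(cl)),
                           cluster = clusterLabels(cl)),
                file.path(outdir, "cluster_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$clusters <- list(sizes = head(clusterSizes(cl), 10))
    fmGenes <- sort(union(genes, degUnion(deg)))
    fm <- fluctuationMap(x, fmGenes)
    write.table(data.frame(gene = rownames(fm), fm, check.names = FALSE),
                file.path(outdir, "fluctuation_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # --- enrichment (optional)
  if (!is.null(config$gmt) && length(genes) > 0) {
    note("gene-set enrichment")
    enr <- enrichGeneSets(genes, readGMT(config$gmt),
                          universe = rownames(x))
    write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$enrichment <- list(nReported = nrow(enr))
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("done; outputs in ", outdir)
  invisible(summary)
}

truthPeak <- function(truth, x) {
  if (!is.null(truth)) return(truth@peakWeek)
  wl <- weekLevels(x)
  wl[ceiling(length(wl) / 2)]
}

peakWeekOf <- function(ss, group) {
  tab <- scoreTable(ss)
  tab <- tab[tab$group == group, ]
  # the pre-disease signature is a simultaneous peak; report the week
  # maximizing the rank-sum of the two scores
  score <- rank(tab$Is) + rank(tab$Ir)
  tab$week[which.max(score)]
}
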