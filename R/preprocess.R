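#' Collapse probes to gene symbols
#'
#' Removes probes without any gene-symbol annotation and, where several
#' probes map to one symbol, takes the per-sample arithmetic mean of their
#' raw intensities. The output is keyed by gene symbol, sorted
#' lexicographically for reproducible downstream indices.
#'
#' @param probes a [ProbeExperiment-class].
#' @return A [ProbeExperiment-class] whose rows are gene symbols (each
#'   symbol annotated to itself).
#' @export
collapseProbes <- function(probes) {
  stopifnot(is(probes, "ProbeExperiment"))
  sym <- rowData(probes)$gene_symbol
  keep <- !is.na(sym) & sym != ""
  if (!any(keep))
    stop("all probes are unannotated; nothing to collapse")
  v <- assay(probes, "intensity")[keep, , drop = FALSE]
  sym <- sym[keep]
  collapsed <- rowsum(v, group = sym) / as.vector(table(sym)[sort(unique(sym))])
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  ProbeExperiment(collapsed,
                  annotation = data.frame(probe_id = rownames(collapsed),
                                          gene_symbol = rownames(collapsed)),
                  group = sampleGroups(probes), week = sampleWeeks(probes),
                  caseLabel = caseLabel(probes),
                  controlLabel = controlLabel(probes),
                  weekLevels = weekLevels(probes))
}

#' 2% trimmed mean of a vector
#'
#' Mean after discarding the lowest and highest `trim` fraction of values;
#' the number discarded per side is `floor(trim * length(x))`, so short
#' vectors are left intact.
#'
#' @param x numeric vector.
#' @param trim fraction trimmed from each tail (default 0.02).
#' @return scalar trimmed mean.
#' @export
trimmedMean <- function(x, trim = 0.02) {
  k <- floor(trim * length(x))
  xs <- sort(x)
  if (k > 0) xs <- xs[(k + 1):(length(xs) - k)]
  mean(xs)
}

#' Normalize samples by their 2% trimmed mean
#'
#' Divides each sample column by its trimmed mean so that array-level scale
#' differences cancel; after normalization every column's recomputed trimmed
#' mean is 1.
#'
#' @param m non-negative genes-by-samples matrix.
#' @param trim fraction trimmed per tail.
#' @return matrix of the same shape.
#' @export
trimmedMeanNormalize <- function(m, trim = 0.02) {
  tm <- apply(m, 2, trimmedMean, trim = trim)
  bad <- which(tm <= 0)
  if (length(bad))
    stop("non-positive trimmed mean in sample(s): ",
         paste(colnames(m)[bad] %||% bad, collapse = ", "))
  sweep(m, 2, tm, `/`)
}

#' Elementwise log2 with domain checking
#'
#' @param m strictly positive matrix.
#' @return `log2(m)`.
#' @export
log2Transform <- function(m) {
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive value at gene '",
         rownames(m)[bad[1, 1]] %||% bad[1, 1], "', sample '",
         colnames(m)[bad[1, 2]] %||% bad[1, 2],
         "': log2 requires strictly positive intensities")
  log2(m)
}

#' Full preprocessing: collapse, normalize, log2
#'
#' Runs the standard pipeline in order — probe collapsing to gene symbols,
#' per-sample 2% trimmed-mean normalization on the raw scale, then base-2
#' log transformation — and returns the analysis-ready container.
#'
#' @param probes a [ProbeExperiment-class] of raw intensities.
#' @param trim trimmed fraction per tail for normalization.
#' @return A [DNBExperiment-class].
#' @examples
#' sim <- simulateProbes(dnbSimConfig(nGenes = 50, nDnb = 5, seed = 3))
#' x <- preprocessProbes(sim$probes)
#' x
#' @export
preprocessProbes <- function(probes, trim = 0.02) {
  collapsed <- collapseProbes(probes)
  norm <- trimmedMeanNormalize(assay(collapsed, "intensity"), trim = trim)
  DNBExperiment(log2Transform(norm),
                group = sampleGroups(probes), week = sampleWeeks(probes),
                caseLabel = caseLabel(probes),
                controlLabel = controlLabel(probes),
                weekLevels = weekLevels(probes))
}
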