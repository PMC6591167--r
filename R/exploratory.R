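#' PCA of samples from mean-centered expression
#'
#' Eigendecomposition of the sample covariance matrix (equivalently a
#' singular value decomposition of the mean-centered genes-by-samples
#' matrix): sample scores, covariance eigenvalues and explained-variance
#' ratios. The number of meaningful components is filled in by
#' [parallelAnalysis()].
#'
#' @param x a [DNBExperiment-class] or genes-by-samples matrix.
#' @return A [PCAResult-class] with `nMeaningful = NA` until parallel
#'   analysis is run.
#' @export
pcaSamples <- function(x) {
  m <- if (is(x, "DNBExperiment")) exprs(x) else as.matrix(x)
  if (ncol(m) < 2) stop("PCA needs at least 2 samples")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  new("PCAResult", scores = pc$x, eigenvalues = ev,
      varExplained = ev / sum(ev), nMeaningful = NA_integer_,
      nullQuantiles = numeric())
}

# ordered covariance eigenvalues of a genes-by-samples matrix
covEigenvalues <- function(m) {
  sv <- svd(scale(t(m), center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  ev <- sv^2 / (nrow(t(m)) - 1)
  sort(ev, decreasing = TRUE)
}

#' Parallel analysis: how many principal components are meaningful
#'
#' A permutation variant of parallel analysis: each gene's values are
#' shuffled across samples independently (destroying inter-gene correlation
#' while preserving every per-gene value multiset exactly), `nShuffles`
#' times; the original ordered eigenvalues are compared with the matching
#' ordered-eigenvalue percentile of the shuffled data, and the number of
#' original eigenvalues above their threshold is reported.
#'
#' @param x a [DNBExperiment-class] or genes-by-samples matrix.
#' @param nShuffles number of shuffled matrices (>= 10; default 100).
#' @param percentile eigenvalue percentile of the null (default 95).
#' @param seed integer seed for the shuffles.
#' @return A [PCAResult-class] with `nMeaningful` and the per-component
#'   null thresholds filled in.
#' @examples
#' sim <- simulateExpression(dnbSimConfig(nGenes = 100, nDnb = 10, seed = 2))
#' pa <- parallelAnalysis(sim$dataset, nShuffles = 20, seed = 1)
#' nMeaningful(pa)
#' @export
parallelAnalysis <- function(x, nShuffles = 100, percentile = 95, seed = 1) {
  stopifnot(nShuffles >= 10)
  m <- if (is(x, "DNBExperiment")) exprs(x) else as.matrix(x)
  res <- pcaSamples(m)
  ev <- res@eigenvalues
  set.seed(seed)
  nullEv <- matrix(0, nShuffles, length(ev))
  for (b in seq_len(nShuffles)) {
    shuf <- t(apply(m, 1, sample))
    nullEv[b, ] <- covEigenvalues(shuf)[seq_along(ev)]
  }
  thr <- apply(nullEv, 2, quantile, probs = percentile / 100, names = FALSE)
  res@nullQuantiles <- thr
  res@nMeaningful <- as.integer(sum(ev > thr))
  res
}

#' @rdname PCAResult-accessors
#' @param x a [PCAResult-class].
#' @export
setMethod("nMeaningful", "PCAResult", function(x) x@nMeaningful)

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult:", length(object@eigenvalues), "components;",
      "leading explained-variance ratios:",
      paste(round(head(object@varExplained, 3), 3), collapse = ", "), "\n")
  if (!is.na(object@nMeaningful))
    cat("  meaningful components (parallel analysis):",
        object@nMeaningful, "\n")
})

#' Correlation-based hierarchical clustering of genes
#'
#' Each gene is z-scored across all samples (so per-gene affine scale drops
#' out), dissimilarity is `1 - r` on the z-scored rows, the dendrogram uses
#' average linkage, and flat clusters are cut at inter-cluster dissimilarity
#' `cutoff`. Cluster labels are renumbered so that label 1 is the largest
#' cluster.
#'
#' @param x a [DNBExperiment-class] or genes-by-samples matrix.
#' @param genes optional subset of genes to cluster (e.g. a DEG union).
#' @param cutoff tree cut height on the 1 - r scale (default 0.5).
#' @return A [ClusterResult-class].
#' @export
clusterGenes <- function(x, genes = NULL, cutoff = 0.5) {
  m <- if (is(x, "DNBExperiment")) exprs(x) else as.matrix(x)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 genes to cluster")
  s <- rowSds(m)
  if (any(s == 0))
    stop("zero-variance gene(s) cannot be z-scored: ",
         paste(head(rownames(m)[s == 0]), collapse = ", "))
  z <- (m - rowMeans(m)) / s
  d <- as.dist(1 - cor(t(z)))
  tree <- hclust(d, method = "average")
  raw <- cutree(tree, h = cutoff)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  labels <- setNames(as.integer(relabel[as.character(raw)]), names(raw))
  new("ClusterResult", labels = labels,
      sizes = as.integer(sizes), tree = tree, zMatrix = z, cutoff = cutoff)
}

#' @rdname ClusterResult-accessors
#' @param x a [ClusterResult-class].
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname ClusterResult-accessors
#' @export
setMethod("clusterSizes", "ClusterResult", function(x) x@sizes)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@labels), "genes in",
      length(object@sizes), "clusters (cutoff", object@cutoff, ")\n")
  cat("  sizes:", paste(head(object@sizes, 10), collapse = ", "),
      if (length(object@sizes) > 10) "..." else "", "\n")
})

#' Case/control dissimilarity for embedding DNB structure
#'
#' `d_ij = 1 - |r_ij| + |r'_ij|`, where `r` and `r'` are the gene-gene
#' correlations in the case and control slices of the scored week. Gene
#' pairs tightly correlated in the case slice but not in the control end up
#' close (d near 0); the reverse pattern is pushed apart (d near 2). The
#' matrix is intended as a precomputed dissimilarity for any embedding
#' method (e.g. t-SNE with perplexity 100); the diagonal equals 1 by the
#' formula and should be excluded from embeddings.
#'
#' @param Xcase,Xcontrol genes-by-samples matrices (same genes, >= 3
#'   samples each).
#' @return symmetric genes-by-genes dissimilarity matrix with values in
#'   \[0, 2\].
#' @export
dnbDissimilarity <- function(Xcase, Xcontrol) {
  stopifnot(identical(rownames(Xcase), rownames(Xcontrol)),
            ncol(Xcase) >= 3, ncol(Xcontrol) >= 3)
  1 - absCorRows(Xcase) + absCorRows(Xcontrol)
}

#' Per-gene standard deviation across all conditions
#'
#' The spatio-temporal fluctuation map: for each requested gene, the sample
#' standard deviation within every (group, week) condition slice. Planted
#' or genuine DNB genes show their row maximum at the case group's peak
#' week.
#'
#' @param x a [DNBExperiment-class].
#' @param genes genes to tabulate (default: all).
#' @return matrix genes x conditions, columns named `group:week`.
#' @export
fluctuationMap <- function(x, genes = rownames(x)) {
  ct <- conditionTable(x)
  out <- sapply(seq_len(nrow(ct)), function(i)
    rowSds(conditionSlice(x, ct$group[i], ct$week[i])[genes, ,
                                                      drop = FALSE]))
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, paste(ct$group, ct$week, sep = ":")))
  out
}
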