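#' Fold-change candidate genes
#'
#' Genes whose log2 group means differ by strictly more than `lfcThreshold`
#' (default 1, i.e. more than a two-fold change on the raw scale).
#'
#' @param X,Y genes-by-samples log2 matrices for the two groups, with the
#'   same gene universe (rownames).
#' @param lfcThreshold log2 difference threshold; strict inequality.
#' @return character vector of candidate gene ids.
#' @export
foldChangeCandidates <- function(X, Y, lfcThreshold = 1) {
  stopifnot(identical(rownames(X), rownames(Y)))
  d <- abs(rowMeans(X) - rowMeans(Y))
  rownames(X)[d > lfcThreshold]
}

#' Two-tailed Welch's t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#' Degenerate inputs follow fixed conventions so the gene universe stays
#' stable across thousands of tests: two constant groups with equal means
#' give `t = 0, p = 1`; constant groups with different means give `p = 0`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welchTest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  if (!is.finite(df) || df <= 0) stop("degenerate degrees of freedom")
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Benjamini-Hochberg rejections
#'
#' Step-up FDR control: rejects all hypotheses with BH-adjusted p-value at
#' most `q` (equivalent to the largest-k step-up rule).
#'
#' @param pvals p-values in \[0, 1\].
#' @param q FDR level.
#' @return logical rejection vector, same length/names as `pvals`.
#' @export
bhReject <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "BH") <= q
}

#' Extract differentially expressed genes per week
#'
#' For every time point, compares the case and control slices gene-by-gene:
#' the DEG set is the intersection of the fold-change candidates (log2 mean
#' difference strictly above `lfcThreshold`) and the Welch-test rejections
#' after Benjamini-Hochberg control at level `q` (applied per week across
#' genes). Also assembles the union across weeks and the gene-by-week
#' incidence pattern.
#'
#' @param x a [DNBExperiment-class] with both groups at every week.
#' @param q FDR level for the BH procedure.
#' @param lfcThreshold log2 fold-change threshold (strict).
#' @return A [DEGResult-class].
#' @examples
#' sim <- simulateExpression(dnbSimConfig(nGenes = 120, nDnb = 10,
#'                                        nDegClusters = 1, seed = 11))
#' res <- extractDEGs(sim$dataset)
#' res
#' @export
extractDEGs <- function(x, q = 0.05, lfcThreshold = 1) {
  weeks <- weekLevels(x)
  perWeek <- list(); sets <- list()
  for (w in weeks) {
    X <- conditionSlice(x, caseLabel(x), w)
    Y <- conditionSlice(x, controlLabel(x), w)
    lfc <- rowMeans(X) - rowMeans(Y)
    tests <- lapply(seq_len(nrow(X)),
                    function(i) welchTest(X[i, ], Y[i, ]))
    p <- vapply(tests, `[[`, 0, "p")
    rejected <- bhReject(p, q)
    fcCand <- abs(lfc) > lfcThreshold
    deg <- fcCand & rejected
    perWeek[[w]] <- data.frame(
      gene = rownames(X), lfc = lfc,
      t = vapply(tests, `[[`, 0, "t"), p = p,
      fcCandidate = fcCand, rejected = rejected, deg = deg,
      row.names = NULL)
    sets[[w]] <- rownames(X)[deg]
  }
  union <- sort(unique(unlist(sets)))
  incidence <- matrix(0L, length(union), length(weeks),
                      dimnames = list(union, weeks))
  for (w in weeks) incidence[sets[[w]], w] <- 1L
  new("DEGResult", perWeek = perWeek, degSets = sets, union = union,
      incidence = incidence, q = q, lfcThreshold = lfcThreshold)
}

#' @rdname DEGResult-accessors
#' @param x a [DEGResult-class].
#' @export
setMethod("degSets", "DEGResult", function(x) x@degSets)

#' @rdname DEGResult-accessors
#' @export
setMethod("degUnion", "DEGResult", function(x) x@union)

#' @rdname DEGResult-accessors
#' @export
setMethod("degIncidence", "DEGResult", function(x) x@incidence)

setMethod("show", "DEGResult", function(object) {
  counts <- vapply(object@degSets, length, 0L)
  cat("DEGResult (q =", object@q, ", |log2 FC| >", object@lfcThreshold,
      "):\n  per week:",
      paste(names(counts), counts, sep = "=", collapse = ", "),
      "\n  union:", length(object@union), "genes\n")
})

#' Write per-week DEG tables and the incidence matrix
#'
#' @param res a [DEGResult-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeDEGResult <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (w in names(res@perWeek)) {
    p <- file.path(dir, paste0("deg_", w, ".tsv"))
    write.table(res@perWeek[[w]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  inc <- file.path(dir, "deg_incidence.tsv")
  write.table(data.frame(gene = rownames(res@incidence), res@incidence,
                         check.names = FALSE),
              inc, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, inc))
}
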