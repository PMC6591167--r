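#' Standard-deviation ratio between case and control slices
#'
#' The first selection statistic: `v1_i = s_i(X) / s_i(Y)`, the per-gene
#' ratio of sample standard deviations (K-1 denominator) between the case
#' slice X and the control slice Y. Genes with zero standard deviation in
#' either slice are undefined and returned as `NA`; [topFraction()] skips
#' them and [selectDNB()] reports them.
#'
#' @param X,Y genes-by-samples log2 matrices with identical rownames.
#' @return named numeric vector of ratios (NA where undefined).
#' @export
varianceRatio <- function(X, Y) {
  stopifnot(identical(rownames(X), rownames(Y)))
  sx <- rowSds(X); sy <- rowSds(Y)
  v1 <- sx / sy
  v1[sx == 0 | sy == 0] <- NA_real_
  setNames(v1, rownames(X))
}

#' Select the highest-scoring fraction of genes
#'
#' Returns the `max(1, floor(theta/100 * n))` genes with the largest scores,
#' where `n` counts the genes with defined (non-NA) scores. Ties at the
#' cutoff are broken by ascending gene id so that selections are
#' deterministic, which leave-one-out statistics require.
#'
#' @param scores named numeric vector; NA entries are excluded from ranking.
#' @param theta percentage in (0, 100].
#' @return character vector of selected gene ids.
#' @export
topFraction <- function(scores, theta) {
  stopifnot(theta > 0, theta <= 100, !is.null(names(scores)))
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no defined scores to rank")
  nSel <- max(1L, floor(theta / 100 * length(scores)))
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(nSel)]
}

# sum of |r| differences with NA-free guarantees; rows of A against rows of B
absCorGain <- function(X, Y, rowsA, rowsB = rowsA) {
  rx <- absCorRows(X[rowsA, , drop = FALSE],
                   if (identical(rowsA, rowsB)) NULL
                   else X[rowsB, , drop = FALSE])
  ry <- absCorRows(Y[rowsA, , drop = FALSE],
                   if (identical(rowsA, rowsB)) NULL
                   else Y[rowsB, , drop = FALSE])
  g <- rx - ry
  g[is.na(g)] <- 0   # zero-variance partners contribute nothing
  rowSums(g)
}

#' Within-set correlation gain
#'
#' The second selection statistic: for each gene i in `S1`,
#' `v2_i = sum_{j in S1} (|r_ij(X)| - |r_ij(Y)|)` — the summed gain in
#' correlation strength against the other members of `S1` between case and
#' control. The self term is included as written and contributes zero.
#'
#' @param X,Y genes-by-samples matrices over the full universe.
#' @param S1 gene ids selected by the first step (length >= 2).
#' @return named numeric vector over `S1`.
#' @export
correlationGainWithin <- function(X, Y, S1) {
  stopifnot(length(S1) >= 2, all(S1 %in% rownames(X)))
  setNames(absCorGain(X, Y, S1), S1)
}

#' Non-specific correlation gain against genes outside S1
#'
#' The third selection statistic: for each gene i in `S1`,
#' `v3_i = sum_{j in S0 \ S1} (|r_ij(X)| - |r_ij(Y)|)`. Genes scoring high
#' here gained correlation indiscriminately across the transcriptome and are
#' excluded from the candidate set.
#'
#' @param X,Y genes-by-samples matrices over the full universe `S0`
#'   (rownames).
#' @param S1 gene ids from step one.
#' @return named numeric vector over `S1`.
#' @export
nonspecificGainOutside <- function(X, Y, S1) {
  outside <- setdiff(rownames(X), S1)
  if (!length(outside)) stop("S0 \\ S1 is empty; cannot compute v3")
  setNames(absCorGain(X, Y, S1, outside), S1)
}

#' Three-step DNB gene selection
#'
#' Implements the ranked selection: `S1` = top `theta1`% of the
#' standard-deviation ratio v1 over all defined genes; `S2` = top `theta2`%
#' of the within-`S1` correlation gain v2; `S3` = top `theta3`% of the
#' non-specific gain v3; and the DNB candidate set `S* = S2 \ S3` — genes
#' whose fluctuation and correlation increased specifically within `S1`.
#' An empty `S*` is a valid outcome.
#'
#' Given a [DNBExperiment-class], the case slice defaults to
#' (caseLabel, caseWeek) and the control slice to (controlLabel,
#' controlWeek).
#'
#' @param x case-slice matrix X (genes x samples), or a
#'   [DNBExperiment-class].
#' @param Y control-slice matrix (matrix method).
#' @param thetas percentages `c(theta1, theta2, theta3)`; the preset used
#'   throughout is `c(10, 50, 80)`.
#' @param caseWeek,controlWeek,caseGroup,controlGroup condition labels
#'   (DNBExperiment method); `controlWeek` defaults to `caseWeek`.
#' @param ... passed through.
#' @return A [DNBSelection-class].
#' @examples
#' sim <- simulateExpression(dnbSimConfig(seed = 5))
#' sel <- selectDNB(sim$dataset, caseWeek = "wk5")
#' sel
#' length(intersect(dnbGenes(sel), sim$truth@dnbGenes))
#' @export
setMethod("selectDNB", "matrix", function(x, Y, thetas = c(10, 50, 80), ...) {
  X <- x
  stopifnot(identical(rownames(X), rownames(Y)),
            ncol(X) >= 3, ncol(Y) >= 3, length(thetas) == 3)
  v1 <- varianceRatio(X, Y)
  excluded <- names(v1)[is.na(v1)]
  S1 <- sort(topFraction(v1, thetas[1]))
  v2 <- if (length(S1) >= 2) correlationGainWithin(X, Y, S1)
        else setNames(0, S1)   # lone gene: only the zero self-term
  v3 <- nonspecificGainOutside(X, Y, S1)
  S2 <- sort(topFraction(v2, thetas[2]))
  S3 <- sort(topFraction(v3, thetas[3]))
  new("DNBSelection", S0 = setdiff(rownames(X), excluded),
      S1 = S1, S2 = S2, S3 = S3,
      sStar = sort(setdiff(S2, S3)),
      v1 = v1, v2 = v2, v3 = v3, thetas = as.numeric(thetas),
      excluded = excluded)
})

#' @rdname selectDNB
#' @export
setMethod("selectDNB", "DNBExperiment",
          function(x, caseWeek, controlWeek = caseWeek,
                   thetas = c(10, 50, 80),
                   caseGroup = caseLabel(x), controlGroup = controlLabel(x),
                   ...) {
  X <- conditionSlice(x, caseGroup, caseWeek)
  Y <- conditionSlice(x, controlGroup, controlWeek)
  selectDNB(X, Y = Y, thetas = thetas)
})

#' @rdname DNBSelection-accessors
#' @param x a [DNBSelection-class].
#' @export
setMethod("dnbGenes", "DNBSelection", function(x) x@sStar)

setMethod("show", "DNBSelection", function(object) {
  cat("DNBSelection (theta =",
      paste(object@thetas, collapse = "/"), "%):\n")
  cat("  |S0| =", length(object@S0), " |S1| =", length(object@S1),
      " |S2| =", length(object@S2), " |S3| =", length(object@S3),
      " |S*| =", length(object@sStar), "\n")
  if (length(object@excluded))
    cat("  ", length(object@excluded),
        "gene(s) excluded (zero SD in a slice)\n")
})

#' Small-sample correlation correction term
#'
#' The expected absolute Pearson correlation of two independent
#' standard-normal samples of size M. Under independence the correlation
#' coefficient has density proportional to `(1 - r^2)^((M-4)/2)` on
#' \[-1, 1\], giving the closed form
#' `c(M) = 1 / ((a + 1) * beta(1/2, a + 1))` with `a = (M - 4)/2`:
#' exactly 0.5 at M = 4 and `4/(3*pi)` (0.4244) at M = 5. Subtracting c(M)
#' removes the systematic small-sample inflation of average correlation
#' strength when comparing conditions with few samples.
#'
#' @param M sample count (>= 3); vectorized.
#' @return expected |r| under the null, strictly decreasing in M.
#' @examples
#' correctionTerm(4)            # 0.5
#' round(correctionTerm(5), 2)  # 0.42
#' @export
correctionTerm <- function(M) {
  stopifnot(all(M >= 3))
  a <- (M - 4) / 2
  1 / ((a + 1) * beta(0.5, a + 1))
}

#' Average standard deviation of a candidate set (I_s)
#'
#' @param Z genes-by-samples matrix of one condition slice.
#' @param genes candidate gene ids (nonempty, in `rownames(Z)`).
#' @return mean of the per-gene sample standard deviations.
#' @export
scoreIs <- function(Z, genes) {
  stopifnot(length(genes) >= 1, all(genes %in% rownames(Z)))
  mean(rowSds(Z[genes, , drop = FALSE]))
}

#' Corrected average correlation strength of a candidate set (I_r)
#'
#' Mean absolute pairwise correlation over unordered gene pairs within the
#' slice, minus the null expectation [correctionTerm()] for the slice's
#' sample count, so that uncorrelated genes score near zero at any sample
#' size.
#'
#' @param Z genes-by-samples matrix of one condition slice (>= 3 samples).
#' @param genes candidate gene ids (>= 2).
#' @param correction optional override of the correction term.
#' @return I_r in \[-c, 1-c\].
#' @export
scoreIr <- function(Z, genes, correction = NULL) {
  stopifnot(length(genes) >= 2, all(genes %in% rownames(Z)), ncol(Z) >= 3)
  c0 <- correction %||% correctionTerm(ncol(Z))
  meanAbsPairCor(Z[genes, , drop = FALSE]) - c0
}

#' I_s and I_r across all experimental conditions
#'
#' Evaluates the two DNB scores for every (group, week) condition slice of
#' the dataset; a genuine pre-disease state shows a simultaneous peak of
#' both scores at one week in the case group.
#'
#' @param x a [DNBExperiment-class].
#' @param genes the candidate set (e.g. `dnbGenes(selection)`).
#' @param ... unused.
#' @return A [DNBScoreSeries-class].
#' @examples
#' sim <- simulateExpression(dnbSimConfig(seed = 5))
#' sel <- selectDNB(sim$dataset, caseWeek = "wk5")
#' scoreSeries(sim$dataset, dnbGenes(sel))
#' @export
setMethod("scoreSeries", "DNBExperiment", function(x, genes, ...) {
  stopifnot(length(genes) >= 2)
  ct <- conditionTable(x)
  rows <- lapply(seq_len(nrow(ct)), function(i) {
    Z <- conditionSlice(x, ct$group[i], ct$week[i])
    c0 <- correctionTerm(ncol(Z))
    data.frame(group = ct$group[i], week = ct$week[i], M = ncol(Z),
               Is = scoreIs(Z, genes),
               Ir = scoreIr(Z, genes, correction = c0), c = c0)
  })
  new("DNBScoreSeries", table = do.call(rbind, rows))
})

#' @rdname DNBScoreSeries-accessors
#' @param x a [DNBScoreSeries-class].
#' @export
setMethod("scoreTable", "DNBScoreSeries", function(x) x@table)

setMethod("show", "DNBScoreSeries", function(object) {
  cat("DNBScoreSeries over", nrow(object@table), "conditions:\n")
  print(object@table, row.names = FALSE, digits = 4)
})

#' Plot I_s and I_r across weeks
#'
#' Base-graphics line plot of the two DNB scores per group, one panel per
#' score.
#'
#' @param x a [DNBScoreSeries-class].
#' @param y ignored.
#' @param weekOrder optional ordered week labels.
#' @param ... passed to [graphics::matplot()].
#' @export
setMethod("plot", signature("DNBScoreSeries", "missing"),
          function(x, y, weekOrder = NULL, ...) {
  tab <- x@table
  weeks <- weekOrder %||% unique(tab$week)
  groups <- unique(tab$group)
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  for (stat in c("Is", "Ir")) {
    m <- sapply(groups, function(g)
      tab[[stat]][match(paste(g, weeks), paste(tab$group, tab$week))])
    graphics::matplot(seq_along(weeks), m, type = "b", pch = 19, lty = 1,
                      xaxt = "n", xlab = "week", ylab = stat, ...)
    graphics::axis(1, at = seq_along(weeks), labels = weeks)
    graphics::legend("topleft", legend = groups, col = seq_along(groups),
                     lty = 1, bty = "n")
  }
  invisible(x)
})

#' Sweep the selection thresholds and rank by peak sharpness
#'
#' Runs [selectDNB()] for every combination of the three threshold grids,
#' scores each candidate set across the case-group weeks, and ranks the
#' combinations by peak sharpness at `targetWeek`: for each of I_s and I_r,
#' `(score at target - max score at other weeks) / (max - min across
#' weeks)`, taking the minimum of the two. Positive sharpness means both
#' scores attain their maximum at the target week; combinations with an
#' empty candidate set get undefined sharpness and rank last.
#'
#' @param x a [DNBExperiment-class].
#' @param caseWeek,controlWeek slices used for the selection itself.
#' @param theta1Grid,theta2Grid,theta3Grid percentage grids.
#' @param targetWeek week at which a sharp peak is sought (defaults to
#'   `caseWeek`).
#' @return data.frame sorted by decreasing sharpness, with one row per
#'   threshold combination (`theta1`, `theta2`, `theta3`, `nStar`,
#'   `sharpness`, `rank`).
#' @export
sweepParameters <- function(x, caseWeek, controlWeek = caseWeek,
                            theta1Grid = c(5, 10, 20),
                            theta2Grid = c(25, 50, 75),
                            theta3Grid = c(60, 80, 90),
                            targetWeek = caseWeek) {
  grid <- expand.grid(theta1 = theta1Grid, theta2 = theta2Grid,
                      theta3 = theta3Grid, KEEP.OUT.ATTRS = FALSE)
  weeks <- weekLevels(x)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- selectDNB(x, caseWeek = caseWeek, controlWeek = controlWeek,
                     thetas = as.numeric(grid[i, 1:3]))
    genes <- dnbGenes(sel)
    if (length(genes) < 2)
      return(cbind(grid[i, ], nStar = length(genes),
                   sharpness = NA_real_))
    tab <- scoreTable(scoreSeries(x, genes))
    tab <- tab[tab$group == caseLabel(x), ]
    tab <- tab[match(weeks, tab$week), ]
    sharp <- vapply(c("Is", "Ir"), function(stat) {
      v <- tab[[stat]]
      spread <- max(v) - min(v)
      if (spread == 0) return(0)
      ti <- match(targetWeek, weeks)
      (v[ti] - max(v[-ti])) / spread
    }, 0)
    cbind(grid[i, ], nStar = length(genes), sharpness = min(sharp))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$sharpness, out$theta1, out$theta2, out$theta3,
                   na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Leave-one-out reproducibility of the DNB selection
#'
#' Drops each sample of the case slice and each sample of the control slice
#' in turn, re-runs the full selection on the remaining samples, and
#' records the overlap of each re-selected set with `reference`. Reports
#' the mean overlap and its standard error over all drops.
#'
#' @param x a [DNBExperiment-class]; both slices need >= 4 samples so that
#'   every reduced slice keeps >= 3.
#' @param caseWeek,controlWeek slices entering the selection.
#' @param thetas threshold triple.
#' @param reference gene set to compare against (defaults to the selection
#'   on the full data).
#' @return list with `overlaps` (named integer vector, one per dropped
#'   sample), `mean`, `sem`, and `reference`.
#' @export
leaveOneOut <- function(x, caseWeek, controlWeek = caseWeek,
                        thetas = c(10, 50, 80), reference = NULL) {
  X <- conditionSlice(x, caseLabel(x), caseWeek)
  Y <- conditionSlice(x, controlLabel(x), controlWeek)
  if (ncol(X) < 4 || ncol(Y) < 4)
    stop("leave-one-out needs >= 4 samples in each slice")
  if (is.null(reference))
    reference <- dnbGenes(selectDNB(X, Y = Y, thetas = thetas))
  dropRun <- function(Xd, Yd)
    length(intersect(dnbGenes(selectDNB(Xd, Y = Yd, thetas = thetas)),
                     reference))
  ovl <- c(
    vapply(seq_len(ncol(X)), function(k)
      dropRun(X[, -k, drop = FALSE], Y), 0L),
    vapply(seq_len(ncol(Y)), function(k)
      dropRun(X, Y[, -k, drop = FALSE]), 0L))
  names(ovl) <- c(colnames(X), colnames(Y))
  list(overlaps = ovl, mean = mean(ovl),
       sem = stats::sd(ovl) / sqrt(length(ovl)), reference = reference)
}

#' Re-select DNB genes against an alternative control slice
#'
#' Swaps the control group: the selection is repeated with the control slice
#' replaced by another condition (for example the case strain at its first
#' week), and the resulting set is compared with `reference` by overlap size
#' and a classic one-tailed Fisher's exact test (hypergeometric upper tail)
#' on the gene universe.
#'
#' @param x a [DNBExperiment-class].
#' @param caseWeek week of the case slice.
#' @param altGroup,altWeek the alternative control condition.
#' @param thetas threshold triple.
#' @param reference gene set to compare against (defaults to the selection
#'   with the original control at `caseWeek`).
#' @return list with `selection` (the alternative [DNBSelection-class]),
#'   `overlap`, `p` (Fisher one-tailed), and `reference`.
#' @export
controlSwap <- function(x, caseWeek, altGroup, altWeek,
                        thetas = c(10, 50, 80), reference = NULL) {
  if (is.null(reference))
    reference <- dnbGenes(selectDNB(x, caseWeek = caseWeek, thetas = thetas))
  X <- conditionSlice(x, caseLabel(x), caseWeek)
  Yalt <- conditionSlice(x, altGroup, altWeek)
  sel <- selectDNB(X, Y = Yalt, thetas = thetas)
  ov <- length(intersect(dnbGenes(sel), reference))
  p <- fisherP(N = nrow(x), n1 = length(reference),
               n2 = length(dnbGenes(sel)), x = ov)
  list(selection = sel, overlap = ov, p = p, reference = reference)
}

#' Relative recovery rate from the largest covariance eigenvalue
#'
#' Near a critical transition the recovery rate from perturbations falls
#' (critical slowing down); it is approximately inversely proportional to
#' the largest eigenvalue of the sample covariance matrix of the DNB genes.
#' This returns `1 / lambda_max` for one condition slice, on an arbitrary
#' common scale.
#'
#' @param Z genes-by-samples matrix of one condition slice (>= 2 samples).
#' @param genes candidate gene ids (>= 2).
#' @return positive scalar.
#' @export
relativeRecoveryRate <- function(Z, genes) {
  stopifnot(length(genes) >= 2, ncol(Z) >= 2)
  cv <- cov(t(Z[genes, , drop = FALSE]))
  1 / max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
}

#' Relative recovery rate across all conditions
#'
#' @param x a [DNBExperiment-class].
#' @param genes candidate gene ids.
#' @return data.frame with columns `group`, `week`, `rate`.
#' @export
recoveryRateSeries <- function(x, genes) {
  ct <- conditionTable(x)
  ct$rate <- vapply(seq_len(nrow(ct)), function(i)
    relativeRecoveryRate(conditionSlice(x, ct$group[i], ct$week[i]), genes),
    0)
  ct
}
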