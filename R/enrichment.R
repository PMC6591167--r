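#' One-tailed Fisher (hypergeometric) overlap p-value
#'
#' Probability of observing an overlap of at least `x` genes between a
#' target set of size `n1` and a known set of size `n2` drawn from a
#' universe of `N` genes: the upper tail of the hypergeometric
#' distribution, `P(K >= x)` with `K ~ Hypergeometric(N, n1, n2)`.
#'
#' @param N universe size.
#' @param n1 target-set size.
#' @param n2 known-set size.
#' @param x observed overlap, `0 <= x <= min(n1, n2)`.
#' @return p-value in \[0, 1\]; `x = 0` gives 1.
#' @export
fisherP <- function(N, n1, n2, x) {
  stopifnot(n1 <= N, n2 <= N, x >= 0, x <= min(n1, n2))
  if (x == 0) return(1)
  phyper(x - 1, m = n1, n = N - n1, k = n2, lower.tail = FALSE)
}

#' Conservative (DAVID-style) Fisher p-value
#'
#' The modified one-tailed test in which the observed overlap `x` and the
#' target size `n1` are replaced by `x - 1` and `n1 - 1`. The substitution
#' discounts one overlapping gene, making the test strictly more
#' conservative (`p_modified >= p_classic` whenever `x >= 1`) and
#' suppressing false positives for small overlaps; `x = 0` (and `x = 1`,
#' whose substituted overlap is 0) give p = 1.
#'
#' @inheritParams fisherP
#' @return p-value in \[0, 1\].
#' @export
fisherPModified <- function(N, n1, n2, x) {
  if (x == 0) return(1)
  fisherP(N, n1 - 1, n2, x - 1)
}

#' Rank gene-set overlaps with a target set
#'
#' Computes the conservative overlap p-value of the target set against every
#' collection set (members intersected with the universe), keeps sets with
#' `p <= pMax` and overlap `x >= minOverlap`, and ranks the survivors by
#' overlap size descending (ties: p ascending, then set name). The top
#' `topN` records are returned. No multiple-testing correction is applied;
#' the filter is exploratory by design.
#'
#' @param target character vector of gene ids (must lie in the universe).
#' @param collection named list of gene sets, e.g. from [readGMT()].
#' @param universe either the character vector of universe gene ids (used
#'   to clip collection sets) or a single integer universe size.
#' @param pMax,minOverlap filtering rules (defaults 0.05 and 2).
#' @param topN number of records reported (default 10).
#' @return data.frame with columns `set`, `N`, `n1`, `n2`, `x`,
#'   `pClassic`, `pModified`, `rank`; zero rows if nothing passes.
#' @examples
#' sets <- list(hit = paste0("g", 1:40), other = paste0("g", 900:950))
#' enrichGeneSets(paste0("g", 1:50), sets, universe = 2000)
#' @export
enrichGeneSets <- function(target, collection, universe,
                           pMax = 0.05, minOverlap = 2, topN = 10) {
  if (is.character(universe)) {
    N <- length(universe)
    if (!all(target %in% universe))
      stop("target genes must be contained in the universe")
    collection <- lapply(collection, intersect, universe)
  } else {
    N <- as.integer(universe)
  }
  target <- unique(target)
  n1 <- length(target)
  if (n1 == 0 || length(collection) == 0)
    return(emptyEnrichment())
  rows <- lapply(names(collection), function(nm) {
    set <- unique(collection[[nm]])
    n2 <- length(set)
    ov <- length(intersect(target, set))
    if (n2 == 0 || n2 > N) return(NULL)
    data.frame(set = nm, N = N, n1 = n1, n2 = n2, x = ov,
               pClassic = fisherP(N, n1, n2, ov),
               pModified = fisherPModified(N, n1, n2, ov),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(emptyEnrichment())
  tab <- tab[tab$pModified <= pMax & tab$x >= minOverlap, , drop = FALSE]
  if (!nrow(tab)) return(emptyEnrichment())
  tab <- tab[order(-tab$x, tab$pModified, tab$set), , drop = FALSE]
  tab <- head(tab, topN)
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

emptyEnrichment <- function() {
  data.frame(set = character(), N = integer(), n1 = integer(),
             n2 = integer(), x = integer(), pClassic = numeric(),
             pModified = numeric(), rank = integer(),
             stringsAsFactors = FALSE)
}
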