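#' Construct a DNBExperiment
#'
#' Wraps a log2-normalized genes-by-samples matrix and its sample annotation
#' into the container used by all downstream analyses.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames = sample ids).
#' @param group character/factor of length `ncol(values)`; the strain or
#'   treatment group of each sample.
#' @param week character/factor of length `ncol(values)`; the time-point
#'   label of each sample. The order of time points is taken from
#'   `weekLevels` (default: order of first appearance).
#' @param caseLabel,controlLabel which group labels play the roles of case
#'   and control in two-group contrasts.
#' @param weekLevels optional ordered vector of time-point labels.
#'
#' @return A [DNBExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' x <- DNBExperiment(m, group = rep(c("case", "control"), each = 5),
#'                    week = rep(c("wk1", "wk2"), 5))
#' x
#' @export
DNBExperiment <- function(values, group, week,
                          caseLabel = "case", controlLabel = "control",
                          weekLevels = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  if (is.null(weekLevels)) weekLevels <- unique(as.character(week))
  cd <- DataFrame(group = as.character(group), week = as.character(week),
                  row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
  metadata(se) <- list(caseLabel = caseLabel, controlLabel = controlLabel,
                       weekLevels = weekLevels)
  new("DNBExperiment", se)
}

#' Construct a ProbeExperiment
#'
#' @param intensity non-negative probe-by-sample raw intensity matrix with
#'   unique probe-id rownames.
#' @param annotation data.frame with columns `probe_id` and `gene_symbol`
#'   (empty string or `NA` = unannotated probe).
#' @param group,week per-sample labels as in [DNBExperiment()].
#' @param caseLabel,controlLabel,weekLevels as in [DNBExperiment()].
#' @return A [ProbeExperiment-class] object.
#' @export
ProbeExperiment <- function(intensity, annotation, group, week,
                            caseLabel = "case", controlLabel = "control",
                            weekLevels = NULL) {
  intensity <- as.matrix(intensity)
  sym <- setNames(as.character(annotation$gene_symbol),
                  as.character(annotation$probe_id))
  miss <- setdiff(rownames(intensity), names(sym))
  if (length(miss))
    stop("annotation missing for probes: ", paste(head(miss), collapse = ", "))
  if (is.null(weekLevels)) weekLevels <- unique(as.character(week))
  cd <- DataFrame(group = as.character(group), week = as.character(week),
                  row.names = colnames(intensity))
  rd <- DataFrame(gene_symbol = unname(sym[rownames(intensity)]),
                  row.names = rownames(intensity))
  se <- SummarizedExperiment(assays = list(intensity = intensity),
                             colData = cd, rowData = rd)
  metadata(se) <- list(caseLabel = caseLabel, controlLabel = controlLabel,
                       weekLevels = weekLevels)
  new("ProbeExperiment", se)
}

#' Accessors for expression containers
#'
#' @param x a [DNBExperiment-class] or [ProbeExperiment-class] object.
#' @return `exprs()` the log2 expression matrix; `sampleGroups()` /
#'   `sampleWeeks()` per-sample labels; `caseLabel()` / `controlLabel()` the
#'   contrast roles; `weekLevels()` the ordered time-point labels.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("exprs", "DNBExperiment", function(x) assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("caseLabel", "SummarizedExperiment",
          function(x) metadata(x)$caseLabel)

#' @rdname accessors
#' @export
setMethod("controlLabel", "SummarizedExperiment",
          function(x) metadata(x)$controlLabel)

#' @rdname accessors
#' @export
setMethod("sampleGroups", "SummarizedExperiment",
          function(x) colData(x)$group)

#' @rdname accessors
#' @export
setMethod("sampleWeeks", "SummarizedExperiment",
          function(x) colData(x)$week)

#' @rdname accessors
#' @export
setMethod("weekLevels", "SummarizedExperiment", function(x) {
  wl <- metadata(x)$weekLevels
  if (is.null(wl)) unique(colData(x)$week) else wl
})

#' Extract the expression submatrix of one (group, week) condition
#'
#' Condition slices are the unit of all DNB statistics: the case slice X, the
#' control slice Y, and each scored slice Z are submatrices of samples
#' sharing one (group, week) label.
#'
#' @param x a [DNBExperiment-class].
#' @param group,week condition labels.
#' @param ... unused.
#' @return A genes-by-samples numeric matrix.
#' @export
setMethod("conditionSlice", "DNBExperiment", function(x, group, week, ...) {
  keep <- sampleGroups(x) == group & sampleWeeks(x) == week
  if (!any(keep))
    stop("no samples for condition (", group, ", ", week, ")")
  assay(x, "exprs")[, keep, drop = FALSE]
})

#' All (group, week) condition pairs present in a dataset
#'
#' @param x a [DNBExperiment-class].
#' @return data.frame with columns `group`, `week` in week-major order
#'   (weeks in `weekLevels()` order, case group first within each week).
#' @export
conditionTable <- function(x) {
  grps <- unique(c(caseLabel(x), controlLabel(x),
                   unique(sampleGroups(x))))
  grps <- grps[grps %in% sampleGroups(x)]
  out <- expand.grid(group = grps, week = weekLevels(x),
                     stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, c("group", "week")]
  present <- paste(sampleGroups(x), sampleWeeks(x))
  out[paste(out$group, out$week) %in% present, , drop = FALSE]
}

setMethod("show", "DNBExperiment", function(object) {
  cat("DNBExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  groups:", paste(unique(sampleGroups(object)), collapse = ", "),
      "(case =", caseLabel(object), ", control =",
      paste0(controlLabel(object), ")"), "\n")
  cat("  weeks:", paste(weekLevels(object), collapse = ", "), "\n")
})

setMethod("show", "ProbeExperiment", function(object) {
  sym <- rowData(object)$gene_symbol
  n_un <- sum(is.na(sym) | sym == "")
  cat("ProbeExperiment:", nrow(object), "probes x", ncol(object),
      "samples (", n_un, "unannotated )\n")
})
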