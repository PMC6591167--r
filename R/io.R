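#' Read an expression matrix with sample metadata
#'
#' Expects the standard tab-delimited genes-by-samples matrix (first column
#' gene ids, header sample ids) and a sample metadata CSV with columns
#' `sample_id`, `group`, `week`.
#'
#' @param valuesPath path to the expression TSV.
#' @param metaPath path to the metadata CSV.
#' @param caseLabel,controlLabel contrast roles; defaults take the first two
#'   distinct groups in the metadata as case and control respectively.
#' @return A [DNBExperiment-class].
#' @export
readExpressionData <- function(valuesPath, metaPath,
                               caseLabel = NULL, controlLabel = NULL) {
  m <- as.matrix(read.delim(valuesPath, row.names = 1, check.names = FALSE))
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "week")
  if (!all(need %in% colnames(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  miss <- setdiff(colnames(m), meta$sample_id)
  if (length(miss))
    stop("samples missing from metadata: ", paste(head(miss), collapse = ", "))
  meta <- meta[match(colnames(m), meta$sample_id), ]
  grps <- unique(meta$group)
  DNBExperiment(m, group = meta$group, week = meta$week,
                caseLabel = caseLabel %||% grps[1],
                controlLabel = controlLabel %||% grps[min(2, length(grps))])
}

#' Read probe-level intensities with annotation and metadata
#'
#' @param valuesPath probe-by-sample intensity TSV (first column probe ids).
#' @param annotationPath TSV with columns `probe_id`, `gene_symbol` (empty
#'   symbol = unannotated).
#' @param metaPath sample metadata CSV (`sample_id`, `group`, `week`).
#' @param caseLabel,controlLabel as in [readExpressionData()].
#' @return A [ProbeExperiment-class].
#' @export
readProbeData <- function(valuesPath, annotationPath, metaPath,
                          caseLabel = NULL, controlLabel = NULL) {
  m <- as.matrix(read.delim(valuesPath, row.names = 1, check.names = FALSE))
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE,
                    colClasses = "character")
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  grps <- unique(meta$group)
  ann$gene_symbol[is.na(ann$gene_symbol)] <- ""
  ProbeExperiment(m, annotation = ann, group = meta$group, week = meta$week,
                  caseLabel = caseLabel %||% grps[1],
                  controlLabel = controlLabel %||% grps[min(2, length(grps))])
}

#' Write an expression dataset as TSV + metadata CSV
#'
#' @param x a [DNBExperiment-class].
#' @param valuesPath,metaPath output paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionData <- function(x, valuesPath, metaPath) {
  df <- data.frame(gene_id = rownames(x), exprs(x), check.names = FALSE)
  write.table(df, valuesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(x), group = sampleGroups(x),
                     week = sampleWeeks(x))
  utils::write.csv(meta, metaPath, row.names = FALSE, quote = FALSE)
  invisible(c(valuesPath, metaPath))
}

#' Minimal reader for the GEO series-matrix text format
#'
#' Parses the plain-text series-matrix layout: `!`-prefixed header lines and
#' the expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Mapping of GEO sample characteristics to
#' (group, week) labels is dataset-specific, so the values and the header
#' fields are returned for the caller to assemble via [DNBExperiment()] or
#' [ProbeExperiment()].
#'
#' @param path path to an (uncompressed) series-matrix file.
#' @return list with `values` (numeric matrix, feature ids x GSM ids) and
#'   `sampleInfo` (data.frame of header fields, one row per field).
#' @export
readSeriesMatrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1 || length(end) != 1 || end <= beg)
    stop("not a series-matrix file (table markers missing): ", path)
  tab <- read.delim(text = lines[(beg + 1):(end - 1)], row.names = 1,
                    check.names = FALSE)
  hdr <- lines[startsWith(lines, "!")]
  hdr <- hdr[!grepl("series_matrix_table", hdr)]
  parts <- strsplit(sub("^!", "", hdr), "\t")
  sampleInfo <- data.frame(
    field = vapply(parts, `[`, "", 1),
    value = vapply(parts, function(p) paste(gsub("\"", "", p[-1]),
                                            collapse = "\t"), ""),
    stringsAsFactors = FALSE)
  list(values = as.matrix(tab), sampleInfo = sampleInfo)
}

#' Read gene-set collections in GMT format
#'
#' One set per line: set name, description, then member genes,
#' tab-separated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (unique members per set).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line(s): ", paste(head(bad), collapse = ", "))
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[`, "", 1))
}
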