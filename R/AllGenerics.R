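#' @rdname conditionSlice
#' @export
setGeneric("conditionSlice", function(x, group, week, ...)
  standardGeneric("conditionSlice"))

#' @rdname selectDNB
#' @export
setGeneric("selectDNB", function(x, ...) standardGeneric("selectDNB"))

#' @rdname scoreSeries
#' @export
setGeneric("scoreSeries", function(x, genes, ...)
  standardGeneric("scoreSeries"))

#' @rdname accessors
#' @export
setGeneric("caseLabel", function(x) standardGeneric("caseLabel"))

#' @rdname accessors
#' @export
setGeneric("controlLabel", function(x) standardGeneric("controlLabel"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("sampleWeeks", function(x) standardGeneric("sampleWeeks"))

#' @rdname accessors
#' @export
setGeneric("weekLevels", function(x) standardGeneric("weekLevels"))

#' @rdname accessors
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))

#' @rdname DNBSelection-accessors
#' @export
setGeneric("dnbGenes", function(x) standardGeneric("dnbGenes"))

#' @rdname DNBScoreSeries-accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname DEGResult-accessors
#' @export
setGeneric("degSets", function(x) standardGeneric("degSets"))

#' @rdname DEGResult-accessors
#' @export
setGeneric("degUnion", function(x) standardGeneric("degUnion"))

#' @rdname DEGResult-accessors
#' @export
setGeneric("degIncidence", function(x) standardGeneric("degIncidence"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname PCAResult-accessors
#' @export
setGeneric("nMeaningful", function(x) standardGeneric("nMeaningful"))
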