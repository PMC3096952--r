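#' @rdname SurvivalCohort
#' @param x A SurvivalCohort (or other object with the accessor defined).
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname SurvivalCohort
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' @rdname SurvivalCohort
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname SurvivalCohort
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname SurvivalCohort
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))

#' @rdname CVSummary-accessors
#' @param object A [CVSummary-class].
#' @export
setGeneric("reducedScores", function(object) standardGeneric("reducedScores"))

#' @rdname CVSummary-accessors
#' @export
setGeneric("fullScores", function(object) standardGeneric("fullScores"))

#' @rdname CVSummary-accessors
#' @export
setGeneric("finalModel", function(object) standardGeneric("finalModel"))

#' @rdname CVSummary-accessors
#' @export
setGeneric("stabilityTable", function(object) standardGeneric("stabilityTable"))

#' @rdname CVSummary-accessors
#' @export
setGeneric("outerRecords", function(object) standardGeneric("outerRecords"))

#' @rdname CVSummary-accessors
#' @export
setGeneric("innerRecords", function(object) standardGeneric("innerRecords"))
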