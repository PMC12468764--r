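#' @rdname zMatrix
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname connectionLabels
#' @export
setGeneric("connectionLabels", function(x) standardGeneric("connectionLabels"))

#' @rdname subjectIds
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname siteCode
#' @export
setGeneric("siteCode", function(x) standardGeneric("siteCode"))

#' @rdname designX
#' @export
setGeneric("designX", function(x) standardGeneric("designX"))

#' @rdname designX
#' @export
setGeneric("designY", function(x) standardGeneric("designY"))

#' @rdname bootstrap-accessors
#' @export
setGeneric("coefDraws", function(x) standardGeneric("coefDraws"))

#' @rdname bootstrap-accessors
#' @export
setGeneric("meanCoef", function(x) standardGeneric("meanCoef"))

#' @rdname bootstrap-accessors
#' @export
setGeneric("sdCoef", function(x) standardGeneric("sdCoef"))

#' @rdname bootstrap-accessors
#' @export
setGeneric("selectionCount", function(x) standardGeneric("selectionCount"))

#' @rdname bootstrap-accessors
#' @export
setGeneric("avgLambda", function(x) standardGeneric("avgLambda"))

#' @rdname report-accessors
#' @export
setGeneric("stableSet", function(x) standardGeneric("stableSet"))

#' @rdname report-accessors
#' @export
setGeneric("cutoffIndex", function(x) standardGeneric("cutoffIndex"))
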