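#' Subject-by-connection Fisher-z matrix
#'
#' @param x a [ConnectivityExperiment-class].
#' @return `zMatrix` returns the subject x connection numeric matrix (the
#'   transpose of the internal connections-x-subjects assay).
#' @export
#' @rdname zMatrix
setMethod("zMatrix", "ConnectivityExperiment", function(x)
  t(SummarizedExperiment::assay(x, "z")))

#' Connection labels
#'
#' @param x a [ConnectivityExperiment-class].
#' @return character vector of connection labels, in predictor order.
#' @export
#' @rdname connectionLabels
setMethod("connectionLabels", "ConnectivityExperiment", function(x)
  rownames(x))

#' Subject identifiers
#'
#' @param x a [ConnectivityExperiment-class].
#' @return character vector of subject ids.
#' @export
#' @rdname subjectIds
setMethod("subjectIds", "ConnectivityExperiment", function(x) colnames(x))

#' Binary scanner-site code
#'
#' @param x a [ConnectivityExperiment-class].
#' @return named integer vector (1 = MGH, 0 = BU), or `NULL` if no site
#'   covariate was recorded.
#' @export
#' @rdname siteCode
setMethod("siteCode", "ConnectivityExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"site" %in% colnames(cd)) return(NULL)
  stats::setNames(as.integer(cd$site), colnames(x))
})

#' Design matrix components
#'
#' @param x a [DesignMatrix-class].
#' @return `designX` the predictor matrix; `designY` the outcome vector.
#' @export
#' @rdname designX
setMethod("designX", "DesignMatrix", function(x) x@X)

#' @export
#' @rdname designX
setMethod("designY", "DesignMatrix", function(x) x@y)

#' Bootstrap-result accessors
#'
#' @param x a [BootstrapResult-class].
#' @return `coefDraws` the B x predictor coefficient matrix; `meanCoef` /
#'   `sdCoef` per-predictor mean and SD across draws (zeros included, n-1
#'   denominator); `selectionCount` per-predictor nonzero-draw counts;
#'   `avgLambda` the mean cross-validated optimal lambda over
#'   non-degenerate draws.
#' @name bootstrap-accessors
#' @export
setMethod("coefDraws", "BootstrapResult", function(x) x@coefDraws)

#' @rdname bootstrap-accessors
#' @export
setMethod("meanCoef", "BootstrapResult", function(x) x@meanCoef)

#' @rdname bootstrap-accessors
#' @export
setMethod("sdCoef", "BootstrapResult", function(x) x@sdCoef)

#' @rdname bootstrap-accessors
#' @export
setMethod("selectionCount", "BootstrapResult", function(x) x@selectionCount)

#' @rdname bootstrap-accessors
#' @export
setMethod("avgLambda", "BootstrapResult", function(x) x@avgLambda)

#' Selection-report accessors
#'
#' @param x a [SelectionReport-class].
#' @return `stableSet` the labels of the stable predictors (rank order);
#'   `cutoffIndex` the first-drop cutoff rank (0 when no drop exists).
#' @name report-accessors
#' @export
setMethod("stableSet", "SelectionReport", function(x) x@stableSet)

#' @rdname report-accessors
#' @export
setMethod("cutoffIndex", "SelectionReport", function(x) x@cutoffIndex)

#' @rdname report-accessors
#' @export
setMethod("avgLambda", "SelectionReport", function(x) x@avgLambda)

#' @describeIn SelectionReport-class per-predictor results table (original
#'   design order).
#' @param x a SelectionReport.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @export
setMethod("as.data.frame", "SelectionReport",
  function(x, row.names = NULL, optional = FALSE, ...) x@results)

setMethod("show", "ConnectivityExperiment", function(object) {
  cat("ConnectivityExperiment:", ncol(object), "subjects x",
      nrow(object), "connections\n")
  s <- siteCode(object)
  if (!is.null(s))
    cat("  site: ", sum(s == 1L), " MGH / ", sum(s == 0L), " BU\n", sep = "")
  z <- SummarizedExperiment::assay(object, "z")
  cat(sprintf("  z range: [%.3f, %.3f]\n", min(z), max(z)))
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@X), "subjects x", ncol(object@X),
      "predictors (site column", object@siteColumnIndex, ")\n")
  cat("  outcome:", object@outcome, "; mean", round(mean(object@y), 3), "\n")
})

setMethod("show", "LassoFit", function(object) {
  cat(sprintf("LassoFit: lambda = %.6g, %d nonzero of %d predictors%s\n",
              object@lambda, object@nNonzero, length(object@coefficients),
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "BootstrapResult", function(object) {
  B <- nrow(object@coefDraws)
  cat("BootstrapResult:", B, "draws x", ncol(object@coefDraws),
      "predictors\n")
  cat(sprintf("  avg optimal lambda: %.4g; degenerate draws: %d\n",
              object@avgLambda, object@nDegenerate))
  top <- sort(object@selectionCount, decreasing = TRUE)[1:min(3, length(object@selectionCount))]
  cat("  most selected:",
      paste(sprintf("%s (%d/%d)", names(top), top, B), collapse = ", "), "\n")
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport (", object@outcome, "): ", nrow(object@results),
      " predictors, B = ", object@B, "\n", sep = "")
  cat(sprintf("  %d significant at adjusted %.0f%% CI (m = %g)\n",
              sum(object@results$significant), 100 * object@ciLevel,
              object@bonferroniM))
  cat("  stable set (first-drop cutoff ", object@cutoffIndex, "): ",
      if (object@cutoffIndex == 0L) "<empty>"
      else paste(object@stableSet, collapse = ", "), "\n", sep = "")
})
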