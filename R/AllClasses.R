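#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData assayNames
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Container for subject-by-connection Fisher-z functional connectivity
#'
#' `ConnectivityExperiment` stores a matrix of Fisher-transformed ROI-to-ROI
#' temporal correlations, one row per connection and one column per subject,
#' as a [SummarizedExperiment::SummarizedExperiment] with a single `"z"`
#' assay. Subject-level covariates (at minimum the binary scanner-site code)
#' live in `colData`.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [ConnectivityExperiment()], [buildConnectivityTable()],
#'   [zMatrix()], [siteCode()]
#' @export
setClass("ConnectivityExperiment", contains = "SummarizedExperiment")

setValidity("ConnectivityExperiment", function(object) {
  msg <- NULL
  if (!"z" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'z' is required")
  else {
    z <- SummarizedExperiment::assay(object, "z")
    if (!is.numeric(z)) msg <- c(msg, "assay 'z' must be numeric")
    else if (any(!is.finite(z))) msg <- c(msg, "assay 'z' contains non-finite values")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "connection labels (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "subject ids (colnames) must be present and unique")
  if ("site" %in% colnames(SummarizedExperiment::colData(object))) {
    s <- SummarizedExperiment::colData(object)$site
    if (!all(s %in% c(0L, 1L)))
      msg <- c(msg, "colData$site must be binary (1 = MGH, 0 = BU)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ConnectivityExperiment
#'
#' @param z numeric subject x connection matrix of Fisher-z coefficients
#'   (rownames = subject ids, colnames = connection labels).
#' @param site optional binary site code per subject (1 = MGH, 0 = BU), or a
#'   character vector of `"MGH"`/`"BU"` labels.
#' @param subjectData optional data.frame of additional per-subject columns.
#'
#' @return a [ConnectivityExperiment-class] object (connections x subjects).
#' @examples
#' z <- matrix(rnorm(6, 0.4, 0.3), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("A--B", "A--C", "B--C")))
#' ConnectivityExperiment(z, site = c(1, 0))
#' @export
ConnectivityExperiment <- function(z, site = NULL, subjectData = NULL) {
  z <- as.matrix(z)
  if (is.null(rownames(z)))
    rownames(z) <- sprintf("S%02d", seq_len(nrow(z)))
  if (is.null(colnames(z)))
    stop("connectivity matrix must have connection labels as colnames")
  cd <- S4Vectors::DataFrame(row.names = rownames(z))
  if (!is.null(site)) {
    if (is.character(site) || is.factor(site)) site <- siteBinary(site)
    cd$site <- as.integer(site)
  }
  if (!is.null(subjectData)) {
    subjectData <- as.data.frame(subjectData)
    for (nm in setdiff(colnames(subjectData), "site"))
      cd[[nm]] <- subjectData[[nm]]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = t(z)), colData = cd)
  methods::new("ConnectivityExperiment", se)
}

#' Design matrix pairing connectivity predictors with one disfluency outcome
#'
#' Rows are subjects (sorted by subject id); columns are the Fisher-z
#' connections in the order of the connection list, followed by a final
#' binary scanner-site column. `y` holds the chosen disfluency percentage.
#'
#' @slot X numeric subject x (connections + 1) matrix.
#' @slot y numeric outcome vector, aligned with rows of `X`.
#' @slot siteColumnIndex integer index of the site column in `X`.
#' @slot outcome character; which disfluency type `y` is.
#' @seealso [assembleDesign()], [designX()], [designY()]
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", y = "numeric",
                 siteColumnIndex = "integer", outcome = "character"))

setValidity("DesignMatrix", function(object) {
  msg <- NULL
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "nrow(X) must equal length(y)")
  if (is.null(colnames(object@X)))
    msg <- c(msg, "X must have column labels")
  if (any(!is.finite(object@X)) || any(!is.finite(object@y)))
    msg <- c(msg, "X and y must be finite")
  k <- object@siteColumnIndex
  if (length(k) != 1L || k < 1L || k > ncol(object@X))
    msg <- c(msg, "siteColumnIndex out of range")
  else if (!all(object@X[, k] %in% c(0, 1)))
    msg <- c(msg, "site column must be binary {0,1}")
  if (is.null(msg)) TRUE else msg
})

#' A single L1-penalized linear fit
#'
#' @slot intercept numeric unpenalized intercept.
#' @slot coefficients named numeric vector on the original predictor scale.
#' @slot lambda numeric penalty at which the fit was computed.
#' @slot nNonzero integer count of exactly nonzero coefficients.
#' @slot converged logical; coordinate descent converged within `maxIter`.
#' @seealso [lassoFit()]
#' @export
setClass("LassoFit",
  representation(intercept = "numeric", coefficients = "numeric",
                 lambda = "numeric", nNonzero = "integer",
                 converged = "logical"))

setValidity("LassoFit", function(object) {
  msg <- NULL
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@nNonzero != sum(object@coefficients != 0))
    msg <- c(msg, "nNonzero inconsistent with coefficients")
  if (is.null(names(object@coefficients)))
    msg <- c(msg, "coefficients must be named")
  if (is.null(msg)) TRUE else msg
})

#' Aggregated results of a paired-bootstrap cross-validated LASSO run
#'
#' Holds the B x predictor matrix of raw (original-scale) LASSO coefficients,
#' one row per bootstrap resample, together with per-predictor aggregates.
#' Degenerate resamples (constant outcome) contribute an all-zero row and an
#' `NA` lambda draw.
#'
#' @slot coefDraws numeric B x p matrix of per-iteration coefficients.
#' @slot lambdaDraws numeric length-B vector of per-iteration optimal lambda.
#' @slot meanCoef,sdCoef named per-predictor mean and SD (n-1 denominator)
#'   across draws, zeros included.
#' @slot selectionCount named integer count of draws in which each predictor
#'   was exactly nonzero.
#' @slot avgLambda numeric mean optimal lambda over non-degenerate draws.
#' @slot nDegenerate integer count of degenerate resamples.
#' @slot seed integer base seed of the run.
#' @seealso [runBootstrap()], [selectionReport()]
#' @export
setClass("BootstrapResult",
  representation(coefDraws = "matrix", lambdaDraws = "numeric",
                 meanCoef = "numeric", sdCoef = "numeric",
                 selectionCount = "integer", avgLambda = "numeric",
                 nDegenerate = "integer", seed = "integer"))

setValidity("BootstrapResult", function(object) {
  msg <- NULL
  B <- nrow(object@coefDraws)
  p <- ncol(object@coefDraws)
  if (is.null(colnames(object@coefDraws)))
    msg <- c(msg, "coefDraws must have predictor labels as colnames")
  if (length(object@meanCoef) != p || length(object@sdCoef) != p ||
      length(object@selectionCount) != p)
    msg <- c(msg, "aggregate lengths must match ncol(coefDraws)")
  if (length(object@lambdaDraws) != B)
    msg <- c(msg, "lambdaDraws must have one entry per draw")
  if (any(object@sdCoef < 0)) msg <- c(msg, "sdCoef must be non-negative")
  if (any(object@selectionCount < 0L) || any(object@selectionCount > B))
    msg <- c(msg, "selectionCount must lie in [0, B]")
  if (length(object@avgLambda) == 1L && is.finite(object@avgLambda) &&
      object@avgLambda < 0)
    msg <- c(msg, "avgLambda must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Per-predictor inference and stability-selection report
#'
#' One row per predictor (original design order) with bootstrap-SE
#' confidence intervals, Bonferroni-adjusted significance flags, selection
#' counts, the stability rank, and stable-set membership; plus the
#' first-drop cutoff index and the stable set itself.
#'
#' @slot results data.frame with columns `predictor`, `mean_coef`,
#'   `sd_coef`, `se_mean`, `ci_lower`, `ci_upper`, `significant`,
#'   `selection_count`, `stability_rank`, `in_stable_set`.
#' @slot cutoffIndex integer rank of the last stable predictor (0 = none).
#' @slot stableSet character labels of the stable predictors, in rank order.
#' @slot ciLevel numeric nominal (pre-adjustment) coverage.
#' @slot bonferroniM numeric number of comparisons used for the adjustment.
#' @slot avgLambda numeric mean optimal lambda of the underlying run.
#' @slot B integer number of bootstrap draws.
#' @slot outcome character outcome label.
#' @seealso [selectionReport()], [writeSelectionReport()]
#' @export
setClass("SelectionReport",
  representation(results = "data.frame", cutoffIndex = "integer",
                 stableSet = "character", ciLevel = "numeric",
                 bonferroniM = "numeric", avgLambda = "numeric",
                 B = "integer", outcome = "character"))

setValidity("SelectionReport", function(object) {
  msg <- NULL
  r <- object@results
  need <- c("predictor", "mean_coef", "sd_coef", "ci_lower", "ci_upper",
            "significant", "selection_count", "stability_rank",
            "in_stable_set")
  if (!all(need %in% colnames(r)))
    msg <- c(msg, "results is missing required columns")
  else {
    sig <- r$ci_lower > 0 | r$ci_upper < 0
    if (!identical(as.logical(sig), as.logical(r$significant)))
      msg <- c(msg, "significant flags inconsistent with CI bounds")
    if (length(object@stableSet) != object@cutoffIndex)
      msg <- c(msg, "stableSet length must equal cutoffIndex")
    if (!setequal(object@stableSet, r$predictor[r$in_stable_set]))
      msg <- c(msg, "stableSet inconsistent with in_stable_set flags")
  }
  if (object@ciLevel <= 0 || object@ciLevel >= 1)
    msg <- c(msg, "ciLevel must be in (0, 1)")
  if (is.null(msg)) TRUE else msg
})
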