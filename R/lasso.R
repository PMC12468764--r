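#' Control parameters for the penalized regression core
#'
#' @param nLambda number of penalty values on the regularization path.
#' @param lambdaMinRatio smallest path value as a fraction of the maximal
#'   penalty; default `0.01` when there are fewer rows than columns, else
#'   `1e-4`.
#' @param cvFolds number of cross-validation folds; silently reduced to the
#'   number of rows when the data are smaller.
#' @param standardize center and scale predictors to unit (population)
#'   variance internally; coefficients are always reported on the original
#'   scale.
#' @param penalizeSite whether the binary scanner column is penalized like
#'   any other predictor (default) or left unpenalized.
#' @param maxIter maximum coordinate-descent sweeps per penalty value.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change per sweep (internal scale).
#' @param seed integer seed for fold assignment; `NULL` uses the current
#'   RNG stream.
#' @return a classed list of settings.
#' @export
lassoControl <- function(nLambda = 100L, lambdaMinRatio = NULL,
                         cvFolds = 10L, standardize = TRUE,
                         penalizeSite = TRUE, maxIter = 1e5L,
                         tol = 1e-7, seed = NULL) {
  nLambda <- assertCount(nLambda, "nLambda", 2L)
  cvFolds <- assertCount(cvFolds, "cvFolds", 2L)
  maxIter <- assertCount(maxIter, "maxIter", 1L)
  if (tol <= 0) stop("tol must be positive")
  if (!is.null(lambdaMinRatio) &&
      (lambdaMinRatio <= 0 || lambdaMinRatio >= 1))
    stop("lambdaMinRatio must be in (0, 1)")
  structure(list(nLambda = nLambda, lambdaMinRatio = lambdaMinRatio,
                 cvFolds = cvFolds, standardize = isTRUE(standardize),
                 penalizeSite = isTRUE(penalizeSite), maxIter = maxIter,
                 tol = tol, seed = seed),
            class = "lassoControl")
}

# center (and optionally scale by population SD) the predictors; constant
# columns get scale 1 and colvar 0 so the solver freezes them at zero
prepDesign <- function(X, y, control) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("X and y must be finite numeric")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 2L) stop("need at least 2 observations")
  n <- nrow(X)
  m <- colMeans(X)
  Xc <- sweep(X, 2, m, "-")
  popvar <- colSums(Xc^2) / n
  if (control$standardize) {
    s <- sqrt(popvar)
    s[s == 0] <- 1
    Xs <- sweep(Xc, 2, s, "/")
    colvar <- as.numeric(popvar > 0)
  } else {
    s <- rep(1, ncol(X))
    Xs <- Xc
    colvar <- popvar
  }
  list(Xs = Xs, m = m, s = s, colvar = colvar,
       ymean = mean(y), yc = y - mean(y), n = n)
}

penaltyFactors <- function(p, control, siteColumnIndex = NULL) {
  pf <- rep(1, p)
  if (!control$penalizeSite && !is.null(siteColumnIndex))
    pf[siteColumnIndex] <- 0
  pf
}

lambdaMaxOf <- function(prep, pf) {
  .cd_lambda_max(prep$Xs, prep$yc, pf, prep$colvar)
}

#' Regularization path of penalty values
#'
#' Geometric sequence of `nLambda` values from the smallest penalty that
#' zeroes every coefficient, `lambda_max = max_j |<x_j, y - ybar>| / n` on
#' the internal (standardized) scale, down to
#' `lambda_max * lambdaMinRatio`.
#'
#' @param X design matrix.
#' @param y outcome vector.
#' @param control a [lassoControl()].
#' @param siteColumnIndex optional site column index (affects the path only
#'   when `penalizeSite = FALSE`).
#' @return decreasing numeric vector; a constant outcome yields the
#'   degenerate single-value path `0` with a warning.
#' @export
lambdaPath <- function(X, y, control = lassoControl(),
                       siteColumnIndex = NULL) {
  prep <- prepDesign(X, y, control)
  pf <- penaltyFactors(ncol(prep$Xs), control, siteColumnIndex)
  lmax <- lambdaMaxOf(prep, pf)
  if (lmax == 0) {
    warning("degenerate path: lambda_max is 0 (constant outcome or no ",
            "penalized variation); returning the single value 0")
    return(0)
  }
  ratio <- control$lambdaMinRatio
  if (is.null(ratio)) ratio <- if (nrow(X) < ncol(X)) 0.01 else 1e-4
  exp(seq(log(lmax), log(lmax * ratio), length.out = control$nLambda))
}

# fit the standardized-scale solution along a decreasing lambda sequence
# with warm starts; returns p x nlambda matrix plus convergence flags
fitPathStd <- function(prep, lambda, pf, control) {
  sol <- .cd_lasso_path(prep$Xs, prep$yc, as.numeric(lambda), pf,
                        prep$colvar, control$tol, control$maxIter)
  sol$converged <- as.logical(sol$converged)
  sol
}

unstandardize <- function(bstd, prep) {
  beta <- bstd / prep$s
  names(beta) <- colnames(prep$Xs)
  list(beta = beta, intercept = prep$ymean - sum(beta * prep$m))
}

#' Fit an L1-penalized linear regression at one penalty value
#'
#' Minimizes `(1/(2n)) * sum((y - b0 - X b)^2) + lambda * sum(|b_j|)` by
#' cyclic coordinate descent with soft-thresholding. Predictors are
#' internally centered and (by default) scaled to unit population variance;
#' the intercept is unpenalized and coefficients are reported on the
#' original scale. Constant columns receive coefficient exactly 0.
#'
#' @param X design matrix (or a [DesignMatrix-class], from which `y` and
#'   the site column index are taken).
#' @param y outcome vector (ignored when `X` is a DesignMatrix).
#' @param lambda penalty value, `>= 0`.
#' @param control a [lassoControl()].
#' @param siteColumnIndex optional site column index (used when
#'   `penalizeSite = FALSE`).
#' @return a [LassoFit-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 40, 5)
#' y <- X[, 1] * 2 + rnorm(40, sd = 0.3)
#' lassoFit(X, y, lambda = 0.1)
#' @export
lassoFit <- function(X, y = NULL, lambda, control = lassoControl(),
                     siteColumnIndex = NULL) {
  if (methods::is(X, "DesignMatrix")) {
    siteColumnIndex <- X@siteColumnIndex
    y <- X@y
    X <- X@X
  }
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single value >= 0")
  prep <- prepDesign(X, y, control)
  pf <- penaltyFactors(ncol(prep$Xs), control, siteColumnIndex)
  sol <- fitPathStd(prep, lambda, pf, control)
  ans <- unstandardize(sol$beta[, 1], prep)
  if (!sol$converged[1])
    warning("coordinate descent did not converge within maxIter sweeps")
  methods::new("LassoFit", intercept = ans$intercept,
               coefficients = ans$beta, lambda = lambda,
               nNonzero = as.integer(sum(ans$beta != 0)),
               converged = as.logical(sol$converged[1]))
}

#' Cross-validated selection of the penalty
#'
#' K-fold cross-validation over the shared regularization path of the full
#' data: folds are assigned by a seeded shuffle, each training fit is a
#' warm-started path solve, and the penalty minimizing the mean validation
#' MSE is returned (ties broken toward the larger penalty, i.e. the
#' sparser model). A fold whose training outcome is constant degenerates
#' to an intercept-only prediction but is still scored; if every fold
#' degenerates, an error is raised.
#'
#' @inheritParams lassoFit
#' @return list with `lambdaOpt`, `cvCurve` (data.frame `lambda`,
#'   `mean_mse`, `se_mse`), and `foldId`.
#' @export
cvSelectLambda <- function(X, y = NULL, control = lassoControl(),
                           siteColumnIndex = NULL) {
  if (methods::is(X, "DesignMatrix")) {
    siteColumnIndex <- X@siteColumnIndex
    y <- X@y
    X <- X@X
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("X and y must be finite numeric")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 observations")
  nf <- min(control$cvFolds, n)

  lambda <- suppressWarnings(
    lambdaPath(X, y, control, siteColumnIndex))
  foldId <- withSeedIf(control$seed, {
    sample(rep(seq_len(nf), length.out = n))
  })

  pf <- penaltyFactors(ncol(X), control, siteColumnIndex)
  res <- .cd_lasso_cv(X, as.numeric(y), as.integer(foldId), nf,
                      as.numeric(lambda), pf, control$standardize,
                      control$tol, control$maxIter)
  if (all(res$degenerate))
    stop("all cross-validation folds had a constant training outcome")

  mse <- res$mse
  cvm <- rowMeans(mse)
  cvse <- apply(mse, 1, stats::sd) / sqrt(nf)
  best <- which.min(cvm)  # first index = largest lambda among exact ties
  list(lambdaOpt = lambda[best],
       cvCurve = data.frame(lambda = lambda, mean_mse = cvm,
                            se_mse = cvse),
       foldId = foldId)
}
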