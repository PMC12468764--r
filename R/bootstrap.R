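#' Control parameters for the paired bootstrap
#'
#' @param nBoot number of bootstrap resamples B (default 1000).
#' @param ciLevel nominal confidence-interval coverage before the
#'   Bonferroni adjustment (default 0.95).
#' @param bonferroniM number of comparisons for the Bonferroni adjustment;
#'   `"auto"` uses the number of predictors in the model (connections plus
#'   the site column).
#' @param seed integer base seed; iteration `b` derives its own seed as
#'   `bitwXor(seed, b)` for both the resampling and the fold assignment.
#' @param cutoffRule `"largestDrop"` (first-drop heuristic, default) or
#'   `"fixedThreshold"`.
#' @param threshold selection-frequency threshold in (0, 1], used only by
#'   `"fixedThreshold"`.
#' @param ciType `"normal"` (mean +/- z * bootstrap SD, default) or
#'   `"percentile"`.
#' @return classed list of settings.
#' @export
bootstrapControl <- function(nBoot = 1000L, ciLevel = 0.95,
                             bonferroniM = "auto", seed = 1L,
                             cutoffRule = c("largestDrop",
                                            "fixedThreshold"),
                             threshold = 0.5,
                             ciType = c("normal", "percentile")) {
  nBoot <- assertCount(nBoot, "nBoot", 2L)
  if (ciLevel <= 0 || ciLevel >= 1) stop("ciLevel must be in (0, 1)")
  if (!identical(bonferroniM, "auto")) {
    bonferroniM <- as.numeric(bonferroniM)
    if (!is.finite(bonferroniM) || bonferroniM < 1)
      stop("bonferroniM must be 'auto' or a number >= 1")
  }
  cutoffRule <- match.arg(cutoffRule)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  structure(list(nBoot = nBoot, ciLevel = ciLevel,
                 bonferroniM = bonferroniM, seed = as.integer(seed),
                 cutoffRule = cutoffRule, threshold = threshold,
                 ciType = match.arg(ciType)),
            class = "bootstrapControl")
}

#' Paired bootstrap index vectors
#'
#' Draws `B` resamples of `{1..n}` uniformly with replacement. Predictor
#' rows and outcomes are resampled jointly (the caller indexes both with
#' the same vector), preserving subject pairing. Iteration `b` is seeded
#' with `bitwXor(seed, b)`, so any single iteration can be reproduced in
#' isolation.
#'
#' @param n number of subjects.
#' @param B number of resamples.
#' @param seed integer base seed.
#' @return integer B x n matrix, one resample per row.
#' @export
pairedBootstrapIndices <- function(n, B, seed = 1L) {
  n <- assertCount(n, "n", 2L)
  B <- assertCount(B, "B", 1L)
  idx <- matrix(NA_integer_, B, n)
  for (b in seq_len(B))
    idx[b, ] <- withr::with_seed(iterSeed(seed, b),
                                 sample.int(n, n, replace = TRUE))
  idx
}

#' Paired-bootstrap cross-validated LASSO
#'
#' The central inference engine: for each of `B` paired bootstrap
#' resamples of the subjects, selects the penalty by K-fold
#' cross-validation on the resampled data ([cvSelectLambda()]), fits the
#' LASSO at that penalty, and records the raw original-scale coefficients.
#' Zero coefficients participate in the per-predictor mean and SD.
#' Resamples with a constant outcome are degenerate: they contribute an
#' all-zero coefficient row, are counted, and excluded from the average
#' optimal lambda; more than 50% degenerate draws is an error.
#'
#' @param design a [DesignMatrix-class] (one outcome; call once per
#'   disfluency type).
#' @param lassoCtrl a [lassoControl()]; its `seed` is overridden
#'   per-iteration.
#' @param bootCtrl a [bootstrapControl()].
#' @return a [BootstrapResult-class].
#' @export
runBootstrap <- function(design, lassoCtrl = lassoControl(),
                         bootCtrl = bootstrapControl()) {
  stopifnot(methods::is(design, "DesignMatrix"))
  X <- design@X
  y <- design@y
  n <- nrow(X)
  B <- bootCtrl$nBoot
  p <- ncol(X)
  draws <- matrix(0, B, p, dimnames = list(NULL, colnames(X)))
  lambdas <- rep(NA_real_, B)

  ctrl <- lassoCtrl
  ctrl$seed <- NULL  # fold assignment uses the per-iteration stream below
  nDegen <- 0L
  for (b in seq_len(B)) {
    res <- withr::with_seed(iterSeed(bootCtrl$seed, b), {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      if (stats::sd(yb) == 0) {
        NULL
      } else {
        Xb <- X[idx, , drop = FALSE]
        cv <- cvSelectLambda(Xb, yb, ctrl, design@siteColumnIndex)
        fit <- lassoFit(Xb, yb, cv$lambdaOpt, ctrl,
                        design@siteColumnIndex)
        list(beta = fit@coefficients, lambda = cv$lambdaOpt)
      }
    })
    if (is.null(res)) {
      nDegen <- nDegen + 1L
    } else {
      draws[b, ] <- res$beta
      lambdas[b] <- res$lambda
    }
  }
  if (nDegen > B / 2)
    stop("more than 50% of bootstrap resamples were degenerate ",
         "(constant outcome): ", nDegen, " of ", B)
  if (nDegen > 0L)
    message(nDegen, " degenerate bootstrap resample(s) recorded as ",
            "all-zero coefficient rows")

  methods::new("BootstrapResult",
               coefDraws = draws,
               lambdaDraws = lambdas,
               meanCoef = colMeans(draws),
               sdCoef = apply(draws, 2, stats::sd),
               selectionCount = stats::setNames(
                 as.integer(colSums(draws != 0)), colnames(draws)),
               avgLambda = mean(lambdas, na.rm = TRUE),
               nDegenerate = nDegen,
               seed = bootCtrl$seed)
}

#' Bootstrap-SE confidence intervals with Bonferroni adjustment
#'
#' Normal-approximation intervals `mean_coef +/- z * sd_coef` at the
#' Bonferroni-adjusted level `alpha' = (1 - ciLevel) / m`; a predictor is
#' significant when its interval excludes zero. With
#' `ciType = "percentile"`, adjusted-level percentile intervals of the
#' coefficient draws are used instead.
#'
#' @param result a [BootstrapResult-class].
#' @param bootCtrl a [bootstrapControl()].
#' @return data.frame `predictor`, `mean_coef`, `sd_coef`, `se_mean`
#'   (bootstrap SD / sqrt(B)), `ci_lower`, `ci_upper`, `significant`.
#' @export
coefficientCI <- function(result, bootCtrl = bootstrapControl()) {
  stopifnot(methods::is(result, "BootstrapResult"))
  m <- bootCtrl$bonferroniM
  if (identical(m, "auto")) m <- ncol(result@coefDraws)
  alphaAdj <- (1 - bootCtrl$ciLevel) / m
  if (bootCtrl$ciType == "normal") {
    zq <- stats::qnorm(1 - alphaAdj / 2)
    lo <- result@meanCoef - zq * result@sdCoef
    hi <- result@meanCoef + zq * result@sdCoef
  } else {
    qs <- apply(result@coefDraws, 2, stats::quantile,
                probs = c(alphaAdj / 2, 1 - alphaAdj / 2), names = FALSE)
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  B <- nrow(result@coefDraws)
  data.frame(predictor = colnames(result@coefDraws),
             mean_coef = unname(result@meanCoef),
             sd_coef = unname(result@sdCoef),
             se_mean = unname(result@sdCoef) / sqrt(B),
             ci_lower = unname(lo), ci_upper = unname(hi),
             significant = unname(lo > 0 | hi < 0))
}

#' Stability ranking of predictors
#'
#' Predictors ordered by how often they were selected (exactly nonzero)
#' across the bootstrap draws, descending; ties broken by `|mean_coef|`
#' descending, then label.
#'
#' @param result a [BootstrapResult-class].
#' @return data.frame `predictor`, `selection_count`, `selection_freq`,
#'   `mean_coef`, `stability_rank`, ordered by rank.
#' @export
stabilitySelect <- function(result) {
  stopifnot(methods::is(result, "BootstrapResult"))
  cnt <- result@selectionCount
  ord <- order(-cnt, -abs(result@meanCoef), names(cnt))
  data.frame(predictor = names(cnt)[ord],
             selection_count = as.integer(cnt[ord]),
             selection_freq = as.numeric(cnt[ord]) / nrow(result@coefDraws),
             mean_coef = unname(result@meanCoef[ord]),
             stability_rank = seq_along(ord))
}

#' First-drop cutoff on ranked selection counts
#'
#' Scree-style heuristic: given selection counts sorted non-increasingly,
#' the cutoff is the index `i` maximizing `count_i - count_{i+1}` (the
#' last variable before the largest drop), with ties broken toward the
#' smallest index. When all counts are equal there is no drop; the cutoff
#' is 0 (empty stable set) with a warning.
#'
#' @param sortedCounts non-increasing numeric vector, length >= 2.
#' @return integer cutoff index.
#' @examples
#' firstDropCutoff(c(990, 985, 980, 400, 390))  # 3
#' firstDropCutoff(c(1000, 0))                  # 1
#' @export
firstDropCutoff <- function(sortedCounts) {
  if (length(sortedCounts) < 2L)
    stop("need at least 2 ranked counts")
  if (is.unsorted(rev(sortedCounts)))
    stop("counts must be sorted non-increasingly")
  drops <- sortedCounts[-length(sortedCounts)] - sortedCounts[-1]
  if (all(drops == 0)) {
    warning("all selection counts equal; no drop exists, returning an ",
            "empty stable set (cutoff 0)")
    return(0L)
  }
  as.integer(which.max(drops))
}

#' Build the per-outcome selection report
#'
#' Combines [coefficientCI()], [stabilitySelect()], and the cutoff rule
#' into a single [SelectionReport-class]: per-predictor intervals and
#' significance flags, the stability ranking, the cutoff index, and the
#' stable set (the top-ranked predictors up to the cutoff).
#'
#' @param result a [BootstrapResult-class].
#' @param bootCtrl a [bootstrapControl()].
#' @param outcome outcome label recorded in the report.
#' @return a [SelectionReport-class].
#' @export
selectionReport <- function(result, bootCtrl = bootstrapControl(),
                            outcome = "outcome") {
  ci <- coefficientCI(result, bootCtrl)
  rk <- stabilitySelect(result)
  B <- nrow(result@coefDraws)
  cut <- if (bootCtrl$cutoffRule == "largestDrop") {
    firstDropCutoff(rk$selection_count)
  } else {
    as.integer(sum(rk$selection_freq >= bootCtrl$threshold))
  }
  stable <- if (cut > 0L) rk$predictor[seq_len(cut)] else character(0)

  res <- ci
  res$selection_count <- rk$selection_count[match(res$predictor,
                                                  rk$predictor)]
  res$stability_rank <- rk$stability_rank[match(res$predictor,
                                                rk$predictor)]
  res$in_stable_set <- res$predictor %in% stable

  m <- bootCtrl$bonferroniM
  if (identical(m, "auto")) m <- ncol(result@coefDraws)
  methods::new("SelectionReport", results = res,
               cutoffIndex = cut, stableSet = stable,
               ciLevel = bootCtrl$ciLevel, bonferroniM = as.numeric(m),
               avgLambda = result@avgLambda, B = as.integer(B),
               outcome = outcome)
}

#' Write a selection report CSV
#'
#' One row per predictor with columns `predictor, mean_coef, sd_coef,
#' se_mean, ci_lower, ci_upper, significant, selection_count,
#' stability_rank, in_stable_set`, in the original predictor order.
#'
#' @param report a [SelectionReport-class].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeSelectionReport <- function(report, path) {
  stopifnot(methods::is(report, "SelectionReport"))
  utils::write.csv(report@results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
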