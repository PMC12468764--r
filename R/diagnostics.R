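#' Levene's test for homogeneity of group variances
#'
#' One-way ANOVA F test on the absolute deviations
#' `z_ij = |x_ij - center(group i)|`, with `(k - 1, N - k)` degrees of
#' freedom. `center = "mean"` is the classic Levene test; `"median"` is
#' the Brown-Forsythe variant. Two degenerate situations are handled
#' explicitly: when every absolute deviation is zero (all groups
#' constant), there is no variance anywhere and the statistic is 0 with
#' p = 1; when the deviations have no within-group spread but differ
#' between groups, the F denominator vanishes with a positive numerator
#' and the statistic is `Inf` with p = 0 (both with a warning).
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`; at least 2 groups
#'   with at least 2 observations each.
#' @param center `"mean"` (default) or `"median"`.
#' @return an object of class `"htest"` with the F `statistic`,
#'   `parameter` (df), and `p.value`.
#' @export
leveneTest <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  if (anyNA(values) || anyNA(groups)) stop("missing values not allowed")
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))

  centerFun <- if (center == "mean") mean else stats::median
  ctr <- tapply(values, g, centerFun)
  z <- abs(values - ctr[as.integer(g)])

  N <- length(z)
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ssB <- sum(sizes * (zg - zbar)^2)
  ssW <- sum((z - zg[as.integer(g)])^2)
  df1 <- k - 1L
  df2 <- N - k

  eps <- .Machine$double.eps * max(1, zbar)^2 * N
  if (ssW <= eps) {
    if (ssB <= eps) {
      warning("no variability in absolute deviations; statistic 0, p 1")
      stat <- 0
      p <- 1
    } else {
      warning("zero within-group spread of absolute deviations with ",
              "differing group means; statistic Inf, p 0")
      stat <- Inf
      p <- 0
    }
  } else {
    stat <- (ssB / df1) / (ssW / df2)
    p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
  }
  structure(list(statistic = c(F = stat),
                 parameter = c(df1 = df1, df2 = df2),
                 p.value = p,
                 method = sprintf("Levene's test (%s-centered)", center),
                 data.name = deparse(substitute(values))),
            class = "htest")
}

#' Per-connection site heteroscedasticity screen
#'
#' Runs [leveneTest()] on every connection's Fisher-z values across the
#' two scanner sites. Flags are multiplicity-unadjusted by default,
#' mirroring use as a descriptive diagnostic; the screen's verdict is
#' `"normalization suggested"` iff any connection is flagged after the
#' chosen adjustment.
#'
#' @param ce a [ConnectivityExperiment-class] with a site code.
#' @param alpha flagging level (default 0.05).
#' @param center passed to [leveneTest()].
#' @param adjust p-value adjustment method for the verdict
#'   (`"none"` default; any [stats::p.adjust()] method).
#' @return data.frame `connection, F, df1, df2, p, flag` with attribute
#'   `"verdict"`.
#' @export
siteHeteroscedasticityScreen <- function(ce, alpha = 0.05,
                                         center = c("mean", "median"),
                                         adjust = "none") {
  center <- match.arg(center)
  if (nrow(ce) == 0L) stop("connectivity table has no connections")
  site <- siteCode(ce)
  if (is.null(site)) stop("ConnectivityExperiment carries no site code")
  if (length(unique(site)) < 2L)
    stop("both scanner sites must be represented")

  z <- zMatrix(ce)
  rows <- lapply(colnames(z), function(cl) {
    lt <- leveneTest(z[, cl], site, center)
    data.frame(connection = cl, F = unname(lt$statistic),
               df1 = unname(lt$parameter["df1"]),
               df2 = unname(lt$parameter["df2"]),
               p = lt$p.value)
  })
  out <- do.call(rbind, rows)
  padj <- stats::p.adjust(out$p, method = adjust)
  out$flag <- padj < alpha
  attr(out, "verdict") <- if (any(out$flag))
    "normalization suggested" else "no site heteroscedasticity detected"
  out
}

#' Write the heteroscedasticity screen CSV
#'
#' @param screen output of [siteHeteroscedasticityScreen()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeScreen <- function(screen, path) {
  utils::write.csv(screen, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
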