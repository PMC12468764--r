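# Shared fixture builders for the suite. Everything is generated in code;
# the only on-disk fixtures are the bundled cohort CSVs under extdata.

# design whose centered columns are exactly orthonormal under the
# population inner product <x_j, x_k>/n = delta_jk (columns are orthogonal
# to the constant, hence mean zero), so the lasso solution has the
# closed form beta_j = soft(<x_j, y>/n, lambda)
makeOrthoDesign <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    M <- cbind(1, matrix(rnorm(n * (p + 1)), n))
    Q <- qr.Q(qr(M))[, 2:(p + 1), drop = FALSE]
    X <- Q * sqrt(n)
    colnames(X) <- paste0("x", seq_len(p))
    X
  })
}

softThreshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# KKT residuals of a fit on the standardized scale:
# for zero coefficients |g_j| - lambda must be <= tol; for nonzero ones
# g_j must equal lambda * sign(beta_j) within tol
kktViolation <- function(X, y, fit, control = lassoControl()) {
  prep <- fcLasso:::prepDesign(X, y, control)
  bstd <- fit@coefficients * prep$s
  r <- prep$yc - drop(prep$Xs %*% bstd)
  g <- drop(crossprod(prep$Xs, r)) / prep$n
  viol <- numeric(length(bstd))
  zero <- bstd == 0 & prep$colvar > 0
  viol[zero] <- pmax(abs(g[zero]) - fit@lambda, 0)
  nz <- bstd != 0
  viol[nz] <- abs(g[nz] - fit@lambda * sign(bstd[nz]))
  max(viol)
}

lassoObjective <- function(X, y, intercept, beta, lambda,
                           control = lassoControl()) {
  prep <- fcLasso:::prepDesign(X, y, control)
  bstd <- beta * prep$s
  rss <- sum((prep$yc - drop(prep$Xs %*% bstd))^2)
  rss / (2 * prep$n) + lambda * sum(abs(bstd))
}

# tiny two-ROI time-series cohort for connectivity tests
makeNoiseTimeSeries <- function(nSubjects, rois, nTime, seed = 1) {
  withr::with_seed(seed, {
    ts <- lapply(seq_len(nSubjects), function(i) {
      m <- matrix(rnorm(nTime * length(rois)), nTime)
      colnames(m) <- rois
      m
    })
    names(ts) <- sprintf("S%02d", seq_len(nSubjects))
    ts
  })
}

awsCohortPath <- function() {
  system.file("extdata", "aws_cohort.csv", package = "fcLasso")
}

awsPrintedPath <- function() {
  system.file("extdata", "aws_cohort_printed_percentages.csv",
              package = "fcLasso")
}

# half-up rounding to 2 decimals, the convention of printed tables
round2 <- function(x) floor(x * 100 + 0.5) / 100
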