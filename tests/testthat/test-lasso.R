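test_that("lassoFit with zero penalty reproduces least squares", {
  withr::with_seed(1, {
    X <- matrix(rnorm(50 * 5), 50, 5)
    colnames(X) <- paste0("x", 1:5)
    y <- drop(X %*% c(2, -1, 0, 0.5, 0)) + rnorm(50, sd = 0.3)
  })
  f <- lassoFit(X, y, 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(c(f@intercept, f@coefficients)), unname(ols),
               tolerance = 1e-6)
  expect_true(f@converged)
})

test_that("penalties at or above lambda_max zero every coefficient", {
  withr::with_seed(2, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    colnames(X) <- paste0("x", 1:6)
    y <- rnorm(40)
  })
  path <- lambdaPath(X, y)
  expect_length(path, 100)
  # geometric spacing, decreasing
  expect_equal(diff(log(path)), rep(diff(log(path))[1], 99),
               tolerance = 1e-10)
  f <- lassoFit(X, y, path[1])
  expect_equal(f@nNonzero, 0L)
  f2 <- lassoFit(X, y, path[1] * 2)
  expect_equal(f2@nNonzero, 0L)
  # lambda_max matches its definition on the standardized scale
  prep <- fcLasso:::prepDesign(X, y, lassoControl())
  expect_equal(path[1], max(abs(crossprod(prep$Xs, prep$yc)) / nrow(X)),
               tolerance = 1e-12)
  # three-point path example: {1, 0.1, 0.01} pattern
  p3 <- lambdaPath(X, y, lassoControl(nLambda = 3, lambdaMinRatio = 0.01))
  expect_equal(p3 / p3[1], c(1, 0.1, 0.01), tolerance = 1e-12)
  # constant outcome degenerates with a warning
  expect_warning(p0 <- lambdaPath(X, rep(1, 40)), "degenerate")
  expect_equal(p0, 0)
})

test_that("orthonormal designs reproduce the soft-thresholding closed form", {
  X <- makeOrthoDesign(50, 5, seed = 3)
  withr::with_seed(4, y <- drop(X %*% c(1.5, -1, 0.4, 0, 0)) + rnorm(50))
  zj <- drop(crossprod(X, y - mean(y))) / nrow(X)
  for (lam in exp(seq(log(2), log(0.001), length.out = 20))) {
    f <- lassoFit(X, y, lam)
    expect_equal(unname(f@coefficients), unname(softThreshold(zj, lam)),
                 tolerance = 1e-8)
  }
})

test_that("the single-predictor solution matches the analytic soft threshold", {
  withr::with_seed(5, {
    x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x1"))
    y <- 2 * x[, 1] + rnorm(30, sd = 0.5)
  })
  prep <- fcLasso:::prepDesign(x, y, lassoControl())
  z <- sum(prep$Xs * prep$yc) / 30
  for (lam in c(0, 0.05, 0.4, 2)) {
    f <- lassoFit(x, y, lam)
    expect_equal(unname(f@coefficients),
                 unname(softThreshold(z, lam) / prep$s),
                 tolerance = 1e-8)
  }
})

test_that("solutions satisfy the KKT conditions", {
  worst <- 0
  withr::with_seed(6, {
    for (i in 1:100) {
      n <- sample(20:50, 1)
      p <- sample(5:10, 1)
      X <- matrix(rnorm(n * p), n, p)
      colnames(X) <- paste0("x", 1:p)
      beta <- rnorm(p) * rbinom(p, 1, 0.4)
      y <- drop(X %*% beta) + rnorm(n)
      lam <- runif(1, 0.01, 0.5)
      f <- lassoFit(X, y, lam)
      worst <- max(worst, kktViolation(X, y, f))
    }
  })
  expect_lte(worst, 1e-5)
})

test_that("warm-started path solutions agree with cold starts", {
  withr::with_seed(7, {
    for (i in 1:5) {
      n <- sample(15:30, 1)
      p <- sample(4:10, 1)
      X <- matrix(rnorm(n * p), n, p)
      colnames(X) <- paste0("x", 1:p)
      y <- rnorm(n)
      ctrl <- lassoControl(nLambda = 20)
      lam <- lambdaPath(X, y, ctrl)
      prep <- fcLasso:::prepDesign(X, y, ctrl)
      warm <- fcLasso:::fitPathStd(prep, lam, rep(1, p), ctrl)
      for (l in c(3, 10, 20)) {
        cold <- lassoFit(X, y, lam[l], ctrl)
        expect_equal(unname(cold@coefficients),
                     unname(warm$beta[, l] / prep$s), tolerance = 1e-6)
      }
    }
  })
})

test_that("the objective never increases across coordinate-descent sweeps", {
  withr::with_seed(8, {
    X <- matrix(rnorm(30 * 8), 30, 8)
    colnames(X) <- paste0("x", 1:8)
    y <- rnorm(30)
  })
  ctrl <- lassoControl()
  prep <- fcLasso:::prepDesign(X, y, ctrl)
  lam <- 0.05
  objs <- vapply(1:12, function(k) {
    sol <- fcLasso:::.cd_lasso_path(prep$Xs, prep$yc, lam, rep(1, 8),
                                    prep$colvar, 0, k)  # tol 0: run k sweeps
    b <- sol$beta[, 1] / prep$s
    lassoObjective(X, y, 0, b, lam, ctrl)
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("constant columns get exactly zero coefficients", {
  withr::with_seed(9, {
    X <- cbind(x1 = rnorm(25), const = rep(2, 25), x3 = rnorm(25))
    y <- X[, 1] + rnorm(25, sd = 0.2)
  })
  f <- lassoFit(X, y, 0.01)
  expect_identical(unname(f@coefficients["const"]), 0)
  expect_gt(f@coefficients["x1"], 0)
})

test_that("cross-validated lambda selection is deterministic and sensible", {
  withr::with_seed(10, {
    X <- matrix(rnorm(50 * 10), 50, 10)
    colnames(X) <- paste0("x", 1:10)
    y <- 5 * X[, 1] + rnorm(50, sd = 0.5)
  })
  c1 <- cvSelectLambda(X, y, lassoControl(seed = 11))
  c2 <- cvSelectLambda(X, y, lassoControl(seed = 11))
  expect_identical(c1$lambdaOpt, c2$lambdaOpt)
  expect_identical(c1$cvCurve, c2$cvCurve)
  expect_equal(nrow(c1$cvCurve), 100)
  # the chosen lambda minimizes the mean validation MSE
  expect_equal(min(c1$cvCurve$mean_mse),
               c1$cvCurve$mean_mse[c1$cvCurve$lambda == c1$lambdaOpt])
  # the strong predictor survives at the chosen penalty
  f <- lassoFit(X, y, c1$lambdaOpt)
  expect_gt(f@coefficients["x1"], 0)
})

test_that("lasso fits agree with an independent implementation", {
  skip_if_not_installed("glmnet")
  withr::with_seed(12, {
    X <- matrix(rnorm(60 * 12), 60, 12)
    colnames(X) <- paste0("x", 1:12)
    y <- drop(X %*% c(3, -2, rep(0, 10))) + rnorm(60, sd = 0.7)
  })
  for (lam in c(0.5, 0.1, 0.02)) {
    ours <- lassoFit(X, y, lam)
    ref <- glmnet::glmnet(X, y, lambda = lam, standardize = TRUE,
                          thresh = 1e-12)
    expect_equal(unname(ours@coefficients), as.numeric(ref$beta),
                 tolerance = 1e-6)
    expect_equal(ours@intercept, as.numeric(ref$a0), tolerance = 1e-6)
  }
})

test_that("degenerate folds are scored as intercept-only and all-degenerate errors", {
  # one outlying y value: folds excluding it have constant training outcome
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(5, rep(1, 5))
  cv <- cvSelectLambda(X, y, lassoControl(cvFolds = 2, seed = 1))
  expect_true(is.finite(cv$lambdaOpt))
  expect_error(cvSelectLambda(X, rep(3, 6), lassoControl(cvFolds = 2,
                                                         seed = 1)),
               "constant training outcome")
})
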