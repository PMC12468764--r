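makeBootResult <- function(draws) {
  methods::new("BootstrapResult",
               coefDraws = draws,
               lambdaDraws = rep(0.1, nrow(draws)),
               meanCoef = colMeans(draws),
               sdCoef = apply(draws, 2, sd),
               selectionCount = stats::setNames(
                 as.integer(colSums(draws != 0)), colnames(draws)),
               avgLambda = 0.1, nDegenerate = 0L, seed = 1L)
}

test_that("paired bootstrap indices are uniform, jointly drawn, reproducible", {
  idx <- pairedBootstrapIndices(20, 1000, seed = 1)
  expect_equal(dim(idx), c(1000, 20))
  expect_true(all(idx >= 1 & idx <= 20))
  expect_identical(idx, pairedBootstrapIndices(20, 1000, seed = 1))
  expect_false(identical(idx[1, ], idx[2, ]))
  # expected distinct subjects per resample: 20 * (1 - (19/20)^20) = 12.83
  distinct <- apply(idx, 1, function(v) length(unique(v)))
  expect_gte(mean(distinct), 12.2)
  expect_lte(mean(distinct), 13.4)
})

test_that("runBootstrap recovers a planted effect and is reproducible", {
  withr::with_seed(20, {
    X <- matrix(rnorm(40 * 10), 40, 10)
    colnames(X) <- paste0("x", 1:10)
    X <- cbind(X, site = rep(c(0, 1), 20))
    y <- 2 * X[, 1] + rnorm(40, sd = 0.5)
    names(y) <- rownames(X) <- sprintf("S%02d", 1:40)
  })
  d <- methods::new("DesignMatrix", X = X, y = y,
                    siteColumnIndex = 11L, outcome = "repetition")
  br <- runBootstrap(d, lassoControl(), bootstrapControl(nBoot = 100,
                                                         seed = 30))
  expect_gt(meanCoef(br)["x1"], 1)
  expect_gte(selectionCount(br)["x1"] / 100, 0.9)
  expect_gt(avgLambda(br), 0)
  # aggregates match an independent recomputation of the draws
  expect_equal(unname(meanCoef(br)), unname(colMeans(coefDraws(br))),
               tolerance = 1e-12)
  expect_equal(unname(sdCoef(br)),
               unname(apply(coefDraws(br), 2, sd)), tolerance = 1e-12)
  expect_equal(unname(selectionCount(br)),
               unname(colSums(coefDraws(br) != 0)))
  # byte-for-byte reproducibility at fixed seed
  br2 <- runBootstrap(d, lassoControl(), bootstrapControl(nBoot = 2,
                                                          seed = 30))
  br3 <- runBootstrap(d, lassoControl(), bootstrapControl(nBoot = 2,
                                                          seed = 30))
  expect_identical(coefDraws(br2), coefDraws(br3))
  expect_identical(br2@lambdaDraws, br3@lambdaDraws)
  # the planted-effect predictor ranks first
  expect_equal(stabilitySelect(br)$predictor[1], "x1")
})

test_that("degenerate resamples are zero-filled and an all-constant outcome errors", {
  withr::with_seed(21, {
    X <- matrix(rnorm(6 * 2), 6, 2, dimnames = list(sprintf("S%d", 1:6),
                                                    c("a", "site")))
    X[, 2] <- rep(c(0, 1), 3)
  })
  yc <- stats::setNames(c(4, rep(1, 5)), rownames(X))
  d <- methods::new("DesignMatrix", X = X, y = yc,
                    siteColumnIndex = 2L, outcome = "block")
  # resamples that miss subject 1 are degenerate but recorded
  expect_message(br <- runBootstrap(d, lassoControl(cvFolds = 2),
                                    bootstrapControl(nBoot = 20, seed = 2)),
                 "degenerate")
  expect_gt(br@nDegenerate, 0)
  expect_true(all(coefDraws(br)[is.na(br@lambdaDraws), ] == 0))
  dconst <- methods::new("DesignMatrix", X = X,
                         y = stats::setNames(rep(2, 6), rownames(X)),
                         siteColumnIndex = 2L, outcome = "block")
  expect_error(runBootstrap(dconst, lassoControl(cvFolds = 2),
                            bootstrapControl(nBoot = 10, seed = 2)),
               "50%")
})

test_that("coefficientCI applies the Bonferroni-adjusted normal interval", {
  draws <- matrix(0, 50, 2, dimnames = list(NULL, c("a", "b")))
  br <- makeBootResult(draws)
  br@meanCoef <- c(a = 1, b = 0)
  br@sdCoef <- c(a = 0.1, b = 0)
  ci <- coefficientCI(br, bootstrapControl(nBoot = 50, bonferroniM = 1))
  expect_equal(ci$ci_lower[1], 1 - 1.959964 * 0.1, tolerance = 1e-6)
  expect_equal(ci$ci_upper[1], 1 + 1.959964 * 0.1, tolerance = 1e-6)
  expect_true(ci$significant[1])
  # degenerate zero predictor: zero-width interval at 0 contains 0
  expect_false(ci$significant[2])
  # width grows with the number of comparisons and with the SD
  ci59 <- coefficientCI(br, bootstrapControl(nBoot = 50, bonferroniM = 59))
  expect_gt(ci59$ci_upper[1] - ci59$ci_lower[1],
            ci$ci_upper[1] - ci$ci_lower[1])
  br2 <- br
  br2@sdCoef <- c(a = 0.2, b = 0)
  ci2 <- coefficientCI(br2, bootstrapControl(nBoot = 50, bonferroniM = 1))
  expect_gt(ci2$ci_upper[1] - ci2$ci_lower[1],
            ci$ci_upper[1] - ci$ci_lower[1])
})

test_that("stability ranking sorts by count, |mean|, then label", {
  draws <- rbind(c(1, 0.2, 0, 0),
                 c(2, -0.4, 0, 0),
                 c(0, 0.3, 0, 0))
  colnames(draws) <- c("b_conn", "a_conn", "d_conn", "c_conn")
  br <- makeBootResult(draws)
  rk <- stabilitySelect(br)
  # a_conn selected 3x, b_conn 2x; ties d/c at 0 broken lexicographically
  expect_equal(rk$predictor, c("a_conn", "b_conn", "c_conn", "d_conn"))
  expect_equal(rk$selection_count, c(3L, 2L, 0L, 0L))
  # permuting input predictor order leaves the ranked labels unchanged
  br2 <- makeBootResult(draws[, c(3, 1, 4, 2)])
  expect_equal(stabilitySelect(br2)$predictor, rk$predictor)
})

test_that("increasing the penalty never increases selection counts", {
  withr::with_seed(22, {
    X <- matrix(rnorm(30 * 5), 30, 5)
    colnames(X) <- paste0("x", 1:5)
    y <- X[, 1] + rnorm(30, sd = 0.5)
    idx <- pairedBootstrapIndices(30, 30, seed = 3)
  })
  countAt <- function(lam) {
    colSums(t(apply(idx, 1, function(i)
      lassoFit(X[i, ], y[i], lam)@coefficients)) != 0)
  }
  expect_true(all(countAt(0.25) <= countAt(0.05)))
})

test_that("firstDropCutoff finds the largest gap, earliest on ties", {
  expect_equal(firstDropCutoff(c(990, 985, 980, 400, 390)), 3L)
  expect_equal(firstDropCutoff(c(1000, 0)), 1L)
  expect_warning(k <- firstDropCutoff(c(500, 500, 500)), "no drop")
  expect_equal(k, 0L)
  # ties go to the smallest index
  expect_equal(firstDropCutoff(c(10, 5, 0)), 1L)
  expect_error(firstDropCutoff(c(1, 5)), "non-increasing")
  expect_error(firstDropCutoff(5), "at least 2")
})

test_that("selectionReport combines CIs, ranking, and the stable set", {
  draws <- rbind(matrix(rep(c(0.5, -0.3, 0, 0), 45), 45, 4, byrow = TRUE),
                 matrix(rep(c(0.4, 0, 0.1, 0), 5), 5, 4, byrow = TRUE))
  colnames(draws) <- c("p1", "p2", "p3", "site")
  br <- makeBootResult(draws)
  ctrl <- bootstrapControl(nBoot = 50, seed = 1)
  rep <- selectionReport(br, ctrl, outcome = "block")
  expect_s4_class(rep, "SelectionReport")
  # p1 always selected, p2 in 45, p3 in 5: largest drop after p2
  expect_equal(cutoffIndex(rep), 2L)
  expect_equal(stableSet(rep), c("p1", "p2"))
  df <- as.data.frame(rep)
  expect_equal(df$predictor, colnames(draws))  # original order kept
  expect_equal(df$in_stable_set, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(df$significant == (df$ci_lower > 0 | df$ci_upper < 0)))
  # fixed-threshold alternative rule
  rep2 <- selectionReport(br, bootstrapControl(nBoot = 50,
                                               cutoffRule = "fixedThreshold",
                                               threshold = 0.95),
                          outcome = "block")
  expect_equal(stableSet(rep2), c("p1"))
  # serialization
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeSelectionReport(rep, tmp)
  back <- read.csv(tmp)
  expect_equal(back$predictor, df$predictor)
  expect_equal(back$selection_count, df$selection_count)
})

test_that("percentile intervals are available behind the config", {
  withr::with_seed(23, draws <- matrix(rnorm(200, 1, 0.2), 100, 2,
                                       dimnames = list(NULL, c("a", "b"))))
  br <- makeBootResult(draws)
  ci <- coefficientCI(br, bootstrapControl(nBoot = 100, bonferroniM = 1,
                                           ciType = "percentile"))
  expect_equal(ci$ci_lower[1],
               unname(quantile(draws[, 1], 0.025)), tolerance = 1e-12)
})
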