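test_that("generators are pure functions of config and seed", {
  cfg <- simulationControl(seed = 41)
  ce1 <- simulateConnectivity(cfg)
  ce2 <- simulateConnectivity(cfg)
  expect_identical(zMatrix(ce1), zMatrix(ce2))
  expect_identical(siteCode(ce1), siteCode(ce2))
  y1 <- simulateOutcome(ce1, cfg, "block")
  expect_identical(y1, simulateOutcome(ce1, cfg, "block"))
  # different outcome types use distinct noise streams
  expect_false(identical(unname(y1),
                         unname(simulateOutcome(ce1, cfg, "repetition"))))
  ds1 <- simulateDataset(cfg)
  ds2 <- simulateDataset(cfg)
  expect_identical(ds1$behavioral, ds2$behavioral)
  expect_identical(designX(ds1$design), designX(ds2$design))
})

test_that("simulated predictors carry the block-exchangeable correlation", {
  smallSupport <- data.frame(index = c(1L, 7L, 11L),
                             effect = c(0.2, -0.18, 0.17))
  cfg0 <- simulationControl(nSubjects = 2000, nConnections = 12,
                            predictorCorrelation = 0,
                            trueSupport = smallSupport, seed = 42)
  z0 <- zMatrix(simulateConnectivity(cfg0))
  c0 <- cor(z0)
  expect_lt(mean(abs(c0[upper.tri(c0)])), 0.1)
  expect_equal(mean(z0), 0.4 + 0.1 * 0.55, tolerance = 0.05)
  expect_equal(mean(apply(z0, 2, sd)), 0.3, tolerance = 0.05)

  cfg3 <- simulationControl(nSubjects = 2000, nConnections = 12,
                            predictorCorrelation = 0.3, blockSize = 6,
                            trueSupport = smallSupport,
                            siteShift = 0, seed = 43)
  z3 <- zMatrix(simulateConnectivity(cfg3))
  c3 <- cor(z3)
  within <- c(c3[1:6, 1:6][upper.tri(diag(6))],
              c3[7:12, 7:12][upper.tri(diag(6))])
  between <- c3[1:6, 7:12]
  expect_equal(mean(within), 0.3, tolerance = 0.05)
  expect_lt(mean(abs(between)), 0.1)

  expect_error(simulationControl(predictorCorrelation = 1),
               "positive definite")
  expect_error(simulationControl(nConnections = 10),
               "indices must lie")
})

test_that("simulated outcomes follow the truncated sparse linear model", {
  cfg <- simulationControl(seed = 44, noiseSd = 0, zeroInflation = 0,
                           trueSupport = data.frame(index = integer(0),
                                                    effect = numeric(0)))
  ce <- simulateConnectivity(cfg)
  y <- simulateOutcome(ce, cfg, "block")
  expect_true(all(y == 3.7))  # no effects, no noise: constant mean

  cfgz <- simulationControl(seed = 44, zeroInflation = 1)
  expect_true(all(simulateOutcome(simulateConnectivity(cfgz), cfgz,
                                  "block") == 0))

  # the planted effects drive the outcome: with effects scaled well above
  # the outcome noise, the support dominates the y correlations at large n
  cfgBig <- simulationControl(nSubjects = 2000,
                              trueSupport = data.frame(
                                index = c(5L, 23L, 41L),
                                effect = c(2, -1.8, 1.7)),
                              seed = 45)
  ceBig <- simulateConnectivity(cfgBig)
  yBig <- simulateOutcome(ceBig, cfgBig, "block")
  cors <- abs(cor(yBig, zMatrix(ceBig)))
  expect_setequal(order(-cors)[1:3], cfgBig$trueSupport$index)
  expect_gt(cor(yBig, zMatrix(ceBig)[, 5]), 0)
  expect_lt(cor(yBig, zMatrix(ceBig)[, 23]), 0)
  expect_true(all(yBig >= 0))
})

test_that("near-noiseless large-sample data let the lasso recover the truth", {
  cfg <- simulationControl(nSubjects = 500, predictorCorrelation = 0,
                           noiseSd = 1e-3, zeroInflation = 0,
                           siteShift = 0, seed = 46)
  ds <- simulateDataset(cfg, outcome = "block")
  f <- lassoFit(ds$design, lambda = 1e-5)
  est <- f@coefficients[ds$truth$support]
  expect_equal(unname(est), cfg$trueSupport$effect, tolerance = 0.05)
})

test_that("behavioral tables reproduce the simulated rates within rounding", {
  cfg <- simulationControl(seed = 47)
  ds <- simulateDataset(cfg)
  r <- aggregateRates(ds$behavioral)
  bound <- 100 / (2 * min(ds$behavioral$total_syllables))
  for (cc in c("repetition_pct", "prolongation_pct", "block_pct")) {
    expect_lt(max(abs(r[[cc]] - ds$rates[[cc]][
      match(r$participant_id, ds$rates$participant_id)])), bound)
  }
  # zero rate maps to zero counts
  zi <- ds$rates$participant_id[ds$rates$prolongation_pct == 0]
  if (length(zi) > 0)
    expect_true(all(ds$behavioral$prolongations[
      ds$behavioral$participant_id %in% zi] == 0))
  # schema round-trips through the CSV reader unchanged
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(ds$behavioral, tmp, row.names = FALSE, quote = FALSE)
  back <- readBehavioralCsv(tmp)
  expect_equal(back, ds$behavioral, ignore_attr = TRUE)
})

test_that("the dataset bundle is internally consistent", {
  cfg <- simulationControl(seed = 48)
  ds <- simulateDataset(cfg, outcome = "repetition")
  expect_s4_class(ds$connectivity, "ConnectivityExperiment")
  expect_equal(dim(designX(ds$design)), c(20, 59))
  expect_equal(ds$design@outcome, "repetition")
  expect_equal(names(ds$truth$beta), colnames(designX(ds$design)))
  expect_equal(unname(ds$truth$beta[ds$truth$support]),
               cfg$trueSupport$effect)
  expect_equal(sum(ds$truth$beta != 0), 3)
  # sites agree between behavioral table and connectivity colData
  beh <- ds$behavioral[!duplicated(ds$behavioral$participant_id), ]
  expect_equal(unname(siteBinary(beh$site)),
               unname(siteCode(ds$connectivity)[beh$participant_id]))
})
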