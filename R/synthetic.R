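#' Control parameters for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a subject x connection matrix of correlated Fisher-z values with a
#' binary scanner covariate, and non-negative, zero-inflated disfluency
#' percentages driven by a sparse linear signal with known ground truth.
#'
#' @param nSubjects cohort size (default 20).
#' @param nConnections number of connectivity predictors (default 58).
#' @param predictorCorrelation exchangeable correlation rho within blocks
#'   of connections (default 0.3), in `[0, 1)`.
#' @param blockSize connections per correlated block (default 6).
#' @param trueSupport data.frame with columns `index`, `effect`: the
#'   planted connections and their effect sizes on the outcome percentage
#'   per unit Fisher-z (default indices 5, 23, 41 with effects +0.20,
#'   -0.18, +0.17, one per distinct correlation block).
#' @param noiseSd residual SD of the outcome percentage (default 1.0).
#' @param siteFraction fraction of subjects at site MGH (default 0.55).
#' @param siteShift additive Fisher-z shift for MGH subjects
#'   (default 0.1).
#' @param zeroInflation probability an outcome is set to exactly 0
#'   (default 0.15).
#' @param zMean,zSd marginal mean and SD of the Fisher-z predictors
#'   (defaults 0.4 and 0.3, a typical resting-state scale).
#' @param outcomeMeans named target means of the three disfluency
#'   percentages.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return classed list of settings.
#' @export
simulationControl <- function(nSubjects = 20L, nConnections = 58L,
                              predictorCorrelation = 0.3, blockSize = 6L,
                              trueSupport = data.frame(
                                index = c(5L, 23L, 41L),
                                effect = c(0.20, -0.18, 0.17)),
                              noiseSd = 1.0, siteFraction = 0.55,
                              siteShift = 0.1, zeroInflation = 0.15,
                              zMean = 0.4, zSd = 0.3,
                              outcomeMeans = c(repetition = 1.2,
                                               prolongation = 0.5,
                                               block = 3.7),
                              seed = 1L) {
  nSubjects <- assertCount(nSubjects, "nSubjects", 2L)
  nConnections <- assertCount(nConnections, "nConnections", 1L)
  blockSize <- assertCount(blockSize, "blockSize", 1L)
  if (predictorCorrelation < 0 || predictorCorrelation >= 1)
    stop("predictorCorrelation must be in [0, 1) ",
         "(the implied covariance is otherwise not positive definite)")
  if (!all(c("index", "effect") %in% colnames(trueSupport)))
    stop("trueSupport needs columns index and effect")
  if (any(trueSupport$index < 1L) || any(trueSupport$index > nConnections))
    stop("trueSupport indices must lie in [1, nConnections]")
  if (anyDuplicated(trueSupport$index)) stop("duplicate support indices")
  if (zeroInflation < 0 || zeroInflation > 1)
    stop("zeroInflation must be in [0, 1]")
  if (noiseSd < 0 || zSd <= 0) stop("noiseSd must be >= 0 and zSd > 0")
  if (siteFraction < 0 || siteFraction > 1)
    stop("siteFraction must be in [0, 1]")
  if (!all(c("repetition", "prolongation", "block") %in%
           names(outcomeMeans)))
    stop("outcomeMeans must name repetition, prolongation, block")
  structure(list(nSubjects = nSubjects, nConnections = nConnections,
                 predictorCorrelation = predictorCorrelation,
                 blockSize = blockSize, trueSupport = trueSupport,
                 noiseSd = noiseSd, siteFraction = siteFraction,
                 siteShift = siteShift, zeroInflation = zeroInflation,
                 zMean = zMean, zSd = zSd, outcomeMeans = outcomeMeans,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulationControl")
}

# role offsets keep the sub-generators on disjoint deterministic streams
simSeed <- function(cfg, role) {
  if (is.null(cfg$seed)) NULL else iterSeed(cfg$seed, role)
}

#' Simulate a subject-by-connection Fisher-z table
#'
#' Rows are drawn from a multivariate normal with block-exchangeable
#' correlation (`sqrt(rho) * block factor + sqrt(1 - rho) * noise`,
#' scaled to marginal SD `zSd` around `zMean`); MGH subjects additionally
#' receive the `siteShift` offset, emulating a scanner effect.
#'
#' @param cfg a [simulationControl()].
#' @param connections optional connection list supplying predictor labels
#'   (must have `nConnections` rows); default generic labels.
#' @return a [ConnectivityExperiment-class] with a site code.
#' @export
simulateConnectivity <- function(cfg = simulationControl(),
                                 connections = NULL) {
  n <- cfg$nSubjects
  p <- cfg$nConnections
  rho <- cfg$predictorCorrelation
  block <- ceiling(seq_len(p) / cfg$blockSize)
  labels <- if (is.null(connections)) {
    sprintf("conn%02d", seq_len(p))
  } else {
    cl <- readConnectionList(connections)
    if (nrow(cl) != p)
      stop("connection list has ", nrow(cl), " pairs but nConnections = ", p)
    cl$label
  }
  withSeedIf(simSeed(cfg, 101L), {
    nMGH <- round(n * cfg$siteFraction)
    site <- sample(c(rep(1L, nMGH), rep(0L, n - nMGH)))
    shared <- matrix(stats::rnorm(n * max(block)), n)[, block, drop = FALSE]
    eps <- matrix(stats::rnorm(n * p), n, p)
    z <- cfg$zMean + cfg$zSd * (sqrt(rho) * shared + sqrt(1 - rho) * eps)
    z <- z + cfg$siteShift * site
    dimnames(z) <- list(sprintf("S%02d", seq_len(n)), labels)
    ConnectivityExperiment(z, site = site)
  })
}

#' Simulate a disfluency-percentage outcome
#'
#' `y = max(0, mu + Z[, support] %*% effects + eps)` with
#' `eps ~ N(0, noiseSd)`, then set to exactly 0 with probability
#' `zeroInflation`. The intercept `mu` is chosen so that the expected
#' outcome approximately matches `outcomeMeans[outcome]`
#' (block-like 3.7% by default).
#'
#' @param ce a [ConnectivityExperiment-class] (typically from
#'   [simulateConnectivity()]).
#' @param cfg a [simulationControl()].
#' @param outcome which disfluency type's target mean to emulate.
#' @return named numeric outcome vector (percent, >= 0).
#' @export
simulateOutcome <- function(ce, cfg = simulationControl(),
                            outcome = c("block", "repetition",
                                        "prolongation")) {
  outcome <- match.arg(outcome)
  z <- zMatrix(ce)
  if (any(cfg$trueSupport$index > ncol(z)))
    stop("support indices exceed the number of connections")
  beta <- rep(0, ncol(z))
  beta[cfg$trueSupport$index] <- cfg$trueSupport$effect
  zExpect <- cfg$zMean + cfg$siteShift * cfg$siteFraction
  mu <- cfg$outcomeMeans[[outcome]] - sum(beta) * zExpect
  role <- 200L + match(outcome, c("repetition", "prolongation", "block"))
  withSeedIf(simSeed(cfg, role), {
    y <- pmax(0, mu + drop(z %*% beta) +
                   stats::rnorm(nrow(z), 0, cfg$noiseSd))
    y[stats::runif(nrow(z)) < cfg$zeroInflation] <- 0
    stats::setNames(y, rownames(z))
  })
}

#' Simulate a long-format behavioral table
#'
#' Per subject, three speech samples (conversation, phone, reading) with
#' syllable totals drawn uniformly from 200-1100 and integer counts
#' back-computed from the supplied rates, so that [aggregateRates()]
#' reproduces each simulated rate up to the integer-count rounding bound
#' `100 / (2 * min total)`.
#'
#' @param cfg a [simulationControl()].
#' @param rates data.frame `participant_id`, `repetition_pct`,
#'   `prolongation_pct`, `block_pct` (e.g. from [simulateOutcome()]).
#' @param site named binary site codes per participant; simulated when
#'   missing.
#' @return data.frame in the [readBehavioralCsv()] schema.
#' @export
simulateBehavioralTable <- function(cfg = simulationControl(), rates,
                                    site = NULL) {
  ids <- as.character(rates$participant_id)
  n <- length(ids)
  withSeedIf(simSeed(cfg, 301L), {
    if (is.null(site)) {
      nMGH <- round(n * cfg$siteFraction)
      site <- stats::setNames(sample(c(rep(1L, nMGH), rep(0L, n - nMGH))),
                              ids)
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      totals <- sample(200:1100, 3)
      counts <- vapply(c("repetition_pct", "prolongation_pct",
                         "block_pct"),
                       function(cc) round(rates[[cc]][i] / 100 * totals),
                       numeric(3))
      over <- rowSums(counts) > totals
      if (any(over))  # cap pathological draws; rates sum far below 100
        counts[over, ] <- floor(counts[over, ] * totals[over] /
                                  (rowSums(counts)[over] + 1))
      rows[[i]] <- data.frame(
        participant_id = ids[i],
        age = sample(18:55, 1),
        gender = sample(c("M", "F"), 1, prob = c(0.75, 0.25)),
        site = ifelse(site[[ids[i]]] == 1L, "MGH", "BU"),
        ssi4 = sample(9:42, 1),
        sample_id = paste0(ids[i], "_s", 1:3),
        task = c("conversation", "phone", "reading"),
        total_syllables = totals,
        repetitions = as.integer(counts[, 1]),
        prolongations = as.integer(counts[, 2]),
        blocks = as.integer(counts[, 3]))
    }
    validateBehavioral(do.call(rbind, rows))
  })
}

#' Simulate a complete synthetic dataset with known ground truth
#'
#' Orchestrates [simulateConnectivity()], three [simulateOutcome()] calls
#' (one per disfluency type, sharing the planted support), and
#' [simulateBehavioralTable()], then assembles the [DesignMatrix-class]
#' for the requested outcome.
#'
#' @param cfg a [simulationControl()].
#' @param outcome which outcome the design is assembled for.
#' @param connections optional connection list for predictor labels.
#' @return list of class `"SyntheticDataset"` with elements
#'   `connectivity`, `rates`, `behavioral`, `design`, and `truth`
#'   (named true coefficient vector, support labels and effects).
#' @export
simulateDataset <- function(cfg = simulationControl(),
                            outcome = c("block", "repetition",
                                        "prolongation"),
                            connections = NULL) {
  outcome <- match.arg(outcome)
  ce <- simulateConnectivity(cfg, connections)
  rates <- data.frame(
    participant_id = subjectIds(ce),
    repetition_pct = simulateOutcome(ce, cfg, "repetition"),
    prolongation_pct = simulateOutcome(ce, cfg, "prolongation"),
    block_pct = simulateOutcome(ce, cfg, "block"),
    row.names = NULL)
  behavioral <- simulateBehavioralTable(cfg, rates, site = siteCode(ce))
  design <- assembleDesign(ce, rates, outcome = outcome)
  beta <- stats::setNames(rep(0, cfg$nConnections + 1L),
                          colnames(design@X))
  beta[cfg$trueSupport$index] <- cfg$trueSupport$effect
  structure(list(connectivity = ce, rates = rates,
                 behavioral = behavioral, design = design,
                 truth = list(beta = beta,
                              support = colnames(design@X)[cfg$trueSupport$index],
                              effect = cfg$trueSupport$effect)),
            class = "SyntheticDataset")
}
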