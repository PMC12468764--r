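#' Disfluency percentage for one speech sample
#'
#' Percentage of syllables affected by a disfluency type: `100 * count /
#' total_syllables`. Values are kept at full precision; rounding to two
#' decimals happens only at reporting time.
#'
#' @param count disfluency count(s), non-negative integers.
#' @param totalSyllables total syllables produced, positive; recycled
#'   against `count`.
#' @return numeric percentage(s) in `[0, 100]`.
#' @examples
#' percentDisfluency(11, 791)   # 1.39 after 2-decimal rounding
#' percentDisfluency(84, 542)   # 15.50
#' @export
percentDisfluency <- function(count, totalSyllables) {
  if (any(!is.finite(count)) || any(!is.finite(totalSyllables)))
    stop("counts and totals must be finite")
  if (any(totalSyllables <= 0))
    stop("totalSyllables must be positive")
  if (any(count < 0) || any(count != floor(count)))
    stop("count must be a non-negative integer")
  if (any(count > totalSyllables))
    stop("count cannot exceed totalSyllables")
  100 * count / totalSyllables
}

#' Participant-level disfluency rates
#'
#' Converts a long-format behavioral table (one row per speech sample) into
#' per-participant rates: each sample's percentage is computed first, then
#' averaged across samples with equal weight per task (not pooled by
#' syllable counts). Participants with fewer than three samples are
#' averaged over what is available, with a warning.
#'
#' @param behavioral data.frame in the schema of [readBehavioralCsv()].
#' @return data.frame with columns `participant_id`, `repetition_pct`,
#'   `prolongation_pct`, `block_pct`, one row per participant, sorted by id.
#' @export
aggregateRates <- function(behavioral) {
  needed <- c("participant_id", "total_syllables",
              "repetitions", "prolongations", "blocks")
  if (!is.data.frame(behavioral) || !all(needed %in% colnames(behavioral)))
    stop("behavioral table must contain columns: ",
         paste(needed, collapse = ", "))
  if (nrow(behavioral) == 0L) stop("behavioral table has no samples")

  pct <- data.frame(
    participant_id = as.character(behavioral$participant_id),
    repetition_pct = percentDisfluency(behavioral$repetitions,
                                       behavioral$total_syllables),
    prolongation_pct = percentDisfluency(behavioral$prolongations,
                                         behavioral$total_syllables),
    block_pct = percentDisfluency(behavioral$blocks,
                                  behavioral$total_syllables))

  # pooled ("combined") rows are complete by construction; only warn when
  # genuine per-task samples are missing
  pooled <- if ("task" %in% colnames(behavioral))
    tapply(behavioral$task == "combined", behavioral$participant_id, all)
  else FALSE
  nSamples <- table(pct$participant_id)
  short <- names(nSamples)[nSamples < 3L]
  short <- setdiff(short, names(which(unlist(pooled))))
  if (length(short) > 0L)
    warning("participant(s) with fewer than 3 samples, averaging over ",
            "available samples: ", paste(short, collapse = ", "))

  out <- stats::aggregate(
    pct[c("repetition_pct", "prolongation_pct", "block_pct")],
    by = list(participant_id = pct$participant_id), FUN = mean)
  out[order(out$participant_id), , drop = FALSE]
}

#' Cohort summary statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of the SSI-4 score
#' and each disfluency rate.
#'
#' @param behavioral behavioral table ([readBehavioralCsv()] schema).
#' @param rates optional output of [aggregateRates()]; computed if missing.
#' @return tidy data.frame with columns `measure`, `mean`, `sd`.
#' @export
summarizeCohort <- function(behavioral, rates = NULL) {
  if (is.null(rates)) rates <- aggregateRates(behavioral)
  ids <- !duplicated(behavioral$participant_id)
  ssi4 <- behavioral$ssi4[ids]
  if (length(ssi4) < 2L)
    stop("cohort summary needs at least 2 participants (SD undefined)")
  vals <- list(ssi4 = ssi4,
               repetition_pct = rates$repetition_pct,
               prolongation_pct = rates$prolongation_pct,
               block_pct = rates$block_pct)
  data.frame(measure = names(vals),
             mean = vapply(vals, mean, numeric(1)),
             sd = vapply(vals, stats::sd, numeric(1)),
             row.names = NULL)
}

#' Inter-rater intraclass correlation
#'
#' Single-measure ICC from the two-way ANOVA decomposition of a
#' rater-by-item matrix. The default `"agreement"` variant is the two-way
#' random-effects absolute-agreement ICC(2,1), which penalizes systematic
#' rater offsets; `"consistency"` gives ICC(3,1), which does not.
#'
#' @param ratings numeric matrix, raters in rows and rated items in
#'   columns; no missing cells.
#' @param variant `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @return single numeric ICC estimate in (-Inf, 1].
#' @examples
#' r <- rbind(rater1 = c(1, 2, 3, 4), rater2 = c(2, 3, 4, 5))
#' iccAgreement(r)                         # < 1: constant offset penalized
#' iccAgreement(r, variant = "consistency") # 1: offset ignored
#' @export
iccAgreement <- function(ratings, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must have no missing cells")
  k <- nrow(ratings)   # raters
  n <- ncol(ratings)   # items
  if (k < 2L || n < 2L) stop("need at least 2 raters and 2 items")

  itemMean <- colMeans(ratings)
  raterMean <- rowMeans(ratings)
  grand <- mean(ratings)
  ssItem <- k * sum((itemMean - grand)^2)
  ssRater <- n * sum((raterMean - grand)^2)
  ssTotal <- sum((ratings - grand)^2)
  ssErr <- ssTotal - ssItem - ssRater

  msItem <- ssItem / (n - 1)
  msRater <- ssRater / (k - 1)
  msErr <- ssErr / ((n - 1) * (k - 1))

  if (msItem <= .Machine$double.eps * max(1, abs(grand))^2) {
    warning("zero between-item variance; ICC undefined, returning 0")
    return(0)
  }
  if (variant == "agreement")
    (msItem - msErr) /
      (msItem + (k - 1) * msErr + k * (msRater - msErr) / n)
  else
    (msItem - msErr) / (msItem + (k - 1) * msErr)
}

behavioralColumns <- c("participant_id", "age", "gender", "site", "ssi4",
                       "sample_id", "task", "total_syllables",
                       "repetitions", "prolongations", "blocks")

#' Read a long-format behavioral CSV
#'
#' One row per speech sample. The header must contain exactly the columns
#' `participant_id, age, gender, site, ssi4, sample_id, task,
#' total_syllables, repetitions, prolongations, blocks`. `task` is one of
#' `conversation`, `phone`, `reading`, or `combined` (counts pooled over
#' samples, as in published per-participant tables). Row-level invariants
#' (non-negative integer counts, counts not exceeding totals, SSI-4 within
#' its 9-42 instrument range, two-level MGH/BU site) are enforced.
#'
#' @param path CSV file path.
#' @return validated data.frame in the same schema.
#' @export
readBehavioralCsv <- function(path) {
  if (!file.exists(path)) stop("behavioral file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(behavioralColumns, colnames(df))
  extra <- setdiff(colnames(df), behavioralColumns)
  if (length(missing) || length(extra))
    stop("behavioral CSV header mismatch; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  df <- df[behavioralColumns]
  validateBehavioral(df)
  if (all(df$task == "combined")) attr(df, "combined") <- TRUE
  df
}

validateBehavioral <- function(df) {
  counts <- c("total_syllables", "repetitions", "prolongations", "blocks")
  for (cc in counts)
    if (any(!is.finite(df[[cc]])) || any(df[[cc]] < 0) ||
        any(df[[cc]] != floor(df[[cc]])))
      stop("column ", cc, " must hold non-negative integers")
  if (any(df$total_syllables <= 0))
    stop("total_syllables must be positive")
  if (any(df$repetitions + df$prolongations + df$blocks > df$total_syllables))
    stop("per-sample disfluency counts exceed total syllables")
  if (any(df$ssi4 < 9 | df$ssi4 > 42))
    stop("ssi4 outside instrument range [9, 42]")
  siteBinary(df$site)  # errors on anything but MGH/BU
  okTask <- c("conversation", "phone", "reading", "combined")
  if (!all(df$task %in% okTask))
    stop("task must be one of: ", paste(okTask, collapse = ", "))
  key <- paste(df$participant_id, df$sample_id)
  if (anyDuplicated(key))
    stop("duplicate (participant_id, sample_id) rows")
  invisible(df)
}

#' Write a cohort summary CSV
#'
#' @param summary output of [summarizeCohort()].
#' @param path destination CSV; means/SDs are written at 2-decimal
#'   reporting precision.
#' @return `path`, invisibly.
#' @export
writeCohortSummary <- function(summary, path) {
  out <- summary
  out$mean <- round(out$mean, 2)
  out$sd <- round(out$sd, 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
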