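#' Fisher z-transform of a correlation
#'
#' `atanh(r)`, variance-stabilizing for inference on correlations.
#' Correlations at or beyond `1 - clip` in magnitude are clipped to
#' `+/-(1 - clip)` with a warning so the transform stays finite for
#' degenerate series (real BOLD correlations never reach |r| = 1).
#'
#' @param r numeric correlation(s) in `[-1, 1]`.
#' @param clip clipping margin (default `1e-7`).
#' @return numeric Fisher-z value(s).
#' @examples
#' fisherZ(0.5)   # 0.5 * log(3) = 0.549306
#' @export
fisherZ <- function(r, clip = 1e-7) {
  if (any(!is.finite(r))) stop("correlations must be finite")
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  hi <- 1 - clip
  if (any(abs(r) >= hi)) {
    warning("correlation magnitude >= ", format(hi),
            "; clipping before the z-transform")
    r <- pmin(pmax(r, -hi), hi)
  }
  atanh(r)
}

#' Read or validate an ROI connection list
#'
#' A connection list names the ordered ROI pairs used as predictors. On
#' disk it is a YAML (or JSON) sequence of two-element label arrays. Pairs
#' must be unique under unordered comparison and may not be self-pairs.
#'
#' @param x path to a YAML/JSON file, or a 2-column matrix/data.frame/list
#'   of label pairs.
#' @return data.frame with columns `roi_a`, `roi_b`, `label`
#'   (`"roiA--roiB"`), preserving input order.
#' @export
readConnectionList <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("connection list file not found: ", x)
    x <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::fromJSON(x, simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
    else yaml::read_yaml(x)
  }
  if (is.matrix(x) || is.data.frame(x)) {
    if (ncol(x) < 2L) stop("connection list needs two label columns")
    pairs <- cbind(as.character(x[[1]]), as.character(x[[2]]))
  } else if (is.list(x)) {
    if (!all(vapply(x, length, integer(1)) == 2L))
      stop("each connection must be a pair of ROI labels")
    pairs <- do.call(rbind, lapply(x, function(p) as.character(unlist(p))))
  } else stop("unsupported connection list input")
  if (nrow(pairs) == 0L) stop("connection list is empty")
  if (any(pairs[, 1] == pairs[, 2]))
    stop("self-pairs are not allowed in a connection list")
  key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "\r"))
  if (anyDuplicated(key))
    stop("duplicate connections (unordered comparison): ",
         paste(unique(pairs[duplicated(key), 1]), collapse = ", "))
  data.frame(roi_a = pairs[, 1], roi_b = pairs[, 2],
             label = paste0(pairs[, 1], "--", pairs[, 2]))
}

#' Default reconstructed DIVA/GODIVA connection list
#'
#' The 58 ROI pairs shipped with the package, spanning the feedback and
#' feedforward speech motor control networks (ventral motor/premotor and
#' somatosensory cortex, auditory regions, SMA/preSMA, posterior inferior
#' frontal sulcus, basal ganglia, thalamic nuclei, and anterior/posterior
#' cerebellum). This list is a plausibility reconstruction assembled from
#' the model ROI vocabulary -- candidate connection sets for a given study
#' should be supplied explicitly.
#'
#' @return data.frame as from [readConnectionList()], 58 rows.
#' @export
defaultConnectionList <- function() {
  readConnectionList(system.file("extdata",
    "connections_diva_godiva_reconstructed.yaml", package = "fcLasso"))
}

#' Read one subject's ROI time-series table
#'
#' CSV/TSV with a header row of ROI labels; rows are volumes (time points).
#'
#' @param path file path (delimiter inferred from extension: `.tsv` tab,
#'   else comma).
#' @return numeric time x ROI matrix with ROI labels as colnames.
#' @export
readTimeSeries <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("time-series table must be numeric: ", path)
  validateTimeSeries(m, path)
  m
}

validateTimeSeries <- function(m, what = "time series") {
  if (nrow(m) < 3L) stop(what, ": need at least 3 time points")
  if (any(!is.finite(m))) stop(what, ": non-finite entries")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop(what, ": ROI labels must be present and unique")
  invisible(m)
}

#' Build a Fisher-z connectivity table from ROI time series
#'
#' For each subject and each listed ROI pair, computes the temporal Pearson
#' correlation between the two ROI columns and Fisher-transforms it.
#'
#' @param ts named list of time x ROI matrices (one per subject; names are
#'   subject ids) as from [readTimeSeries()].
#' @param connections a connection list ([readConnectionList()]).
#' @param site optional per-subject site labels/codes (see
#'   [ConnectivityExperiment()]).
#' @return a [ConnectivityExperiment-class], subjects x
#'   `nrow(connections)` Fisher-z values.
#' @export
buildConnectivityTable <- function(ts, connections, site = NULL) {
  connections <- readConnectionList(connections)
  if (is.null(names(ts)) || anyDuplicated(names(ts)))
    stop("ts must be a named list with unique subject ids")
  rois <- unique(c(connections$roi_a, connections$roi_b))
  z <- matrix(NA_real_, nrow = length(ts), ncol = nrow(connections),
              dimnames = list(names(ts), connections$label))
  for (s in names(ts)) {
    m <- validateTimeSeries(ts[[s]], paste("subject", s))
    missing <- setdiff(rois, colnames(m))
    if (length(missing))
      stop("subject ", s, " is missing ROI label(s): ",
           paste(missing, collapse = ", "))
    sds <- apply(m[, rois, drop = FALSE], 2, stats::sd)
    flat <- rois[sds == 0]
    if (length(flat))
      stop("subject ", s, " has zero-variance ROI series: ",
           paste(flat, collapse = ", "))
    r <- stats::cor(m[, connections$roi_a, drop = FALSE],
                    m[, connections$roi_b, drop = FALSE])
    z[s, ] <- fisherZ(diag(r))
  }
  ConnectivityExperiment(z, site = site)
}

#' Read/write a wide connectivity CSV
#'
#' Wide format: first column `subject_id`, optional `site` column, then one
#' column per connection labelled `"roiA--roiB"`. The precomputed input
#' path and [buildConnectivityTable()] produce identical containers.
#'
#' @param path CSV path.
#' @param connections optional connection list; when given, columns are
#'   checked and reordered to match it.
#' @return a [ConnectivityExperiment-class].
#' @export
readConnectivityTable <- function(path, connections = NULL) {
  if (!file.exists(path)) stop("connectivity file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "subject_id")
    stop("first column of a connectivity CSV must be subject_id")
  site <- NULL
  if ("site" %in% colnames(df)) {
    site <- df$site
    df$site <- NULL
  }
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- as.character(df$subject_id)
  if (!is.null(connections)) {
    connections <- readConnectionList(connections)
    missing <- setdiff(connections$label, colnames(z))
    if (length(missing))
      stop("connectivity CSV lacks connection column(s): ",
           paste(missing, collapse = ", "))
    z <- z[, connections$label, drop = FALSE]
  }
  ConnectivityExperiment(z, site = site)
}

#' @rdname readConnectivityTable
#' @param ce a [ConnectivityExperiment-class] to serialize.
#' @export
writeConnectivityTable <- function(ce, path) {
  z <- zMatrix(ce)
  df <- data.frame(subject_id = rownames(z), check.names = FALSE)
  s <- siteCode(ce)
  if (!is.null(s)) df$site <- ifelse(s == 1L, "MGH", "BU")
  df <- cbind(df, as.data.frame(z, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the regression design for one disfluency outcome
#'
#' Joins the connectivity predictors with the participant-level disfluency
#' rates and the binary scanner covariate. Rows are ordered by sorted
#' subject id; predictor columns keep the connection-list order, and the
#' site column is appended last.
#'
#' @param ce a [ConnectivityExperiment-class].
#' @param rates output of [aggregateRates()].
#' @param behavioral behavioral table supplying the site labels (ignored if
#'   `ce` already carries a site code).
#' @param outcome `"repetition"`, `"prolongation"`, or `"block"`.
#' @return a [DesignMatrix-class] with `ncol = nConnections + 1`.
#' @export
assembleDesign <- function(ce, rates, behavioral = NULL,
                           outcome = c("repetition", "prolongation",
                                       "block")) {
  outcome <- match.arg(outcome)
  if (nrow(ce) == 0L) stop("connectivity table has no connections")
  ids <- sort(subjectIds(ce))
  rids <- as.character(rates$participant_id)
  mism <- c(setdiff(ids, rids), setdiff(rids, ids))
  if (length(mism))
    stop("subject ids of connectivity and rates do not coincide: ",
         paste(unique(mism), collapse = ", "))

  site <- siteCode(ce)
  if (is.null(site)) {
    if (is.null(behavioral))
      stop("no site covariate: supply a behavioral table or a ",
           "ConnectivityExperiment with colData$site")
    bid <- !duplicated(behavioral$participant_id)
    site <- stats::setNames(siteBinary(behavioral$site[bid]),
                            as.character(behavioral$participant_id[bid]))
    if (!all(ids %in% names(site)))
      stop("behavioral table lacks site for subject(s): ",
           paste(setdiff(ids, names(site)), collapse = ", "))
  }
  if (length(unique(site[ids])) > 2L)
    stop("more than two sites are not supported")

  z <- zMatrix(ce)[ids, , drop = FALSE]
  X <- cbind(z, site = as.numeric(site[ids]))
  ycol <- paste0(outcome, "_pct")
  y <- rates[[ycol]][match(ids, rids)]
  names(y) <- ids
  methods::new("DesignMatrix", X = X, y = y,
               siteColumnIndex = ncol(X), outcome = outcome)
}
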