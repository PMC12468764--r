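#' Run the full disfluency-connectivity analysis pipeline
#'
#' Wires the stages end to end: read/validate the behavioral table,
#' compute participant rates and cohort summaries, load or accept the
#' Fisher-z connectivity table, run the site heteroscedasticity screen,
#' and for each requested disfluency outcome run the paired-bootstrap
#' cross-validated LASSO and write its selection report. Because every
#' bootstrap iteration derives its seed from `bootCtrl$seed` and the
#' iteration index only, the same resampled subjects are used for all
#' three outcome models, and identical inputs and seeds give
#' byte-identical report CSVs.
#'
#' @param behavioral path to a behavioral CSV or a validated data.frame.
#' @param connectivity path to a wide connectivity CSV or a
#'   [ConnectivityExperiment-class].
#' @param connections optional connection list (path or object) used to
#'   check/reorder connectivity columns.
#' @param outcomes character subset of repetition/prolongation/block.
#' @param outdir output directory, created if needed.
#' @param lassoCtrl a [lassoControl()].
#' @param bootCtrl a [bootstrapControl()].
#' @param diagAlpha flagging level of the heteroscedasticity screen.
#' @param writePlots also write scree and heatmap PNGs.
#' @return invisibly, a manifest list (also written as
#'   `manifest.json`): per-outcome report files, average optimal lambdas,
#'   stable sets, seeds, config hash, package version.
#' @export
runPipeline <- function(behavioral, connectivity, connections = NULL,
                        outcomes = c("repetition", "prolongation",
                                     "block"),
                        outdir = ".", lassoCtrl = lassoControl(),
                        bootCtrl = bootstrapControl(),
                        diagAlpha = 0.05, writePlots = FALSE) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  if (is.character(behavioral)) behavioral <- readBehavioralCsv(behavioral)
  else validateBehavioral(behavioral)
  rates <- aggregateRates(behavioral)
  cohort <- summarizeCohort(behavioral, rates)
  writeCohortSummary(cohort, file.path(outdir, "cohort_summary.csv"))

  ce <- if (methods::is(connectivity, "ConnectivityExperiment"))
    connectivity else readConnectivityTable(connectivity, connections)
  if (is.null(siteCode(ce))) {
    bid <- !duplicated(behavioral$participant_id)
    site <- stats::setNames(siteBinary(behavioral$site[bid]),
                            as.character(behavioral$participant_id[bid]))
    SummarizedExperiment::colData(ce)$site <-
      as.integer(site[colnames(ce)])
    methods::validObject(ce)
  }

  screen <- siteHeteroscedasticityScreen(ce, alpha = diagAlpha)
  writeScreen(screen, file.path(outdir, "site_levene_screen.csv"))

  reports <- list()
  for (oc in outcomes) {
    design <- assembleDesign(ce, rates, behavioral, oc)
    res <- runBootstrap(design, lassoCtrl, bootCtrl)
    rep <- selectionReport(res, bootCtrl, outcome = oc)
    writeSelectionReport(rep, file.path(outdir,
                                        paste0("report_", oc, ".csv")))
    if (writePlots)
      ggplot2::ggsave(file.path(outdir, paste0("scree_", oc, ".png")),
                      plotSelectionScree(rep), width = 7, height = 4,
                      dpi = 150)
    reports[[oc]] <- rep
  }
  if (writePlots && length(reports) > 0L)
    ggplot2::ggsave(file.path(outdir, "coefficient_heatmap.png"),
                    plotCoefficientHeatmap(reports), width = 10,
                    height = 2 + length(reports), dpi = 150)

  cfg <- list(lasso = lassoCtrl[setdiff(names(lassoCtrl), "seed")],
              bootstrap = unclass(bootCtrl))
  manifest <- list(
    package = "fcLasso",
    version = as.character(utils::packageVersion("fcLasso")),
    seed = bootCtrl$seed,
    config = cfg,
    config_hash = rlang::hash(cfg),
    n_subjects = nrow(rates),
    n_connections = nrow(ce),
    levene_verdict = attr(screen, "verdict"),
    outcomes = lapply(reports, function(r) list(
      report = paste0("report_", r@outcome, ".csv"),
      avg_lambda = r@avgLambda,
      n_significant = sum(r@results$significant),
      stable_set = as.list(r@stableSet))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, reports = reports,
                 screen = screen, cohort = cohort))
}
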