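#' Selection-frequency scree plot
#'
#' Predictors by stability rank against their bootstrap selection
#' frequency, with the first-drop cutoff marked: everything at or left of
#' the dashed line is in the stable set.
#'
#' @param report a [SelectionReport-class].
#' @return a ggplot object.
#' @export
plotSelectionScree <- function(report) {
  r <- report@results
  df <- r[order(r$stability_rank), ]
  df$freq <- df$selection_count / report@B
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stability_rank,
                                        y = .data$freq)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$in_stable_set),
                        size = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#b2182b",
                                           `FALSE` = "grey55"),
                                guide = "none") +
    ggplot2::labs(x = "stability rank",
                  y = "selection frequency",
                  title = paste0("Selection-frequency scree (",
                                 report@outcome, ")")) +
    ggplot2::theme_minimal()
  if (report@cutoffIndex > 0L)
    p <- p + ggplot2::geom_vline(xintercept = report@cutoffIndex + 0.5,
                                 linetype = "dashed", color = "#b2182b")
  p
}

#' Coefficient heatmap across outcomes
#'
#' Mean bootstrap LASSO coefficients, outcomes in rows and predictors in
#' columns; stable-set cells are outlined in black.
#'
#' @param reports named list of [SelectionReport-class] objects (one per
#'   outcome).
#' @return a ggplot object.
#' @export
plotCoefficientHeatmap <- function(reports) {
  df <- do.call(rbind, lapply(reports, function(r) {
    d <- r@results
    data.frame(outcome = r@outcome, predictor = d$predictor,
               mean_coef = d$mean_coef, stable = d$in_stable_set)
  }))
  df$predictor <- factor(df$predictor,
                         levels = reports[[1]]@results$predictor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor,
                                   y = .data$outcome,
                                   fill = .data$mean_coef)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_tile(data = df[df$stable, , drop = FALSE],
                       fill = NA, color = "black", linewidth = 0.7) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "mean coef") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Mean bootstrap LASSO coefficients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Outcome-vs-connectivity scatter
#'
#' One connection's Fisher-z values against the chosen disfluency rate,
#' with a least-squares fit line.
#'
#' @param ce a [ConnectivityExperiment-class].
#' @param rates output of [aggregateRates()].
#' @param connection connection label to plot.
#' @param outcome disfluency type.
#' @return a ggplot object.
#' @export
plotConnectionScatter <- function(ce, rates, connection,
                                  outcome = c("repetition",
                                              "prolongation", "block")) {
  outcome <- match.arg(outcome)
  z <- zMatrix(ce)
  if (!connection %in% colnames(z))
    stop("unknown connection: ", connection)
  ids <- intersect(rownames(z), as.character(rates$participant_id))
  df <- data.frame(
    z = z[ids, connection],
    y = rates[[paste0(outcome, "_pct")]][
      match(ids, rates$participant_id)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$y)) +
    ggplot2::geom_point(color = "#2166ac", size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#b2182b", linewidth = 0.6) +
    ggplot2::labs(x = paste0("Fisher-z (", connection, ")"),
                  y = paste0(outcome, " rate (%)")) +
    ggplot2::theme_minimal()
}
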