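#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the network-by-contrast consistency grid
#'
#' The classic recruitment heatmap: one tile per network x contrast,
#' coloured by the group t-statistic with colour saturating at `|t| >=
#' t_saturation` (orange activation, blue deactivation), and annotated with
#' the percent of the sample recruiting the network positively.
#'
#' @param object A `consistency_table` from [consistency_table()].
#' @param t_saturation Saturation point of the fill scale (default 5).
#' @param label_percent Annotate tiles with `percent_positive`
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consistency_table
#' @export
autoplot.consistency_table <- function(object, t_saturation = 5,
                                       label_percent = TRUE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$network, y = .data$condition,
                                    fill = pmax(pmin(.data$t, t_saturation),
                                                -t_saturation))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#e08214",
                                  limits = c(-t_saturation, t_saturation),
                                  name = "group t") +
    ggplot2::labs(x = "network", y = "contrast") +
    ggplot2::theme_minimal()
  if (label_percent)
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.0f%%", .data$percent_positive)),
      size = 3)
  p
}

#' Plot the performance-recruitment relationship
#'
#' Scatter of per-subject betas against the performance score with the
#' robust (Huber) trendline; subjects down-weighted by the M-estimator are
#' drawn smaller.
#'
#' @param object A `performance_fit` from [performance_regression()].
#' @param data Tibble with `beta` and `performance` per subject (the data
#'   the fit was run on); when omitted, only the trendline is drawn if
#'   performance was selected.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot performance_fit
#' @export
autoplot.performance_fit <- function(object, data = NULL, ...) {
  cf <- object$robust$coefficients
  has_perf <- "performance" %in% cf$term
  p <- ggplot2::ggplot() +
    ggplot2::labs(x = "performance (accuracy %)",
                  y = expression(beta),
                  title = sprintf("%s / %s", object$network,
                                  object$condition)) +
    ggplot2::theme_minimal()
  if (!is.null(data))
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(data, .w = object$robust$weights),
      ggplot2::aes(x = .data$performance, y = .data$beta,
                   size = .data$.w), alpha = 0.7, show.legend = FALSE) +
      ggplot2::scale_size_continuous(range = c(1, 2.5))
  if (has_perf) {
    b0 <- cf$estimate[cf$term == "(Intercept)"]
    b1 <- cf$estimate[cf$term == "performance"]
    p <- p + ggplot2::geom_abline(intercept = b0, slope = b1,
                                  colour = "#b2182b", linewidth = 0.8)
  }
  p
}

#' Plot one axial slice of a component map
#'
#' @param map A [component_map()].
#' @param z Axial slice (1-based); default the middle slice.
#' @param threshold Optional display threshold: weights below it are blanked
#'   (the conventional display cut for z/t maps is 4).
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, z = NULL, threshold = NULL) {
  stopifnot(inherits(map, "component_map"))
  if (is.null(z)) z <- ceiling(map$grid$shape[3] / 2)
  sl <- map$weights[, , z]
  df <- tibble::tibble(x = rep(seq_len(nrow(sl)), times = ncol(sl)),
                       y = rep(seq_len(ncol(sl)), each = nrow(sl)),
                       w = as.vector(sl))
  if (!is.null(threshold)) df$w[df$w < threshold] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "weight") +
    ggplot2::labs(title = sprintf("%s (z = %d)", map$label, z)) +
    ggplot2::theme_minimal()
}

#' Plot a component timecourse
#'
#' @param object A `component_timecourse` from [project_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot component_timecourse
#' @export
autoplot.component_timecourse <- function(object, ...) {
  df <- tibble::tibble(time = (seq_along(object$values) - 1) * object$tr,
                       value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "component activity",
                  title = object$label) +
    ggplot2::theme_minimal()
}
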