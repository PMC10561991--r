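#' Plot a population sleep profile
#'
#' Mean fraction of time asleep over zeitgeber time per group, with the
#' bootstrap confidence ribbon.
#'
#' @param profile Output of [sleep_profile()].
#' @return A ggplot object.
#' @export
plot_sleep_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$zt_bin,
                               y = .data$mean_fraction_asleep,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Fraction asleep",
                  colour = NULL, fill = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a specimen-by-time heatmap
#'
#' @param m A `behav_heatmap` from [heatmap_matrix()].
#' @return A ggplot object (tile raster, specimens on the y axis).
#' @export
plot_heatmap <- function(m) {
  df <- tibble::tibble(
    id = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    t_h = rep(as.numeric(colnames(m)), each = nrow(m)) / 3600,
    value = as.vector(unclass(m))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_h, y = .data$id,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "Time (h)", y = NULL,
                  fill = attr(m, "variable")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot chi-squared periodograms
#'
#' Q statistic against candidate period with the significance line, one
#' colour per specimen or group.
#'
#' @param object A `behav_periodogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot behav_periodogram
#' @export
autoplot.behav_periodogram <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$period_h, y = .data$Q,
                                    colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Period (h)", y = expression(chi^2 ~ statistic),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!all(is.na(object$threshold))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$threshold),
                                linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a double-plotted actogram
#'
#' @param m A `behav_actogram` from [actogram_matrix()].
#' @return A ggplot object (days top to bottom, 48 h per row when
#'   double-plotted).
#' @export
plot_actogram <- function(m) {
  bin_h <- attr(m, "bin_s") / 3600
  df <- tibble::tibble(
    day = rep(seq_len(nrow(m)), ncol(m)),
    hour = rep((seq_len(ncol(m)) - 1) * bin_h, each = nrow(m)),
    value = as.vector(unclass(m))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$value)) +
    ggplot2::geom_col(width = bin_h, fill = "grey20", na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$day)) +
    ggplot2::scale_x_continuous(
      breaks = seq(0, 48, 12),
      name = if (isTRUE(attr(m, "double"))) "Time (h, double-plotted)"
             else "Time (h)"
    ) +
    ggplot2::labs(y = "Activity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0),
                   axis.text.y = ggplot2::element_blank())
}

#' Plot sleep-stage occupancy over zeitgeber time
#'
#' @param occupancy Output of [state_occupancy()].
#' @return A ggplot object.
#' @export
plot_state_occupancy <- function(occupancy) {
  ggplot2::ggplot(occupancy,
                  ggplot2::aes(x = .data$zt_bin, y = .data$fraction,
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Fraction of bins",
                  colour = "Stage") +
    ggplot2::theme_minimal()
}

#' Plot an SVM decision surface
#'
#' @param surface Output of [decision_surface()].
#' @return A ggplot object: predicted-label field with specimens overlaid.
#' @export
plot_decision_surface <- function(surface) {
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = surface$grid,
                         ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                      fill = .data$predicted),
                         alpha = 0.3) +
    ggplot2::geom_point(data = surface$points,
                        ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                     colour = .data$label), size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * surface$explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * surface$explained[2]),
      fill = "Predicted", colour = "Observed"
    ) +
    ggplot2::theme_minimal()
}
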