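## ggplot2 autoplot() methods for the package's result types.

#' @export
autoplot.transient_set <- function(object, dff = NULL, ...) {
  if (!is.null(dff)) {
    p <- ggplot2::ggplot(dff, ggplot2::aes(.data$time_s, .data$dff)) +
      ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
      ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                          colour = "firebrick") +
      ggplot2::geom_point(data = object$events,
                          ggplot2::aes(.data$time_s, .data$amplitude + object$mu),
                          colour = "firebrick", size = 1)
  } else {
    p <- ggplot2::ggplot(object$events,
                         ggplot2::aes(.data$time_s, .data$amplitude)) +
      ggplot2::geom_segment(ggplot2::aes(xend = .data$time_s, yend = 0)) +
      ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "time (s)", y = expression(Delta * "F/F"),
                    title = sprintf("%d transients, %.3f Hz",
                                    object$n_events, object$frequency_hz))
}

#' @export
autoplot.peri_event_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_offset_s, .data$trial,
                                 fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (s)", y = "trial", fill = "z")
}

#' Plot a trajectory over its arena zones
#'
#' @param traj a trajectory tibble.
#' @param zones optional zone list (defaults to the trajectory's arena).
#' @return a ggplot object.
#' @export
plot_trajectory <- function(traj, zones = NULL) {
  zones <- traj_zones(traj, zones)
  polys <- purrr::imap_dfr(zones, function(p, nm) {
    tibble(zone = nm, x = p[, 1], y = p[, 2])
  })
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(.data$x, .data$y, group = .data$zone),
                          fill = NA, colour = "grey60") +
    ggplot2::geom_path(data = traj,
                       ggplot2::aes(.data$x_mm, .data$y_mm),
                       colour = "steelblue", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' @export
autoplot.fi_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$step_pA, .data$n_spikes)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "injected current (pA)", y = "spikes per step",
                  title = if (is.na(attr(object, "rheobase_pA"))) "no rheobase"
                          else sprintf("rheobase %g pA", attr(object, "rheobase_pA")))
}

#' @export
autoplot.ltp_timecourse <- function(object, ...) {
  ggplot2::ggplot(object$normalized,
                  ggplot2::aes(.data$time_min, .data$percent_baseline)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$induction_time_min,
                        linetype = "dotted") +
    ggplot2::labs(x = "time (min)", y = "oEPSC amplitude (% baseline)")
}

#' @export
autoplot.group_report <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(y = "mean +/- SEM", x = NULL,
                  title = sprintf("%s, p = %.3g", object$test$method[1],
                                  object$test$p_value[1]))
}
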