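#' Plot a capillary trace
#'
#' Time series of the fluorescence signal, optionally overlaying the
#' extracted baseline (dashed) and detected peaks (points).
#'
#' @param object A [cap_trace()].
#' @param baseline Optional [extract_baseline()] result or [als_baseline()]
#'   tibble.
#' @param peaks Optional `cap_peaks` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cap_trace
#' @export
autoplot.cap_trace <- function(object, baseline = NULL, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$signal_fu)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Fluorescence (FU)",
                  title = sprintf("Trace: %s (%s)", trace_sample_id(object),
                                  trace_channel(object))) +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    if (inherits(baseline, "cap_baseline")) {
      p <- p + ggplot2::geom_segment(
        data = tibble::tibble(x = baseline$region_start_s,
                              xend = baseline$region_end_s,
                              y = baseline$baseline_fu),
        ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                     yend = .data$y),
        linetype = "dashed", colour = "red", inherit.aes = FALSE)
    } else if (is.data.frame(baseline)) {
      p <- p + ggplot2::geom_line(
        data = baseline,
        ggplot2::aes(x = .data$time_s, y = .data$baseline_fu),
        colour = "red", linetype = "dashed", inherit.aes = FALSE)
    }
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    base_fu <- attr(peaks, "baseline_fu") %||% 0
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(tibble::as_tibble(peaks),
                           y = .data$height_fu + base_fu),
      ggplot2::aes(x = .data$peak_time_s, y = .data$y),
      colour = "blue", size = 0.8, inherit.aes = FALSE)
  }
  p
}

#' Histogram of spike heights
#'
#' @param object A `cap_peaks` tibble.
#' @param bins Number of bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cap_peaks
#' @export
autoplot.cap_peaks <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$height_fu)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40", colour = "white") +
    ggplot2::labs(x = "Peak height above baseline (FU)", y = "Count") +
    ggplot2::theme_minimal()
}

#' Plot a fitted binding isotherm
#'
#' Titration points with the fitted apparent-radius curve; the
#' zero-analyte point is highlighted.
#'
#' @param object A `cap_binding_fit`.
#' @param n_curve Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cap_binding_fit
#' @export
autoplot.cap_binding_fit <- function(object, n_curve = 200, ...) {
  dat <- object$data
  pos <- dat$analyte_um[dat$analyte_um > 0]
  grid <- c(0, exp(seq(log(max(min(pos), 1e-3) / 10), log(max(pos) * 1.2),
                       length.out = n_curve)))
  curve <- tibble::tibble(analyte_um = grid,
                          rh_nm = binding_isotherm(object$model, grid))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$analyte_um, y = .data$rh_nm)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$analyte_um == 0)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(
      x = "Analyte concentration (uM)", y = "Apparent R_h (nm)",
      title = sprintf("1:%d binding fit, K_d = %.3g uM",
                      object$model$stoichiometry_n, object$model$kd_um)) +
    ggplot2::theme_minimal()
}

#' Plot the predicted relative-intensity distribution
#'
#' @param mode Radial density mode(s) to draw.
#' @param s_max Upper intensity limit.
#' @return A ggplot object.
#' @export
plot_intensity_model <- function(mode = c("empirical", "poiseuille"),
                                 s_max = 10) {
  dens <- purrr::map_dfr(mode, function(m) {
    d <- predicted_intensity_distribution(m, n_grid = 512, s_max = s_max)
    dplyr::mutate(tibble::as_tibble(d), mode = m)
  })
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$s, y = .data$density,
                                     colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Relative signal intensity s = u_max / u(r)",
                  y = "Density", colour = "Radial density") +
    ggplot2::theme_minimal()
}
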