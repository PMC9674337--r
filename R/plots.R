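# ggplot2 autoplot methods for the main result types.

#' Plot selected frames of a stimulus movie
#'
#' @param object A `stimulus_movie`.
#' @param frames Frame indices to montage (default 6 evenly spaced).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stimulus_movie <- function(object, frames = NULL, ...) {
  d <- dim(object$frames)
  if (is.null(frames)) {
    frames <- unique(round(seq(1, d[1], length.out = 6)))
  }
  df <- purrr::map_dfr(frames, function(i) {
    tibble(
      frame = sprintf("t = %.2f s", object$times[i]),
      el = rep(seq_len(d[2]), d[3]),
      az = rep(seq_len(d[3]), each = d[2]),
      luminance = as.vector(object$frames[i, , ])
    )
  })
  df$frame <- factor(df$frame, levels = unique(df$frame))
  ggplot2::ggplot(df, ggplot2::aes(.data$az, .data$el,
                                   fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~frame) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth (px)", y = "elevation (px)") +
    ggplot2::theme_minimal()
}

#' Plot membrane potential and firing rate of a simulation
#'
#' @param object A `sim_result`.
#' @param kernel_sd_ms IFR kernel SD passed to [detect_spikes_ifr()].
#' @param ... Unused.
#' @return A ggplot with Vm and IFR panels.
#' @export
autoplot.sim_result <- function(object, kernel_sd_ms = 20, ...) {
  t_s <- object$t_start + object$t_ms / 1000
  ifr <- detect_spikes_ifr(object, kernel_sd_ms = kernel_sd_ms)$ifr
  df <- dplyr::bind_rows(
    tibble(time_s = t_s, value = object$vm[, ncol(object$vm)],
           panel = "Vm (mV)"),
    tibble(time_s = ifr$time_s, value = ifr$rate_hz,
           panel = "IFR (spk/s)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time relative to collision (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a center-of-mass trajectory
#'
#' @param object A `com_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the CoM path colored by time.
#' @export
autoplot.com_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_um, .data$y_um,
                                       color = .data$time_s)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  color = "time (s)") +
    ggplot2::theme_minimal()
}

#' Compare the ATP estimates of an energy report
#'
#' @param object An `energy_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of the ATP estimates and savings.
#' @export
autoplot.energy_report <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$unit == "ATP")
  ggplot2::ggplot(df, ggplot2::aes(.data$quantity, .data$value)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "ATP molecules") +
    ggplot2::theme_minimal()
}
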