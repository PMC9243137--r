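# ggplot2 display methods for the main result types.

#' Plot a pore-radius profile
#'
#' @param object A [pore_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pore_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$z, y = .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1.4, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "z along pore axis (Å)",
                  y = "pore radius (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a current trace
#'
#' @param object A `chan_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chan_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' Plot a chi1 clash scan
#'
#' Clash count around the chi1 circle with allowed intervals shaded.
#'
#' @param object A `rotamer_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rotamer_scan <- function(object, ...) {
  td <- tidy.rotamer_scan(object)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$angle, y = .data$n_clash)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "chi1 (degrees)", y = "clashing residues") +
    ggplot2::theme_minimal()
  if (nrow(object$allowed_intervals) > 0)
    p <- p + ggplot2::geom_rect(
      data = object$allowed_intervals,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "palegreen", alpha = 0.25)
  p
}

#' Plot a G-V curve with its Boltzmann fit
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  vv <- seq(min(object$data$voltage_mV), max(object$data$voltage_mV),
            length.out = 200)
  curve <- tibble(voltage_mV = vv,
                  g = predict.boltzmann_fit(object, vv))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$voltage_mV, y = .data$g)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "voltage (mV)", y = "G / Gmax") +
    ggplot2::theme_minimal()
}

#' Plot an all-points amplitude histogram with its Gaussian components
#'
#' @param object An [amplitude_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amplitude_histogram <- function(object, ...) {
  bins <- object$bins
  dens <- bins
  total <- sum(bins$count) * object$bin_width
  comp_curves <- purrr::pmap(object$components[, c("mean", "sd", "weight")],
    function(mean, sd, weight)
      tibble(mid = bins$mid,
             count = weight * total * dnorm(bins$mid, mean, sd))) |>
    list_rbind(names_to = "component")
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey70") +
    ggplot2::geom_line(data = comp_curves,
                       ggplot2::aes(group = .data$component),
                       colour = "firebrick") +
    ggplot2::labs(x = "current (pA)", y = "samples") +
    ggplot2::theme_minimal()
}
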