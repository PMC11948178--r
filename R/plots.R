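#' Plot a raw or composite spectrum
#'
#' @param spectrum `tibble(mz, intensity)`.
#' @return a ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.adc_peaks
#' @export
plot_peaks <- function(object, ...) autoplot.adc_peaks(object, ...)

#' Plot deconvoluted neutral-mass peaks
#'
#' Stick plot of neutral mass vs intensity.
#'
#' @param object an `adc_peaks` tibble from [deconvolve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot adc_peaks
#' @export
autoplot.adc_peaks <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$neutral_mass, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$neutral_mass, yend = 0)) +
    ggplot2::labs(x = "neutral mass (Da)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a biotransformation time course
#'
#' Mean fractional abundance per species over time with standard-deviation
#' error bars across biological replicates; points with no observed signal
#' plot as zero.
#'
#' @param object an `adc_timecourse` from [aggregate_replicates()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot adc_timecourse
#' @export
autoplot.adc_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h,
                                       y = .data$mean_fraction,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_fraction - .data$sd_fraction, 0),
      ymax = pmin(.data$mean_fraction + .data$sd_fraction, 1)), width = 4) +
    ggplot2::labs(x = "time (h)", y = "fractional abundance",
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.adc_timecourse
#' @param x an `adc_timecourse`.
#' @export
plot_timecourse <- function(x, ...) autoplot.adc_timecourse(x, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
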