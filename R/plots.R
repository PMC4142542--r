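#' Plot a power spectrum
#'
#' @param object a `power_spectrum` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "wavelet power (a.u.)")
}

#' Plot a coupling-plane sweep as a tile map
#'
#' @param object a `scan_grid`.
#' @param statistic column of `object$points` to map (default
#'   `"gamma_mean"`).
#' @param ... unused.
#' @return A ggplot; transition-region points are outlined.
#' @export
autoplot.scan_grid <- function(object, statistic = "gamma_mean", ...) {
  pts <- object$points
  reg <- locate_transition_region(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$j_exc, y = .data$j_inh)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[statistic]])) +
    ggplot2::geom_point(data = reg[reg$in_transition, ],
                        colour = "white", size = 1) +
    ggplot2::labs(x = expression(J[exc] ~ "(mV)"),
                  y = expression(j[inh]), fill = statistic)
}

#' Plot condition-averaged spectra of an attention contrast
#'
#' @param object an `attention_contrast`.
#' @param c_mix which mixing constant to show (default the largest).
#' @param ... unused.
#' @return A ggplot of trial-averaged spectra per stimulus and condition.
#' @export
autoplot.attention_contrast <- function(object, c_mix = NULL, ...) {
  spec <- object$spectra
  if (is.null(c_mix)) c_mix <- max(spec$c_mix)
  cm <- c_mix
  avg <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(spec, .data$c_mix == cm),
                    .data$condition, .data$stimulus, .data$freq_hz),
    power = mean(.data$power), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$freq_hz, y = .data$power,
                                    colour = factor(.data$stimulus))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (a.u.)",
                  colour = "stimulus")
}

#' Raster plot of a simulation
#'
#' @param raster a `spike_raster`.
#' @param t_lim optional time window, ms.
#' @return A ggplot.
#' @export
plot_raster <- function(raster, t_lim = NULL) {
  sp <- raster$spikes
  if (!is.null(t_lim))
    sp <- sp[sp$time_ms >= t_lim[1] & sp$time_ms <= t_lim[2], ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time_ms, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.5) +
    ggplot2::labs(x = "time (ms)", y = "neuron")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
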