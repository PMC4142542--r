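#' Logarithmically spaced analysis frequencies
#'
#' @param n_freq number of frequencies (default 20).
#' @param f_min,f_max frequency range, Hz (defaults 5 and 200).
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @export
log_freqs <- function(n_freq = 20, f_min = 5, f_max = 200) {
  exp(seq(log(f_min), log(f_max), length.out = n_freq))
}

#' Time-resolved complex Morlet wavelet power of an LFP trace
#'
#' Computes `p(t, f) = |W(t, f)|^2`, the squared modulus of the continuous
#' wavelet transform with a complex Morlet mother wavelet of centre
#' frequency `omega0 = 6` cycles (the standard admissible choice), via the
#' FFT convolution of the analytic wavelet at each requested frequency.
#' The scale-to-frequency map and the cone of influence (the e-folding
#' time `sqrt(2) * scale` of wavelet power at each scale) follow the usual
#' geophysical convention.  Absolute power is convention-dependent (it
#' scales with the wavelet normalisation); every downstream statistic in
#' the package is invariant to a per-frequency monotone rescaling.
#'
#' @param lfp an `lfp_trace`.
#' @param freqs analysis frequencies, Hz (default [log_freqs()]).
#' @param omega0 Morlet centre frequency, cycles (default 6).
#' @return An object of class `wavelet_power`: list with `power`
#'   (time-by-frequency matrix), `freqs`, `coi_samples` (per-frequency
#'   number of samples inside the cone of influence at each end), `valid`
#'   (per-frequency flag: any sample outside the cone), and `dt` in ms.
#' @export
morlet_power <- function(lfp, freqs = log_freqs(), omega0 = 6) {
  stopifnot(inherits(lfp, "lfp_trace"))
  x <- lfp$u
  n <- length(x)
  dt_s <- lfp$dt / 1000                      # Hz-based scales need seconds
  npad <- 2^ceiling(log2(n))                 # zero-pad against wraparound
  xh <- fft(c(x - mean(x), numeric(npad - n)))
  omega <- 2 * pi * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / (npad * dt_s)

  # Morlet centre-frequency relation: f = omega0 / (2 pi s) up to the
  # admissibility correction term
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs)
  coi_t <- sqrt(2) * scales                  # e-folding time, seconds
  coi_samples <- pmin(as.integer(ceiling(coi_t / dt_s)), n)

  power <- matrix(0, nrow = n, ncol = length(freqs))
  for (k in seq_along(freqs)) {
    s <- scales[k]
    psi_hat <- numeric(npad)
    pos <- omega > 0
    psi_hat[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt_s) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    w <- fft(xh * psi_hat, inverse = TRUE) / npad
    power[, k] <- Mod(w[seq_len(n)])^2
  }
  out <- list(power = power, freqs = freqs, coi_samples = coi_samples,
              valid = 2L * coi_samples < n, dt = lfp$dt)
  class(out) <- "wavelet_power"
  out
}

#' Time-averaged power spectrum outside the cone of influence
#'
#' Averages `p(t, f)` over the time samples that lie outside the cone of
#' influence at each frequency.  Frequencies at which no sample survives
#' are flagged invalid and carry `NA` power.
#'
#' @param wp a `wavelet_power` object.
#' @return A tibble `(freq_hz, power, n_valid)` of class
#'   `power_spectrum`; `power >= 0` where defined.
#' @export
time_average_outside_coi <- function(wp) {
  stopifnot(inherits(wp, "wavelet_power"))
  n <- nrow(wp$power)
  avg <- vapply(seq_along(wp$freqs), function(k) {
    m <- wp$coi_samples[k]
    if (2 * m >= n) return(NA_real_)
    mean(wp$power[(m + 1):(n - m), k])
  }, numeric(1))
  n_valid <- pmax(n - 2L * wp$coi_samples, 0L)
  out <- tibble::tibble(freq_hz = wp$freqs, power = avg, n_valid = n_valid)
  class(out) <- c("power_spectrum", class(out))
  out
}

#' One-call spectrum of an LFP trace
#'
#' Convenience wrapper: [morlet_power()] followed by
#' [time_average_outside_coi()].
#'
#' @inheritParams morlet_power
#' @return A `power_spectrum` tibble.
#' @export
lfp_spectrum <- function(lfp, freqs = log_freqs(), omega0 = 6) {
  time_average_outside_coi(morlet_power(lfp, freqs, omega0))
}

#' Mean power in a frequency band
#'
#' @param spectrum a `power_spectrum` tibble.
#' @param band two-element numeric, Hz (default the gamma band 35-80 Hz).
#' @return Mean power over in-band frequencies.
#' @export
band_power <- function(spectrum, band = c(35, 80)) {
  sel <- spectrum$freq_hz >= band[1] & spectrum$freq_hz <= band[2]
  mean(spectrum$power[sel], na.rm = TRUE)
}
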