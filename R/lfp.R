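#' Synthesize a local field potential from spiking activity
#'
#' The LFP is the linear superposition of recurrent-layer spikes plus
#' `c_mix`-scaled external (feedforward) spikes, convolved causally with a
#' normalized exponential kernel `K(t) = exp(-t / tau_k) / tau_k` — a
#' low-pass filter approximating the sum of postsynaptic currents.  The
#' convolution operates on per-step binned spike counts (bin = `dt`), with
#' the kernel truncated at `10 * tau_k`; a margin (default 50 ms, about
#' `3.3 * tau_k`) is discarded from both ends of the filtered trace to
#' avoid boundary effects.  Only activity after the configured transient
#' enters the signal.
#'
#' @param raster a `spike_raster`.
#' @param c_mix mixing constant scaling external input spikes into the
#'   signal (0.2 for the full model; 0 in reduced conditions, where the
#'   external input still drives the neurons but is excluded from the
#'   signal).
#' @param tau_k kernel time constant, ms.
#' @param trim_ms margin removed from each end after filtering, ms.
#' @return An object of class `lfp_trace`: list with the amplitude series
#'   `u` (arbitrary units), sample interval `dt` (ms) and the absolute
#'   time `t0` (ms) of the first retained sample.
#' @examples
#' \donttest{
#' cfg <- network_config("full", n = 100, n_active = 40, t_total = 600,
#'                       t_transient = 100)
#' w <- build_coupling(100, seed = 1)
#' stim <- draw_stimulus_set(100, 40, 1, seed = 2)[[1]]
#' lfp <- generate_lfp(simulate_full(cfg, w, stim, seed = 3), c_mix = 0.2)
#' }
#' @export
generate_lfp <- function(raster, c_mix = 0.2, tau_k = 15, trim_ms = 50) {
  dt <- raster$dt
  n_steps <- length(raster$ext_counts)
  first_step <- as.integer(floor(raster$t_transient / dt)) + 1L
  keep <- first_step:n_steps
  if (length(keep) * dt <= 2 * trim_ms)
    stop("raster too short: need more than twice the trim margin after the transient",
         call. = FALSE)

  sp <- raster$spikes
  sp_steps <- as.integer(round(sp$time_ms / dt))
  v4_counts <- tabulate(sp_steps, nbins = n_steps)[keep]
  x <- v4_counts + c_mix * as.numeric(raster$ext_counts[keep])

  u <- exp_kernel_filter(x, tau_k = tau_k, dt = dt)
  n_trim <- as.integer(round(trim_ms / dt))
  u <- u[(n_trim + 1):(length(u) - n_trim)]
  out <- list(u = u, dt = dt,
              t0 = (first_step - 1L + n_trim) * dt + dt)
  class(out) <- "lfp_trace"
  out
}

# causal convolution with the normalized exponential kernel, truncated at
# 10 tau_k; the input is the binned count signal so the delta-train
# convolution reduces to a kernel-weighted count sum
exp_kernel_filter <- function(x, tau_k, dt) {
  m <- as.integer(ceiling(10 * tau_k / dt))
  kern <- exp(-(0:m) * dt / tau_k) / tau_k
  # open (linear) FFT convolution, then keep the causal part
  y <- stats::convolve(x, rev(kern), type = "open")
  y[seq_along(x)]
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace: %d samples at dt = %g ms, from t = %g ms>\n",
              length(x$u), x$dt, x$t0))
  invisible(x)
}

#' @rdname as_tibble.spike_raster
#' @export
as_tibble.lfp_trace <- function(x, ...) {
  tibble::tibble(time_ms = x$t0 + (seq_along(x$u) - 1) * x$dt, u = x$u)
}

#' Split an LFP trace into contiguous equal-length trials
#'
#' Long single-run traces (reduced-model conditions) are segmented into
#' `n_trials` contiguous, equal-length pieces before spectral analysis, so
#' each trial independently excludes its own cone of influence.  Any
#' remainder samples at the end are dropped.
#'
#' @param lfp an `lfp_trace`.
#' @param n_trials number of segments.
#' @return A list of `lfp_trace` objects.
#' @export
split_lfp <- function(lfp, n_trials) {
  len <- length(lfp$u) %/% n_trials
  if (len < 1) stop("trace shorter than the requested number of trials",
                    call. = FALSE)
  lapply(seq_len(n_trials), function(k) {
    i0 <- (k - 1L) * len
    out <- list(u = lfp$u[i0 + seq_len(len)], dt = lfp$dt,
                t0 = lfp$t0 + i0 * lfp$dt)
    class(out) <- "lfp_trace"
    out
  })
}

#' Write an LFP trace as a two-column table
#'
#' Plain CSV with columns `(time_ms, u)`; the sample interval is recorded
#' in a `# dt_ms:` header comment line.
#'
#' @param lfp an `lfp_trace`.
#' @param path output file.
#' @export
write_lfp <- function(lfp, path) {
  con <- file(path, "w")
  writeLines(sprintf("# dt_ms: %g", lfp$dt), con)
  utils::write.csv(as.data.frame(as_tibble(lfp)), con, row.names = FALSE)
  close(con)
  invisible(path)
}
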