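# Small in-code fixtures shared across test files.

# hand-assembled coupling matrix from an explicit edge list
make_coupling <- function(n, edges, eps = 4) {
  w <- list(n = as.integer(n),
            n_exc = as.integer(n * eps / (1 + eps)),
            n_inh = as.integer(n / (1 + eps)),
            edges = tibble::tibble(from = as.integer(edges$from),
                                   to = as.integer(edges$to)))
  class(w) <- "coupling_matrix"
  w
}

# raster with explicit spikes/external counts (times in ms)
make_raster <- function(spike_times, spike_neurons, n_steps, n = 10,
                        dt = 0.1, t_transient = 0, ext_counts = NULL,
                        mode = "full") {
  if (is.null(ext_counts)) ext_counts <- integer(n_steps)
  spikes <- tibble::tibble(time_ms = spike_times,
                           neuron = as.integer(spike_neurons))
  spikes$post_transient <- spikes$time_ms > t_transient
  critnet:::new_spike_raster(
    spikes, as.integer(ext_counts),
    list(n = as.integer(n), dt = dt, t_total = n_steps * dt,
         t_transient = t_transient), mode)
}

# independent single-neuron reference integrator (pure R, same membrane
# equation, per-step Poisson external input) used as a brute-force oracle
reference_isolated_neuron <- function(v_r = -60, v_theta = -50, tau = 10,
                                      j_ext = 0.1, rate_per_step = 1,
                                      dt = 0.1, n_steps, v0 = v_r) {
  v <- v0
  n_spikes <- 0L
  ks <- rpois(n_steps, rate_per_step)
  for (t in seq_len(n_steps)) {
    v <- v + dt / tau * (v_r - v) + j_ext * ks[t]
    if (v >= v_theta) {
      v <- v_r
      n_spikes <- n_spikes + 1L
    }
  }
  n_spikes
}

# synthetic long-format spectra: list of per-(stimulus, trial) power rows
make_spectra <- function(power_fun, n_stim, n_tr, freqs = 1:5) {
  rows <- list()
  for (i in seq_len(n_stim)) for (tr in seq_len(n_tr)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      stimulus = i, trial = tr, freq_hz = freqs,
      power = power_fun(i, tr, freqs))
  }
  dplyr::bind_rows(rows)
}
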