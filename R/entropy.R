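#' Coarse-grain a spike raster into pattern states
#'
#' At observation scale `K`, the per-step binary spike pattern of the `N`
#' neurons is reduced to `N/K` channels: neurons are permuted once by a
#' fixed random `channel_order` and summed in consecutive blocks of `K`.
#' `K = 1` is the raw binary pattern; `K = N` is the per-step population
#' spike count.  The same `channel_order` must be reused across scales and
#' across a coupling sweep for one network, so the scales form a nested
#' coarse-graining hierarchy.
#'
#' Only post-transient steps enter the series.  In avalanche-mode rasters
#' an entire cascade occupies one step, so the step pattern contains all
#' of its generations.
#'
#' @param raster a `spike_raster`.
#' @param k observation scale; must divide the neuron count.
#' @param channel_order permutation of `1:N` (neuron ids in channel
#'   order); drawn once from `seed` when missing.
#' @param seed RNG seed used only when `channel_order` is missing.
#' @return An object of class `pattern_series`: list with `keys` (one
#'   compact state key per step, `""` for silent steps), `k`,
#'   `n_channels`, `n_steps`, `channel_order`.
#' @export
coarse_grain <- function(raster, k, channel_order = NULL, seed = NULL) {
  n <- raster$n
  if (n %% k != 0) stop("k must divide the neuron count", call. = FALSE)
  if (is.null(channel_order))
    channel_order <- with_seed(seed, sample.int(n))
  stopifnot(length(channel_order) == n)
  rank_of <- integer(n)
  rank_of[channel_order] <- seq_len(n)

  dt <- raster$dt
  n_steps <- length(raster$ext_counts)
  first_step <- as.integer(floor(raster$t_transient / dt)) + 1L
  steps_kept <- n_steps - first_step + 1L

  sp <- raster$spikes[raster$spikes$post_transient, ]
  keys <- character(steps_kept)
  if (nrow(sp) > 0) {
    step <- as.integer(round(sp$time_ms / dt)) - first_step + 1L
    channel <- (rank_of[sp$neuron] - 1L) %/% as.integer(k) + 1L
    ord <- order(step)
    keys <- pattern_keys_cpp(step[ord], channel[ord], steps_kept)
  }
  out <- list(keys = keys, k = as.integer(k),
              n_channels = as.integer(n / k), n_steps = steps_kept,
              channel_order = channel_order)
  class(out) <- "pattern_series"
  out
}

#' @export
print.pattern_series <- function(x, ...) {
  cat(sprintf("<pattern_series: K = %d (%d channels), %d steps, %d distinct states>\n",
              x$k, x$n_channels, x$n_steps, length(unique(x$keys))))
  invisible(x)
}

#' Decode a pattern-series state key into channel counts
#'
#' @param key a state key from a `pattern_series`.
#' @param n_channels number of channels.
#' @return Integer vector of per-channel spike sums.
#' @export
decode_state <- function(key, n_channels) {
  out <- integer(n_channels)
  if (nzchar(key)) {
    parts <- strsplit(strsplit(key, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    for (p in parts) out[as.integer(p[1])] <- as.integer(p[2])
  }
  out
}

#' Plug-in information entropy of a pattern series
#'
#' Shannon entropy `H = -sum p log2 p` of the empirical distribution of
#' coarse-grained spike patterns over the post-transient time steps, in
#' bits, without bias correction.
#'
#' @param series a `pattern_series`, or a plain vector of states.
#' @return Entropy in bits (`>= 0`).
#' @export
pattern_entropy <- function(series) {
  states <- if (inherits(series, "pattern_series")) series$keys else series
  if (length(states) == 0) stop("need at least one state", call. = FALSE)
  p <- tabulate(factor(states)) / length(states)
  -sum(p * log2(p))
}
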