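#' Build the random excitatory/inhibitory coupling matrix
#'
#' Draws a directed Erdos-Renyi graph on `n` neurons: each of the `n^2`
#' ordered pairs (including self-loops) carries a connection independently
#' with probability `p`.  By convention the first `n * eps / (1 + eps)`
#' indices are excitatory and the rest inhibitory, so identity is fixed by
#' index and a fit-for-purpose seed makes the architecture reproducible.
#'
#' @param n neuron count; must be divisible by `1 + eps`.
#' @param p connection probability in `[0, 1]`.
#' @param eps excitatory-to-inhibitory count ratio.
#' @param seed integer RNG seed.
#' @return An object of class `coupling_matrix`: a list with `n`, `n_exc`,
#'   `n_inh`, and `edges`, a tibble of directed edges `(from, to)` meaning
#'   a connection from presynaptic `from` to postsynaptic `to`.
#' @examples
#' w <- build_coupling(100, p = 0.05, eps = 4, seed = 1)
#' w$n_exc / w$n_inh
#' @export
build_coupling <- function(n, p = 0.02, eps = 4, seed = NULL) {
  n <- as.integer(n)
  if (n %% (1 + eps) != 0)
    stop("n must be divisible by 1 + eps", call. = FALSE)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    # row j of the dense adjacency is Bernoulli(p) over n entries;
    # drawing the per-row edge count then placing it uniformly without
    # replacement is an equivalent, memory-light construction
    deg <- rbinom(n, n, p)
    from <- rep.int(seq_len(n), deg)
    to <- unlist(lapply(deg, function(k) if (k > 0) sample.int(n, k) else integer(0)),
                 use.names = FALSE)
    out <- list(n = n,
                n_exc = as.integer(n * eps / (1 + eps)),
                n_inh = as.integer(n / (1 + eps)),
                edges = tibble::tibble(from = from, to = as.integer(to)))
    class(out) <- "coupling_matrix"
    out
  })
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix: %d neurons (%d exc / %d inh), %d edges>\n",
              x$n, x$n_exc, x$n_inh, nrow(x$edges)))
  invisible(x)
}

# compressed adjacency (targets + offsets) for the C++ simulators, 0-based
adjacency_csr <- function(w) {
  ord <- order(w$edges$from)
  from <- w$edges$from[ord]
  counts <- tabulate(from, nbins = w$n)
  list(targets = as.integer(w$edges$to[ord] - 1L),
       offsets = as.integer(c(0L, cumsum(counts))))
}

#' Draw stimulus-specific sets of externally driven neurons
#'
#' Each stimulus activates a uniform-random subset of `n_active` neurons;
#' subsets for different stimuli may overlap.  When `n_active == n`
#' (reduced-network conditions) every subset is the whole network and
#' stimulus identity is carried by the coupling architecture instead.
#'
#' @param n neuron count.
#' @param n_active driven-subset size, `<= n`.
#' @param n_stimuli number of stimuli.
#' @param seed integer RNG seed.
#' @return A list of `stimulus_drive` objects, each with sorted unique
#'   `active_set` indices and a `stimulus_id`.
#' @export
draw_stimulus_set <- function(n, n_active = 1000, n_stimuli = 6, seed = NULL) {
  if (n_active > n) stop("n_active cannot exceed n", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_stimuli), function(a) {
      s <- list(active_set = sort(sample.int(n, n_active)),
                stimulus_id = a)
      class(s) <- "stimulus_drive"
      s
    })
  })
}

#' Initial membrane potentials in an asynchronous state
#'
#' Potentials are drawn so that, when isolated and driven by a constant
#' suprathreshold current, each neuron would reach threshold at a
#' uniform-random phase of its firing period.  The constant-drive
#' trajectory of the leaky integrator is
#' `V(t) = v_star - (v_star - v_r) exp(-t / tau_mem)` with asymptote
#' `v_star`; sampling the phase uniformly and reading off `V` gives the
#' sojourn density of that trajectory.  The mean stochastic drive of the
#' model parameterisation asymptotes exactly at threshold (where the
#' deterministic period diverges), so the initialiser uses a suprathreshold
#' asymptote, by default twice the rest-to-threshold gap.
#'
#' @param cfg a [network_config()].
#' @param seed integer RNG seed.
#' @param v_star asymptotic potential of the constant drive, mV; must
#'   exceed `v_theta`.  Default `v_r + 2 * (v_theta - v_r)`.
#' @return Numeric vector of `cfg$n` initial potentials in
#'   `[v_r, v_theta)`.
#' @export
init_membrane <- function(cfg, seed = NULL, v_star = NULL) {
  if (is.null(v_star)) v_star <- cfg$v_r + 2 * (cfg$v_theta - cfg$v_r)
  if (v_star <= cfg$v_theta)
    stop("v_star must exceed v_theta for a finite firing period", call. = FALSE)
  t_period <- cfg$tau_mem * log((v_star - cfg$v_r) / (v_star - cfg$v_theta))
  with_seed(seed, {
    phase <- runif(cfg$n) * t_period
    v_star - (v_star - cfg$v_r) * exp(-phase / cfg$tau_mem)
  })
}

new_spike_raster <- function(spikes, ext_counts, cfg, mode) {
  r <- list(spikes = spikes, ext_counts = ext_counts,
            n = cfg$n, dt = cfg$dt, t_total = cfg$t_total,
            t_transient = cfg$t_transient, mode = mode)
  class(r) <- "spike_raster"
  r
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster: %s mode, %d neurons, %d spikes over %g ms (dt = %g ms)>\n",
              x$mode, x$n, nrow(x$spikes), x$t_total, x$dt))
  invisible(x)
}

#' Tidy a spike raster
#'
#' @param x a `spike_raster`.
#' @param ... unused.
#' @return A tibble `(time_ms, neuron, layer)`; external input is recorded
#'   as per-step delivered-spike counts under `layer = "ext"` with the
#'   count in `neuron`'s companion column `count`.
#' @export
as_tibble.spike_raster <- function(x, ...) {
  v4 <- dplyr::mutate(x$spikes, layer = "v4", count = 1L)
  steps <- which(x$ext_counts > 0)
  ext <- tibble::tibble(time_ms = steps * x$dt, neuron = NA_integer_,
                        layer = "ext", count = x$ext_counts[steps])
  dplyr::bind_rows(v4, ext)
}

#' Simulate the full network dynamics
#'
#' Euler integration of the membrane equation
#' `tau_mem dV/dt = -(V - V_R) + inputs` at step `dt`: every driven neuron
#' receives an independent Poisson number of external spikes per step
#' (mean `f_max * dt`, each adding `j_ext` mV), recurrent spikes add
#' `J_exc` (excitatory presynaptic neuron) or subtract `J_inh = eps *
#' J_exc * j_inh` (inhibitory) and are delivered at the next integration
#' step, and threshold crossings emit a spike and reset the potential to
#' `v_r`.  Undriven neurons receive no external input.
#'
#' @param cfg a [network_config()] (`mode = "full"`).
#' @param w a [build_coupling()] architecture consistent with `cfg`.
#' @param stimulus a `stimulus_drive` (or `NULL` for no external drive).
#' @param v0 initial potentials; defaults to [init_membrane()].
#' @param seed integer RNG seed for the run.
#' @return A `spike_raster` whose `spikes` tibble has `(time_ms, neuron)`
#'   rows for recurrent-layer spikes and whose `ext_counts` records the
#'   per-step total of delivered external spikes.  Spikes at or before
#'   `t_transient` are retained but flagged by the `post_transient` column.
#' @export
simulate_full <- function(cfg, w, stimulus = NULL, v0 = NULL, seed = NULL) {
  stopifnot(inherits(w, "coupling_matrix"), w$n == cfg$n)
  adj <- adjacency_csr(w)
  active <- if (is.null(stimulus)) integer(0) else as.integer(stimulus$active_set - 1L)
  n_steps <- as.integer(round(cfg$t_total / cfg$dt))
  with_seed(seed, {
    if (is.null(v0)) v0 <- init_membrane(cfg)
    res <- simulate_full_cpp(cfg$n, w$n_exc, adj$targets, adj$offsets,
                             active, v0, cfg$v_r, cfg$v_theta, cfg$tau_mem,
                             cfg$j_ext, cfg$j_exc, coupling_inh(cfg),
                             cfg$f_max, cfg$dt, n_steps)
    spikes <- tibble::tibble(time_ms = res$spike_step * cfg$dt,
                             neuron = res$spike_neuron)
    spikes$post_transient <- spikes$time_ms > cfg$t_transient
    new_spike_raster(spikes, res$ext_counts, cfg, "full")
  })
}

#' Simulate in avalanche mode (separation of timescales)
#'
#' Recurrent spikes are delivered instantaneously: within one integration
#' step any threshold crossing triggers a cascade that propagates through
#' successive generations of postsynaptic neurons until no new neuron
#' crosses threshold.  Each cascade is one avalanche of size `s` (distinct
#' neurons fired) and duration `T` (generations); a neuron fires at most
#' once per cascade and is held at `v_r` for its remainder.  External
#' Poisson input continues between cascades.  Requires the reduced
#' configuration in which all neurons are driven.
#'
#' @inheritParams simulate_full
#' @return A list with `raster` (a `spike_raster`, mode `"avalanche"`) and
#'   `avalanches`, a tibble `(time_ms, size, duration, post_transient)`.
#' @export
simulate_avalanche_mode <- function(cfg, w, stimulus = NULL, v0 = NULL,
                                    seed = NULL) {
  stopifnot(inherits(w, "coupling_matrix"), w$n == cfg$n)
  if (cfg$mode != "avalanche")
    stop("cfg must be an avalanche-mode configuration", call. = FALSE)
  adj <- adjacency_csr(w)
  active <- if (is.null(stimulus)) seq_len(cfg$n) - 1L
            else as.integer(stimulus$active_set - 1L)
  n_steps <- as.integer(round(cfg$t_total / cfg$dt))
  with_seed(seed, {
    if (is.null(v0)) v0 <- init_membrane(cfg)
    res <- simulate_avalanche_cpp(cfg$n, w$n_exc, adj$targets, adj$offsets,
                                  active, v0, cfg$v_r, cfg$v_theta,
                                  cfg$tau_mem, cfg$j_ext, cfg$j_exc,
                                  coupling_inh(cfg), cfg$f_max, cfg$dt,
                                  n_steps)
    spikes <- tibble::tibble(time_ms = res$spike_step * cfg$dt,
                             neuron = res$spike_neuron)
    spikes$post_transient <- spikes$time_ms > cfg$t_transient
    raster <- new_spike_raster(spikes, res$ext_counts, cfg, "avalanche")
    av <- tibble::tibble(time_ms = res$av_step * cfg$dt,
                         size = res$av_size, duration = res$av_dur)
    av$post_transient <- av$time_ms > cfg$t_transient
    list(raster = raster, avalanches = av)
  })
}

#' Write or read a spike raster as plain-text tables
#'
#' The store is a pair of gzipped CSVs: `<stem>_spikes.csv.gz` with
#' columns `(time_ms, neuron_id, layer)` for recurrent-layer spikes and
#' `<stem>_ext.csv.gz` with the per-step external delivered-spike counts
#' `(step, count)`, plus a JSON metadata record `<stem>_meta.json` holding
#' the run parameters.  Round-trips exactly.
#'
#' @param raster a `spike_raster`.
#' @param stem path stem (no extension).
#' @return `write_raster()` returns `stem` invisibly; `read_raster()`
#'   returns a `spike_raster`.
#' @export
write_raster <- function(raster, stem) {
  sp <- data.frame(time_ms = raster$spikes$time_ms,
                   neuron_id = raster$spikes$neuron, layer = "v4")
  con <- gzfile(paste0(stem, "_spikes.csv.gz"), "w")
  utils::write.csv(sp, con, row.names = FALSE)
  close(con)
  steps <- which(raster$ext_counts > 0)
  con <- gzfile(paste0(stem, "_ext.csv.gz"), "w")
  utils::write.csv(data.frame(step = steps, count = raster$ext_counts[steps]),
                   con, row.names = FALSE)
  close(con)
  meta <- list(n = raster$n, dt = raster$dt, t_total = raster$t_total,
               t_transient = raster$t_transient, mode = raster$mode,
               n_steps = length(raster$ext_counts))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_raster
#' @param stem path stem used by [write_raster()].
#' @export
read_raster <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  sp <- utils::read.csv(gzfile(paste0(stem, "_spikes.csv.gz")))
  ext <- utils::read.csv(gzfile(paste0(stem, "_ext.csv.gz")))
  ext_counts <- integer(meta$n_steps)
  ext_counts[ext$step] <- ext$count
  spikes <- tibble::tibble(time_ms = sp$time_ms, neuron = as.integer(sp$neuron_id))
  spikes$post_transient <- spikes$time_ms > meta$t_transient
  cfg_like <- list(n = meta$n, dt = meta$dt, t_total = meta$t_total,
                   t_transient = meta$t_transient)
  new_spike_raster(spikes, ext_counts, cfg_like, meta$mode)
}
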