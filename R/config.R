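#' Network and simulation configuration
#'
#' Collects every physiological and numerical parameter of the
#' integrate-and-fire network in one validated object.  Two stock
#' parameter sets are provided: `mode = "full"` is the 2500-neuron network
#' with finite-time (one integration step) recurrent delivery used for the
#' attention experiments, and `mode = "avalanche"` is the reduced
#' 1000-neuron network in which every driven neuron is part of the
#' stimulus subset and recurrent spikes propagate instantaneously as
#' cascades.
#'
#' The inhibitory coupling is never stored: it is always derived as
#' `J_inh = eps * J_exc * j_inh`, with `eps` the excitatory-to-inhibitory
#' count ratio and `j_inh` the dimensionless inhibitory scaling factor.
#'
#' @param mode `"full"` or `"avalanche"`.
#' @param n total neuron count (default 2500 full, 1000 avalanche).
#' @param n_active size of the externally driven subset (default 1000).
#' @param p connection probability of the directed Erdos-Renyi coupling
#'   graph (default 0.02).
#' @param eps excitatory-to-inhibitory count ratio (default 4).
#' @param v_r resting/reset potential, mV (default -60).
#' @param v_theta firing threshold, mV (default -50).
#' @param tau_mem membrane time constant, ms (default 10).
#' @param j_ext external (feedforward) input strength per spike, mV
#'   (default 0.1).
#' @param j_exc excitatory recurrent coupling strength, mV.
#' @param j_inh dimensionless inhibitory scaling factor.
#' @param f_max external Poisson rate per driven neuron, kHz (default 10,
#'   i.e. mean `f_max * dt = 1` spike per neuron per step).
#' @param dt Euler integration step, ms (default 0.1).
#' @param t_total total simulated duration, ms (default 2500 full,
#'   12000 avalanche).
#' @param t_transient initial interval discarded from analysis, ms
#'   (default 500).
#' @param seed integer RNG seed attached to the configuration.
#' @return An object of class `network_config` (a named list).
#' @examples
#' cfg <- network_config(j_exc = 0.2, j_inh = 0.8)
#' coupling_inh(cfg)  # eps * j_exc * j_inh
#' @export
network_config <- function(mode = c("full", "avalanche"),
                           n = NULL, n_active = 1000, p = 0.02, eps = 4,
                           v_r = -60, v_theta = -50, tau_mem = 10,
                           j_ext = 0.1, j_exc = 0.2, j_inh = 0.8,
                           f_max = 10, dt = 0.1,
                           t_total = NULL, t_transient = 500, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n)) n <- if (mode == "full") 2500L else 1000L
  if (is.null(t_total)) t_total <- if (mode == "full") 2500 else 12000
  if (mode == "avalanche") n_active <- n
  cfg <- list(mode = mode, n = as.integer(n), n_active = as.integer(n_active),
              p = p, eps = eps, v_r = v_r, v_theta = v_theta,
              tau_mem = tau_mem, j_ext = j_ext, j_exc = j_exc,
              j_inh = j_inh, f_max = f_max, dt = dt,
              t_total = t_total, t_transient = t_transient,
              seed = as.integer(seed))
  class(cfg) <- "network_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  if (cfg$v_r >= cfg$v_theta)
    stop("v_r must be below v_theta", call. = FALSE)
  if (cfg$tau_mem <= 0 || cfg$dt <= 0 || cfg$t_total <= 0)
    stop("time constants and durations must be positive", call. = FALSE)
  if (cfg$p < 0 || cfg$p > 1)
    stop("connection probability p must lie in [0, 1]", call. = FALSE)
  if (cfg$n_active > cfg$n)
    stop("n_active cannot exceed n", call. = FALSE)
  if (cfg$n %% (1 + cfg$eps) != 0)
    stop("n must be divisible by 1 + eps so the E/I split is exact",
         call. = FALSE)
  if (cfg$mode == "avalanche" && cfg$n_active != cfg$n)
    stop("avalanche mode requires n_active == n", call. = FALSE)
  cfg
}

#' @rdname network_config
#' @param cfg a `network_config`.
#' @export
coupling_inh <- function(cfg) cfg$eps * cfg$j_exc * cfg$j_inh

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config: %s mode>\n", x$mode))
  cat(sprintf("  N = %d (%d driven), p = %g, eps = %g\n",
              x$n, x$n_active, x$p, x$eps))
  cat(sprintf("  V_R = %g mV, V_theta = %g mV, tau_mem = %g ms\n",
              x$v_r, x$v_theta, x$tau_mem))
  cat(sprintf("  J_ext = %g mV, J_exc = %g mV, j_inh = %g (J_inh = %g mV)\n",
              x$j_ext, x$j_exc, x$j_inh, coupling_inh(x)))
  cat(sprintf("  f_max = %g kHz, dt = %g ms, T = %g ms (transient %g ms)\n",
              x$f_max, x$dt, x$t_total, x$t_transient))
  invisible(x)
}

#' Read and write configurations as key: value files
#'
#' The on-disk format is YAML with one entry per [network_config()] field,
#' so a configuration file maps one-to-one onto the object.  `overrides`
#' (e.g. parsed from command-line flags) replace any key after reading.
#'
#' @param path file path.
#' @param cfg a `network_config`.
#' @param overrides named list of fields to replace after reading.
#' @return `read_config()` returns a `network_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "network_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files", call. = FALSE)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files", call. = FALSE)
  vals <- utils::modifyList(yaml::read_yaml(path), overrides)
  do.call(network_config, vals)
}
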