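#' Population-rate oscillation strength of a raster
#'
#' Bins the post-transient population spike count (default 1 ms bins) and
#' returns the largest autocorrelation at lags of 3 ms or more — near zero
#' for asynchronous firing and increasingly positive as gamma-band
#' collective oscillations emerge.
#'
#' @param raster a `spike_raster`.
#' @param bin_ms bin width, ms.
#' @param max_lag_ms largest lag examined, ms.
#' @return Scalar oscillation strength.
#' @export
oscillation_strength <- function(raster, bin_ms = 1, max_lag_ms = 50) {
  sp <- raster$spikes[raster$spikes$post_transient, ]
  n_bins <- as.integer((raster$t_total - raster$t_transient) / bin_ms)
  if (nrow(sp) < 2 || n_bins < 10) return(0)
  counts <- tabulate(pmin(as.integer((sp$time_ms - raster$t_transient) / bin_ms) + 1L,
                          n_bins), nbins = n_bins)
  if (sd(counts) == 0) return(0)
  lag_max <- as.integer(max_lag_ms / bin_ms)
  a <- stats::acf(counts, lag.max = lag_max, plot = FALSE)$acf[-1]
  lags <- seq_along(a) * bin_ms
  max(a[lags >= 3])
}

#' Gamma-band peak prominence of a power spectrum
#'
#' Fits a log-log linear (1/f-type) trend to the spectrum outside the
#' gamma band and returns the largest in-band power excess over that
#' trend.  Values near 1 mean no peak; a clear gamma peak rises severalfold
#' above the background.
#'
#' @param spectrum a `power_spectrum` tibble (or any tibble with
#'   `freq_hz`, `power`).
#' @param band gamma band, Hz.
#' @return List with `excess` (max in-band power / trend ratio) and
#'   `freq_hz` (its frequency).
#' @export
gamma_peak_prominence <- function(spectrum, band = c(35, 80)) {
  f <- spectrum$freq_hz; p <- spectrum$power
  ok <- is.finite(p) & p > 0
  f <- f[ok]; p <- p[ok]
  in_band <- f >= band[1] & f <= band[2]
  if (!any(in_band) || sum(!in_band) < 3)
    return(list(excess = NA_real_, freq_hz = NA_real_))
  co <- stats::coef(stats::lm(log(p[!in_band]) ~ log(f[!in_band])))
  trend <- exp(co[1] + co[2] * log(f[in_band]))
  ratio <- p[in_band] / trend
  list(excess = max(ratio), freq_hz = f[in_band][which.max(ratio)])
}

#' Auto-tune the excitatory coupling to the operating point
#'
#' The operating regime of the attention experiments is marginally
#' subcritical: gamma-band oscillations have just emerged above the 1/f
#' background while stimulus-nonspecific neurons remain silent.  This
#' routine scans an increasing grid of `J_exc` values with short
#' full-model probe simulations in the non-attended condition and returns
#' the smallest grid value whose stimulus-averaged LFP spectrum shows a
#' gamma-band peak rising at least `min_excess`-fold above the fitted 1/f
#' trend — the onset of collective synchrony — subject to the
#' physiological exclusion rule: the mean firing rate of undriven neurons
#' must stay below `undriven_max_hz` in both the non-attended and the
#' attended condition.
#'
#' The peak prominence of a single architecture fluctuates considerably
#' (individual architectures plateau anywhere between roughly 2.5- and
#' 4-fold), so the probe averages spectra over `n_arch` architecture
#' realisations; the architecture family, not the trial noise, dominates
#' the variance of the excess estimate.
#' If no grid value reaches `min_excess`, the selection falls back to the
#' onset of the profile's own plateau: the smallest value whose excess
#' reaches 90 percent of the profile maximum (synchrony has stopped
#' strengthening there, so the peak has emerged as far as this
#' architecture family allows).
#'
#' An alternative `method = "reduced"` locates the border as the smallest
#' grid value whose reduced-model mean supercriticality indicator exceeds
#' zero; because the full network recruits its undriven pool well below
#' the reduced model's cascade transition, that rule lands in the
#' excluded epileptic regime of the full model and is provided for
#' phase-space exploration only.
#'
#' @param j_inh inhibitory scaling factor of the non-attended condition
#'   (default 0.80).
#' @param j_inh_attended attended-condition scaling factor checked
#'   against the exclusion rule (default 0.72).
#' @param j_exc_grid increasing grid of excitatory couplings, mV.
#' @param cfg full-model configuration template (`method = "full"`) or
#'   reduced template (`method = "reduced"`).
#' @param n_stimuli,n_trials probe design per grid value (full method).
#' @param min_excess gamma-peak prominence threshold (default 3).
#' @param undriven_max_hz exclusion threshold, Hz (default 1).
#' @param n_arch architecture realisations averaged per grid value.
#' @param method `"full"` (default) or `"reduced"`.
#' @param seed master seed.
#' @return A list with `j_exc` (the tuned value) and `profile`, a tibble
#'   of the per-grid-value diagnostics.
#' @export
tune_operating_point <- function(j_inh = 0.80, j_inh_attended = 0.72,
                                 j_exc_grid = seq(0.2, 0.6, by = 0.05),
                                 cfg = NULL,
                                 n_stimuli = 4, n_trials = 1,
                                 min_excess = 3, undriven_max_hz = 1,
                                 n_arch = 3,
                                 method = c("full", "reduced"),
                                 seed = 1L) {
  stopifnot(!is.unsorted(j_exc_grid))
  method <- match.arg(method)
  if (method == "reduced") {
    if (is.null(cfg)) cfg <- network_config("avalanche")
    gamma_mean <- numeric(0)
    for (g in seq_along(j_exc_grid)) {
      gs <- vapply(seq_len(n_arch), function(a) {
        cfg_g <- cfg; cfg_g$j_exc <- j_exc_grid[g]; cfg_g$j_inh <- j_inh
        w <- build_coupling(cfg$n, cfg$p, cfg$eps,
                            seed = derive_seed(seed, 1L, a))
        run <- simulate_avalanche_mode(cfg_g, w,
                                       seed = derive_seed(seed, 2L, a, g))
        as.numeric(criticality_fit(collect_avalanches(run), cfg$n)$gamma)
      }, numeric(1))
      gamma_mean[g] <- mean(gs, na.rm = TRUE)
      if (gamma_mean[g] > 0)
        return(list(j_exc = j_exc_grid[g],
                    profile = tibble::tibble(j_exc = j_exc_grid[seq_len(g)],
                                             gamma_mean = gamma_mean)))
    }
    warning("no grid value crossed the subcritical border; returning the largest")
    return(list(j_exc = j_exc_grid[length(j_exc_grid)],
                profile = tibble::tibble(j_exc = j_exc_grid,
                                         gamma_mean = gamma_mean)))
  }

  if (is.null(cfg)) cfg <- network_config("full")
  archs <- lapply(seq_len(n_arch), function(a) list(
    w = build_coupling(cfg$n, cfg$p, cfg$eps, seed = derive_seed(seed, 1L, a)),
    stimuli = draw_stimulus_set(cfg$n, cfg$n_active, n_stimuli,
                                seed = derive_seed(seed, 2L, a))))

  # probe one (grid value, condition): mean undriven rate and, for the
  # non-attended condition, the architecture-averaged spectrum
  probe <- function(g, cond) {
    jx <- j_exc_grid[g]
    und <- numeric(0); pow <- NULL
    for (a in seq_len(n_arch)) {
      cfg_c <- cfg
      cfg_c$j_exc <- jx
      cfg_c$j_inh <- if (cond == "non") j_inh else j_inh_attended
      for (s in seq_len(n_stimuli)) for (tr in seq_len(n_trials)) {
        r <- simulate_full(cfg_c, archs[[a]]$w, archs[[a]]$stimuli[[s]],
                           seed = derive_seed(seed, 5L, a, g, s, tr,
                                              match(cond, c("non", "att"))))
        sp <- r$spikes[r$spikes$post_transient, ]
        out_set <- setdiff(seq_len(cfg$n), archs[[a]]$stimuli[[s]]$active_set)
        und <- c(und, sum(sp$neuron %in% out_set) /
                   (length(out_set) * (cfg$t_total - cfg$t_transient) / 1000))
        if (cond == "non") {
          spec <- lfp_spectrum(generate_lfp(r, c_mix = 0.2))
          pow <- if (is.null(pow)) spec$power else pow + spec$power
        }
      }
    }
    list(undriven = mean(und),
         power = if (!is.null(pow)) pow / (n_arch * n_stimuli * n_trials))
  }

  prof <- purrr::map_dfr(seq_along(j_exc_grid), function(g) {
    p <- probe(g, "non")
    peak <- gamma_peak_prominence(
      tibble::tibble(freq_hz = log_freqs(), power = p$power))
    tibble::tibble(j_exc = j_exc_grid[g], gamma_excess = peak$excess,
                   peak_freq_hz = peak$freq_hz, undriven_non = p$undriven)
  })

  usable <- is.finite(prof$gamma_excess) &
    prof$undriven_non < undriven_max_hz
  candidates <- which(usable & prof$gamma_excess >= min_excess)
  if (length(candidates) == 0) {
    warning("no grid value reached the gamma-peak threshold; ",
            "falling back to the plateau onset of the excess profile")
    plateau <- 0.9 * max(prof$gamma_excess[usable])
    candidates <- which(usable & prof$gamma_excess >= plateau)
  }
  pick <- NA_real_
  att_rates <- rep(NA_real_, nrow(prof))
  for (g in candidates) {     # ascending: smallest qualifying value first
    att <- probe(g, "att")
    att_rates[g] <- att$undriven
    if (att$undriven < undriven_max_hz) {
      pick <- j_exc_grid[g]
      break
    }
  }
  if (is.na(pick)) {
    warning("all candidates excluded in the attended condition; ",
            "returning the smallest grid value")
    pick <- j_exc_grid[1]
  }
  prof$undriven_att <- att_rates
  prof$selected <- prof$j_exc == pick
  list(j_exc = pick, profile = prof)
}

full_trial_spectra <- function(cfg, w, stimuli, n_trials, c_mix_values,
                               freqs, seed, arch_id) {
  rows <- list(); undriven <- numeric(0)
  for (s in seq_along(stimuli)) {
    for (tr in seq_len(n_trials)) {
      raster <- simulate_full(cfg, w, stimuli[[s]],
                              seed = derive_seed(seed, arch_id, s, tr))
      sp <- raster$spikes[raster$spikes$post_transient, ]
      out_set <- setdiff(seq_len(cfg$n), stimuli[[s]]$active_set)
      undriven <- c(undriven,
                    sum(sp$neuron %in% out_set) /
                      (length(out_set) * (cfg$t_total - cfg$t_transient) / 1000))
      for (cm in c_mix_values) {
        spec <- lfp_spectrum(generate_lfp(raster, c_mix = cm), freqs)
        rows[[length(rows) + 1L]] <-
          dplyr::mutate(spec, stimulus = s, trial = tr, c_mix = cm)
      }
    }
  }
  list(spectra = dplyr::bind_rows(rows), undriven_rate_hz = mean(undriven))
}

#' Full-model attention contrast
#'
#' Runs the full 2500-neuron model at two inhibitory scaling factors —
#' non-attended and attended, attention being a global reduction of
#' inhibitory efficacy — with shared architectures, stimulus sets and
#' simulation seeds, and quantifies single-trial stimulus decodability of
#' the resulting LFP spectra by leave-one-out linear SVM accuracy and by
#' the discriminability index.  Spectra are computed for each requested
#' background-noise mixing constant from the same network runs.
#'
#' Grid points where stimulus-nonspecific neurons become persistently
#' active (mean undriven-neuron rate above `undriven_max_hz`) are flagged
#' `excluded` in the results, as such epileptic regimes are outside the
#' physiological scope of the model.
#'
#' @param j_exc excitatory coupling, mV (see [tune_operating_point()]).
#' @param j_inh_nonattended,j_inh_attended inhibitory scaling factors of
#'   the two conditions (defaults 0.80 and 0.72).
#' @param cfg full-model configuration template.
#' @param n_arch number of coupling-matrix realisations.
#' @param n_stimuli,n_trials design size per architecture.
#' @param c_mix_values mixing constants at which spectra are evaluated.
#' @param freqs analysis frequencies.
#' @param undriven_max_hz exclusion threshold on the mean firing rate of
#'   undriven neurons, Hz.
#' @param seed master seed.
#' @return A list of class `attention_contrast`: `results`, a tibble with
#'   one row per (condition, c_mix, architecture) carrying
#'   `svm_accuracy`, `di`, `gamma_band_power`, `undriven_rate_hz` and
#'   `excluded`; `summary`, the architecture-averaged tibble; and
#'   `spectra`, the full long table.
#' @export
run_attention_contrast <- function(j_exc,
                                   j_inh_nonattended = 0.80,
                                   j_inh_attended = 0.72,
                                   cfg = network_config("full", j_exc = j_exc),
                                   n_arch = 5, n_stimuli = 6, n_trials = 20,
                                   c_mix_values = c(0.2, 0),
                                   freqs = log_freqs(),
                                   undriven_max_hz = 1,
                                   seed = 1L) {
  conds <- tibble::tibble(condition = c("non_attended", "attended"),
                          j_inh = c(j_inh_nonattended, j_inh_attended))
  res <- list(); all_spec <- list()
  for (a in seq_len(n_arch)) {
    w <- build_coupling(cfg$n, cfg$p, cfg$eps, seed = derive_seed(seed, 1L, a))
    stimuli <- draw_stimulus_set(cfg$n, cfg$n_active, n_stimuli,
                                 seed = derive_seed(seed, 2L, a))
    for (ci in seq_len(nrow(conds))) {
      cfg_c <- cfg
      cfg_c$j_exc <- j_exc
      cfg_c$j_inh <- conds$j_inh[ci]
      # identical per-(arch, stimulus, trial) seeds across conditions
      out <- full_trial_spectra(cfg_c, w, stimuli, n_trials, c_mix_values,
                                freqs, seed, a)
      for (cm in c_mix_values) {
        spec <- dplyr::filter(out$spectra, .data$c_mix == cm)
        di <- discriminability_index(spec)
        acc <- svm_loo_accuracy(spec, seed = derive_seed(seed, 3L, a, ci))
        gb <- mean(vapply(split(spec, interaction(spec$stimulus, spec$trial)),
                          band_power, numeric(1)))
        res[[length(res) + 1L]] <- tibble::tibble(
          condition = conds$condition[ci], j_inh = conds$j_inh[ci],
          j_exc = j_exc, c_mix = cm, arch = a,
          svm_accuracy = acc, di = di$di, gamma_band_power = gb,
          undriven_rate_hz = out$undriven_rate_hz,
          excluded = out$undriven_rate_hz > undriven_max_hz)
        all_spec[[length(all_spec) + 1L]] <-
          dplyr::mutate(spec, condition = conds$condition[ci], arch = a)
      }
    }
  }
  results <- dplyr::bind_rows(res)
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$condition, .data$j_inh, .data$c_mix),
    svm_accuracy = mean(.data$svm_accuracy), di = mean(.data$di),
    gamma_band_power = mean(.data$gamma_band_power),
    undriven_rate_hz = mean(.data$undriven_rate_hz),
    excluded = any(.data$excluded), .groups = "drop")
  out <- list(results = results, summary = summary,
              spectra = dplyr::bind_rows(all_spec),
              n_arch = n_arch, n_stimuli = n_stimuli, n_trials = n_trials,
              seed = seed)
  class(out) <- "attention_contrast"
  out
}

#' @export
print.attention_contrast <- function(x, ...) {
  cat("<attention_contrast>\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

reduced_point <- function(j_exc, j_inh, cfg, n_arch, n_trials, k_ladder,
                          channel_orders, freqs, seed, keep_avalanches) {
  per_arch <- list(); spec_rows <- list(); ent_rows <- list()
  avalanches <- if (keep_avalanches) list() else NULL
  for (a in seq_len(n_arch)) {
    cfg_p <- cfg; cfg_p$j_exc <- j_exc; cfg_p$j_inh <- j_inh
    w <- build_coupling(cfg$n, cfg$p, cfg$eps, seed = derive_seed(seed, 1L, a))
    run <- simulate_avalanche_mode(
      cfg_p, w,
      seed = derive_seed(seed, 4L, a,
                         as.integer(round(j_exc * 1e5)),
                         as.integer(round(j_inh * 1e5))))
    av <- collect_avalanches(run)
    fit <- criticality_fit(av, cfg$n)
    osc <- oscillation_strength(run$raster)

    lfp <- generate_lfp(run$raster, c_mix = 0)
    trials <- split_lfp(lfp, n_trials)
    for (tr in seq_along(trials)) {
      spec <- lfp_spectrum(trials[[tr]], freqs)
      spec_rows[[length(spec_rows) + 1L]] <-
        dplyr::mutate(spec, stimulus = a, trial = tr)
    }
    for (k in k_ladder) {
      h <- pattern_entropy(coarse_grain(run$raster, k, channel_orders[[a]]))
      ent_rows[[length(ent_rows) + 1L]] <-
        tibble::tibble(arch = a, k = k, h_bits = h)
    }
    per_arch[[a]] <- dplyr::mutate(fit, arch = a, oscillation = osc)
    if (keep_avalanches) avalanches[[a]] <- av
  }
  spectra <- dplyr::bind_rows(spec_rows)
  di <- if (n_arch >= 2) discriminability_index(spectra)$di else NA_real_
  list(per_arch = dplyr::bind_rows(per_arch),
       entropy = dplyr::bind_rows(ent_rows), di = di,
       avalanches = avalanches)
}

#' Sweep the excitatory/inhibitory coupling plane (reduced model)
#'
#' At every grid point, simulates `n_arch` reduced avalanche-mode networks
#' (distinct architectures standing for distinct stimuli), fits the
#' avalanche criticality statistics, computes the discriminability index
#' of the segmented LFP spectra across architectures, and the
#' coarse-grained pattern entropy for each observation scale in
#' `k_ladder`.  Architectures, their entropy channel orders, and per-point
#' simulation seeds all derive deterministically from the master seed, so
#' the sweep is reproducible and order-independent.
#'
#' @param j_exc_values,j_inh_values grid axes (mV, dimensionless).
#' @param cfg reduced-model configuration template.
#' @param n_arch architectures (= stimuli) per point.
#' @param n_trials LFP segments per run used as trials.
#' @param k_ladder observation scales for entropy; every value must
#'   divide `cfg$n`.
#' @param freqs spectral analysis frequencies.
#' @param seed master seed.
#' @param keep_avalanches retain the per-point avalanche lists (needed
#'   for bootstrap analyses).
#' @return An object of class `scan_grid`: list with `points` (one row
#'   per grid point: `gamma_mean`, `ks_d_mean`, `di`, mean exponents,
#'   `oscillation`), `per_arch`, `entropy` (long over `k`), and
#'   optionally `avalanches`.
#' @export
run_coupling_sweep <- function(j_exc_values, j_inh_values,
                               cfg = network_config("avalanche"),
                               n_arch = 5, n_trials = 36,
                               k_ladder = c(1, 2, 5, 10, 50, 100, 250, 500, 1000),
                               freqs = log_freqs(),
                               seed = 1L, keep_avalanches = FALSE) {
  stopifnot(length(j_exc_values) > 0, length(j_inh_values) > 0)
  if (any(cfg$n %% k_ladder != 0))
    stop("every k in k_ladder must divide cfg$n", call. = FALSE)
  channel_orders <- lapply(seq_len(n_arch), function(a)
    with_seed(derive_seed(seed, 3L, a), sample.int(cfg$n)))
  grid <- tidyr::expand_grid(j_exc = j_exc_values, j_inh = j_inh_values)
  pts <- list(); per_arch <- list(); ent <- list()
  avalanches <- if (keep_avalanches) list() else NULL
  for (g in seq_len(nrow(grid))) {
    p <- reduced_point(grid$j_exc[g], grid$j_inh[g], cfg, n_arch, n_trials,
                       k_ladder, channel_orders, freqs, seed,
                       keep_avalanches)
    pa <- dplyr::mutate(p$per_arch, j_exc = grid$j_exc[g],
                        j_inh = grid$j_inh[g])
    pts[[g]] <- tibble::tibble(
      j_exc = grid$j_exc[g], j_inh = grid$j_inh[g],
      gamma_mean = mean(pa$gamma, na.rm = TRUE),
      ks_d_mean = mean(pa$ks_d, na.rm = TRUE),
      tau_mean = mean(pa$tau_hat, na.rm = TRUE),
      alpha_mean = mean(pa$alpha_hat, na.rm = TRUE),
      inv_snz_mean = mean(pa$inv_snz, na.rm = TRUE),
      oscillation = mean(pa$oscillation), di = p$di)
    per_arch[[g]] <- pa
    ent[[g]] <- dplyr::mutate(p$entropy, j_exc = grid$j_exc[g],
                              j_inh = grid$j_inh[g])
    if (keep_avalanches) avalanches[[g]] <- p$avalanches
  }
  out <- list(points = dplyr::bind_rows(pts),
              per_arch = dplyr::bind_rows(per_arch),
              entropy = dplyr::bind_rows(ent),
              avalanches = avalanches, n_arch = n_arch, seed = seed,
              grid = grid)
  class(out) <- "scan_grid"
  out
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid: %d points x %d architectures>\n",
              nrow(x$points), x$n_arch))
  print(as.data.frame(x$points))
  invisible(x)
}

#' Locate the transition region of a sweep
#'
#' The transition region is the set of grid points at which the
#' stimulus-averaged supercriticality indicator lies strictly between 0
#' and 1 — subcritical for some architectures, supercritical for others.
#'
#' @param scan a `scan_grid`.
#' @return Tibble `(j_exc, j_inh, gamma_mean, in_transition)`.
#' @export
locate_transition_region <- function(scan) {
  stopifnot(inherits(scan, "scan_grid"))
  dplyr::mutate(
    dplyr::select(scan$points, "j_exc", "j_inh", "gamma_mean"),
    in_transition = .data$gamma_mean > 0 & .data$gamma_mean < 1)
}

#' Per-inhibition entropy maxima across the sweep
#'
#' For each observation scale `K` and each inhibitory scaling factor,
#' finds the excitatory coupling that maximises the architecture-averaged
#' pattern entropy.
#'
#' @param scan a `scan_grid`.
#' @return Tibble `(j_inh, k, j_exc_max, h_bits)`.
#' @export
entropy_maxima <- function(scan) {
  stopifnot(inherits(scan, "scan_grid"))
  h <- dplyr::summarise(
    dplyr::group_by(scan$entropy, .data$j_exc, .data$j_inh, .data$k),
    h_bits = mean(.data$h_bits), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(h, .data$j_inh, .data$k),
    j_exc_max = .data$j_exc[which.max(.data$h_bits)],
    h_bits = max(.data$h_bits), .groups = "drop")
}
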