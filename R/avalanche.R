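#' Hurwitz zeta function
#'
#' `zeta(tau, a) = sum_{k >= 0} (k + a)^(-tau)`, the normalising constant
#' of the discrete power law on `{a, a + 1, ...}`.  Evaluated by a partial
#' sum of `m` terms plus the Euler-Maclaurin tail correction; with the
#' default `m` the absolute error is far below 1e-12 for `tau >= 1.05`.
#' Vectorised over `tau`.
#'
#' @param tau exponent(s), `> 1`.
#' @param a offset, `> 0`.
#' @param m number of explicit terms.
#' @return Numeric vector of the same length as `tau`.
#' @export
hurwitz_zeta <- function(tau, a, m = 2000L) {
  stopifnot(all(tau > 1), a > 0)
  k <- 0:(m - 1)
  lk <- log(k + a)
  head_sum <- as.numeric(exp(-outer(lk, tau)) |> colSums())
  b <- m + a
  tail_sum <- b^(1 - tau) / (tau - 1) + 0.5 * b^(-tau) +
    tau * b^(-tau - 1) / 12 -
    tau * (tau + 1) * (tau + 2) * b^(-tau - 3) / 720
  head_sum + tail_sum
}

.zeta_cache <- new.env(parent = emptyenv())

#' Collect avalanches from an avalanche-mode run
#'
#' Filters the cascade records of [simulate_avalanche_mode()] to the
#' analysis window: events at or before the transient are excluded.
#'
#' @param run the list returned by [simulate_avalanche_mode()] (or its
#'   `avalanches` tibble together with `raster`).
#' @return A tibble `(time_ms, size, duration)` of class `avalanche_list`
#'   with attribute `n_system`.
#' @export
collect_avalanches <- function(run) {
  if (is.null(run$avalanches) || is.null(run$raster))
    stop("expected the output of simulate_avalanche_mode()", call. = FALSE)
  if (!identical(run$raster$mode, "avalanche"))
    stop("avalanche bookkeeping is undefined for full-mode rasters",
         call. = FALSE)
  av <- dplyr::filter(run$avalanches, .data$post_transient)
  out <- dplyr::select(av, "time_ms", "size", "duration")
  attr(out, "n_system") <- run$raster$n
  class(out) <- c("avalanche_list", class(out))
  out
}

#' Discrete power-law maximum-likelihood exponent
#'
#' Restricts the samples to the window `[x_min, x_max]` and maximises the
#' discrete power-law log-likelihood
#' `L(tau) = -n log Z(tau) - tau sum(log x_i)` over a dense
#' exponent grid (default `[1.1, 4]` in steps of 0.001; ties break toward
#' the smaller exponent).  With the default `normalization = "tail"` the
#' constant is the Hurwitz zeta at `x_min` over the unbounded support —
#' the upper cut-off only windows the data, which stabilises the estimate
#' against supercritical tail bumps (the avalanche pipeline's convention).
#' With `normalization = "window"` the constant is
#' `zeta(tau, x_min) - zeta(tau, x_max + 1)`, the matched normalisation
#' for samples that genuinely live on the finite window; only this
#' variant is a consistent estimator for truncated power-law draws.
#'
#' @param x integer-valued samples (sizes or durations).
#' @param x_min,x_max window cut-offs.
#' @param grid exponent grid to search.
#' @param normalization `"tail"` (default) or `"window"`.
#' @return A list of class `powerlaw_fit`: `exponent`, `n` (samples in
#'   window), `x_min`, `x_max`, `valid`.
#' @export
fit_powerlaw_ml <- function(x, x_min, x_max,
                            grid = seq(1.1, 4, by = 0.001),
                            normalization = c("tail", "window")) {
  normalization <- match.arg(normalization)
  xs <- x[x >= x_min & x <= x_max]
  if (length(xs) == 0)
    return(structure(list(exponent = NA_real_, n = 0L, x_min = x_min,
                          x_max = x_max, valid = FALSE),
                     class = "powerlaw_fit"))
  slog <- sum(log(xs))
  key <- sprintf("%s_%.6g_%.6g_%d_%.6g_%.6g", normalization, grid[1],
                 grid[length(grid)], length(grid), x_min,
                 if (normalization == "window") x_max else Inf)
  lz <- .zeta_cache[[key]]
  if (is.null(lz)) {
    lz <- if (normalization == "tail") log(hurwitz_zeta(grid, x_min))
          else log(hurwitz_zeta(grid, x_min) - hurwitz_zeta(grid, x_max + 1))
    .zeta_cache[[key]] <- lz
  }
  ll <- -length(xs) * lz - grid * slog
  structure(list(exponent = grid[which.max(ll)], n = length(xs),
                 x_min = x_min, x_max = x_max, valid = TRUE),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<powerlaw_fit: exponent %.3f on [%g, %g], n = %d>\n",
                x$exponent, x$x_min, x$x_max, x$n))
  else cat("<powerlaw_fit: invalid (no samples in window)>\n")
  invisible(x)
}

#' @rdname fit_powerlaw_ml
#' @param durations avalanche durations (generation counts).
#' @param t_min,t_max duration window (defaults 5 and 30).
#' @export
fit_duration_exponent <- function(durations, t_min = 5, t_max = 30,
                                  grid = seq(1.1, 4, by = 0.001),
                                  normalization = c("tail", "window")) {
  fit_powerlaw_ml(durations, t_min, t_max, grid, normalization)
}

#' Growth exponent of mean avalanche size with duration
#'
#' Computes `<s>(T)` for every duration in the window with at least one
#' event, then the least-squares slope of `ln <s>` against `ln T` via the
#' closed-form normal equation — the exponent `1/(sigma nu z)` of
#' `<s>(T) ~ T^(1/sigma nu z)`.
#'
#' @param events avalanche tibble with columns `size` and `duration`.
#' @param t_min,t_max duration window (defaults 2 and 20).
#' @return List of class `snz_fit`: `exponent`, `n_points`, `valid`.
#' @export
fit_mean_size_given_duration <- function(events, t_min = 2, t_max = 20) {
  ev <- events[events$duration >= t_min & events$duration <= t_max, ]
  if (nrow(ev) == 0 || length(unique(ev$duration)) < 2)
    return(structure(list(exponent = NA_real_, n_points = 0L, valid = FALSE),
                     class = "snz_fit"))
  ms <- dplyr::summarise(dplyr::group_by(ev, .data$duration),
                         mean_size = mean(.data$size), .groups = "drop")
  lt <- log(ms$duration); ls <- log(ms$mean_size); m <- length(lt)
  slope <- (m * sum(lt * ls) - sum(lt) * sum(ls)) /
    (m * sum(lt^2) - sum(lt)^2)
  structure(list(exponent = slope, n_points = m, valid = TRUE),
            class = "snz_fit")
}

#' Power-law model CDF
#'
#' CDF at integer `s` of the discrete power law with exponent `tau`
#' normalised over `{s_min, s_min + 1, ...}`:
#' `F_fit(s) = 1 - zeta(tau, s + 1) / zeta(tau, s_min)`; 0 below `s_min`.
#'
#' @param s integer evaluation points.
#' @param tau exponent.
#' @param s_min lower support bound.
#' @return Numeric vector of CDF values.
#' @export
powerlaw_cdf <- function(s, tau, s_min) {
  s <- floor(s)
  z0 <- hurwitz_zeta(tau, s_min)
  smax <- max(s, s_min)
  # zeta(tau, a + 1) = zeta(tau, a) - a^(-tau): one pass up the support
  supp <- s_min:smax
  zs <- z0 - cumsum(supp^(-tau))             # zeta(tau, s + 1) for s in supp
  f <- c(0, 1 - zs / z0)                     # prepend F(s_min - 1) = 0
  idx <- pmax(pmin(s, smax), s_min - 1) - (s_min - 1) + 1
  out <- f[idx]
  out[s < s_min] <- 0
  out
}

# Empirical CDF of the tail sample {s_i >= s_min}: P(S <= s | S >= s_min).
# The goodness-of-fit comparison conditions both distributions on the
# fitted support, as is standard for power-law tails; the unconditional
# CDF would saturate the discrepancy with the (never fitted) mass below
# the cut-off.
empirical_cdf <- function(sizes, s, s_min = -Inf) {
  tail_s <- sizes[sizes >= s_min]
  if (length(tail_s) == 0) return(rep(NA_real_, length(s)))
  stats::ecdf(tail_s)(floor(s))
}

#' Kolmogorov-Smirnov statistic of an avalanche size power-law fit
#'
#' `D = max_{s >= N/100} |F(s) - F_fit(s)|` where `F` is the empirical
#' CDF of the observed sizes conditioned on `s >= s_min` (the standard
#' convention when fitting a power law above a cut-off) and `F_fit` the
#' fitted power-law CDF normalised over `[s_min, Inf)`; both are
#' right-continuous step functions evaluated at integer `s` from
#' `floor(N/100)` to `N`.
#'
#' @param sizes observed avalanche sizes; alternatively supply `f_emp`.
#' @param tau fitted exponent (ignored when `f_fit` is supplied).
#' @param n_system system size `N`.
#' @param s_min fit lower cut-off (default `floor(N/100)`).
#' @param f_emp,f_fit optional CDF functions of integer `s`, overriding
#'   the empirical/model CDFs.
#' @return `D` in `[0, 1]`.
#' @export
ks_statistic <- function(sizes = NULL, tau = NULL, n_system,
                         s_min = max(1, floor(n_system / 100)),
                         f_emp = NULL, f_fit = NULL) {
  if (is.null(f_emp)) f_emp <- function(s) empirical_cdf(sizes, s, s_min)
  if (is.null(f_fit)) f_fit <- function(s) powerlaw_cdf(s, tau, s_min)
  s <- s_min:n_system
  d <- abs(f_emp(s) - f_fit(s))
  if (all(is.na(d))) return(NA_real_)
  max(d)
}

#' Supercriticality indicator of an avalanche size distribution
#'
#' Classifies the distribution as supercritical (`1`) when the empirical
#' tail mass beyond `0.6 N` exceeds that of the fitted power law after the
#' fit is rescaled to match the empirical CDF at `N/100`:
#' `gamma = 1` iff `F(N) - F(0.6N - 1) > F'_fit(N) - F'_fit(0.6N - 1)`
#' with `F'_fit(s) = F_fit(s) * F(N/100) / F_fit(N/100)` (strict
#' inequality; non-integer arguments are floored; `F` conditioned on
#' `s >= s_min` as in [ks_statistic()]).  Otherwise `0` (subcritical).
#'
#' @param sizes observed avalanche sizes; alternatively supply `f_emp`.
#' @param tau fitted exponent (ignored when `f_fit` is supplied).
#' @param n_system system size `N`.
#' @param s_min fit lower cut-off (default `floor(N/100)`).
#' @param f_emp,f_fit optional CDF functions of integer `s`, overriding
#'   the empirical/model CDFs.
#' @return `0` or `1`.
#' @export
gamma_indicator <- function(sizes = NULL, tau = NULL, n_system,
                            s_min = max(1, floor(n_system / 100)),
                            f_emp = NULL, f_fit = NULL) {
  if (is.null(f_emp)) f_emp <- function(s) empirical_cdf(sizes, s, s_min)
  if (is.null(f_fit)) f_fit <- function(s) powerlaw_cdf(s, tau, s_min)
  ref <- f_fit(s_min)
  if (!is.finite(ref) || ref <= 0)
    stop("fitted CDF vanishes at the reference point N/100", call. = FALSE)
  scale <- f_emp(s_min) / ref
  lo <- floor(0.6 * n_system - 1)
  emp_tail <- f_emp(n_system) - f_emp(lo)
  fit_tail <- scale * (f_fit(n_system) - f_fit(lo))
  as.integer(emp_tail > fit_tail)
}

#' Residual of the crackling-noise scaling relation
#'
#' The universal scaling theory of avalanches links the three exponents by
#' `(alpha - 1) / (tau - 1) = 1 / (sigma nu z)`; the residual is the left
#' side minus the right side.
#'
#' @param tau size exponent (`!= 1`).
#' @param alpha duration exponent.
#' @param inv_snz growth exponent of `<s>(T)`.
#' @return Scalar residual.
#' @export
scaling_relation_residual <- function(tau, alpha, inv_snz) {
  if (any(tau == 1)) stop("scaling relation undefined at tau = 1", call. = FALSE)
  (alpha - 1) / (tau - 1) - inv_snz
}

#' Full criticality characterisation of one avalanche list
#'
#' Runs the whole fitting chain on one network/coupling point: ML size
#' exponent on `[N/100, 0.6N]`, ML duration exponent on `[5, 30]`,
#' least-squares `<s>(T)` exponent on `[2, 20]`, the KS statistic `D` and
#' the supercriticality flag `gamma`.
#'
#' @param avalanches an `avalanche_list` (or tibble with `size`,
#'   `duration`) from [collect_avalanches()].
#' @param n_system system size `N`; defaults to the list's attribute.
#' @return A one-row tibble of class `criticality_fit` with columns
#'   `tau_hat`, `alpha_hat`, `inv_snz`, `ks_d`, `gamma`, `n_events`, and
#'   the cut-offs used.
#' @export
criticality_fit <- function(avalanches, n_system = attr(avalanches, "n_system")) {
  if (is.null(n_system)) stop("n_system required", call. = FALSE)
  s_min <- max(1, floor(n_system / 100)); s_max <- floor(0.6 * n_system)
  size_fit <- fit_powerlaw_ml(avalanches$size, s_min, s_max)
  dur_fit <- fit_duration_exponent(avalanches$duration)
  snz <- fit_mean_size_given_duration(avalanches)
  d <- if (size_fit$valid)
    ks_statistic(avalanches$size, size_fit$exponent, n_system, s_min)
  else NA_real_
  g <- if (size_fit$valid)
    gamma_indicator(avalanches$size, size_fit$exponent, n_system, s_min)
  else NA_integer_
  out <- tibble::tibble(tau_hat = size_fit$exponent,
                        alpha_hat = dur_fit$exponent,
                        inv_snz = snz$exponent,
                        ks_d = d, gamma = g,
                        n_events = nrow(avalanches),
                        s_min = s_min, s_max = s_max,
                        t_min_alpha = 5, t_max_alpha = 30,
                        t_min_snz = 2, t_max_snz = 20)
  class(out) <- c("criticality_fit", class(out))
  out
}

#' @rdname tidy.di_result
#' @export
glance.criticality_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("tau_hat", "alpha_hat", "inv_snz", "ks_d",
                           "gamma", "n_events")]
}

#' Draw synthetic discrete power-law samples
#'
#' Samples from `P(s) propto s^(-tau)` on the finite integer support
#' `[x_min, x_max]` by exact inversion of the normalised mass function.
#' Used for estimator-recovery checks.
#'
#' @param n number of draws.
#' @param tau exponent.
#' @param x_min,x_max support bounds.
#' @param seed integer RNG seed.
#' @return Integer vector of length `n`.
#' @export
rpowerlaw_discrete <- function(n, tau, x_min, x_max, seed = NULL) {
  supp <- x_min:x_max
  w <- supp^(-tau)
  with_seed(seed, sample(supp, n, replace = TRUE, prob = w / sum(w)))
}

#' Bootstrap the avalanche exponent triple
#'
#' Resamples avalanches with replacement and refits `tau`, `alpha` and
#' `1/(sigma nu z)`, giving the sampling spread of the exponents and of
#' the scaling-relation left side `(alpha - 1) / (tau - 1)`.
#'
#' @param avalanches an avalanche tibble (`size`, `duration`).
#' @param n_system system size `N`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @return Tibble with one row per replicate: `tau_hat`, `alpha_hat`,
#'   `inv_snz`, `lhs`.
#' @export
bootstrap_exponents <- function(avalanches, n_system, n_boot = 20,
                                seed = NULL) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(avalanches), replace = TRUE)
      fit <- criticality_fit(avalanches[idx, ], n_system)
      tibble::tibble(tau_hat = fit$tau_hat, alpha_hat = fit$alpha_hat,
                     inv_snz = fit$inv_snz,
                     lhs = (fit$alpha_hat - 1) / (fit$tau_hat - 1))
    })
  })
}
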