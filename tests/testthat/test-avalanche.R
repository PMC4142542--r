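test_that("hurwitz zeta matches the Riemann zeta and its own recurrence", {
  taus <- c(1.2, 1.5, 2, 3, 4)
  expect_equal(hurwitz_zeta(taus, 1), pracma::zeta(taus), tolerance = 1e-10)
  for (a in c(2, 10, 600)) {
    expect_equal(hurwitz_zeta(taus, a) - hurwitz_zeta(taus, a + 1),
                 a^(-taus), tolerance = 1e-12)
  }
  # integral bounds: zeta(tau, a) between the two Riemann-sum brackets
  z <- hurwitz_zeta(2.5, 10)
  lower <- 10^(1 - 2.5) / 1.5          # integral from 10
  upper <- lower + 10^(-2.5)
  expect_gt(z, lower)
  expect_lt(z, upper)
})

test_that("collect_avalanches filters the transient and rejects full mode", {
  cfg <- network_config("avalanche", n = 100, t_total = 1000,
                        t_transient = 500)
  w <- build_coupling(100, p = 0.02, seed = 1)
  run <- simulate_avalanche_mode(cfg, w, seed = 2)
  av <- collect_avalanches(run)
  expect_true(all(av$time_ms > 500))
  expect_equal(attr(av, "n_system"), 100L)

  fake_full <- run
  fake_full$raster$mode <- "full"
  expect_error(collect_avalanches(fake_full), "full-mode")
  expect_error(collect_avalanches(list()), "simulate_avalanche_mode")
})

test_that("ML estimator recovers known exponents from synthetic draws", {
  for (tau in c(1.5, 2.0)) {
    x <- rpowerlaw_discrete(1e5, tau, 10, 600, seed = round(tau * 100))
    fit <- fit_powerlaw_ml(x, 10, 600, normalization = "window")
    expect_lt(abs(fit$exponent - tau), 0.05)
  }
  # the tail normalisation is deliberately not matched to truncated draws:
  # it overestimates the exponent by the missing tail mass, more so for
  # shallow exponents
  x <- rpowerlaw_discrete(1e5, 1.5, 10, 600, seed = 150)
  expect_gt(fit_powerlaw_ml(x, 10, 600)$exponent, 1.5)
})

test_that("degenerate and empty windows are handled", {
  fit <- fit_powerlaw_ml(rep(10, 500), 10, 600)
  expect_equal(fit$exponent, 4)     # steepest available decay
  bad <- fit_powerlaw_ml(c(1, 2, 700), 10, 600)
  expect_false(bad$valid)
  expect_true(is.na(bad$exponent))
})

test_that("grid argmax matches a brute-force finer-grid refinement", {
  x <- rpowerlaw_discrete(20000, 1.7, 10, 600, seed = 99)
  coarse <- fit_powerlaw_ml(x, 10, 600, grid = seq(1.1, 4, by = 0.01))
  fine <- fit_powerlaw_ml(x, 10, 600, grid = seq(1.1, 4, by = 0.001))
  expect_lte(abs(coarse$exponent - fine$exponent), 0.01)
})

test_that("estimator error shrinks with sample size", {
  set.seed(12)
  med_err <- vapply(c(500, 20000), function(n) {
    errs <- vapply(1:20, function(b) {
      x <- rpowerlaw_discrete(n, 1.5, 10, 600)
      abs(fit_powerlaw_ml(x, 10, 600)$exponent - 1.5)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[2], med_err[1])
})

test_that("duration exponent fitting mirrors the size fit on [5, 30]", {
  x <- rpowerlaw_discrete(5e4, 2.0, 5, 30, seed = 17)
  fit <- fit_duration_exponent(x, normalization = "window")
  expect_equal(fit$x_min, 5)
  expect_equal(fit$x_max, 30)
  expect_lt(abs(fit$exponent - 2.0), 0.1)
  expect_equal(fit_duration_exponent(rep(5, 100))$exponent, 4)
})

test_that("mean-size-given-duration slope matches closed form and lm", {
  ev <- tibble::tibble(duration = rep(2:20, each = 3))
  ev$size <- ev$duration^2
  expect_equal(fit_mean_size_given_duration(ev)$exponent, 2, tolerance = 1e-12)

  set.seed(13)
  ev2 <- tibble::tibble(duration = sample(2:20, 400, replace = TRUE))
  ev2$size <- round(ev2$duration^1.6 * exp(rnorm(400, 0, 0.2)))
  ms <- aggregate(size ~ duration, ev2, mean)
  lm_slope <- unname(coef(lm(log(size) ~ log(duration), ms))[2])
  expect_equal(fit_mean_size_given_duration(ev2)$exponent, lm_slope,
               tolerance = 1e-10)

  single <- tibble::tibble(duration = rep(5, 10), size = 25)
  expect_false(fit_mean_size_given_duration(single)$valid)
})

test_that("the KS statistic measures the maximal CDF gap", {
  # identical CDFs
  f <- function(s) powerlaw_cdf(s, 1.5, 10)
  expect_equal(ks_statistic(n_system = 1000, f_emp = f, f_fit = f), 0)

  # hand-built step CDFs with a known largest gap of 0.25
  f_emp <- function(s) ifelse(s < 10, 0, ifelse(s < 50, 0.5, ifelse(s < 100, 0.75, 1)))
  f_fit <- function(s) ifelse(s < 10, 0, ifelse(s < 50, 0.25, ifelse(s < 100, 0.75, 1)))
  expect_equal(ks_statistic(n_system = 1000, f_emp = f_emp, f_fit = f_fit), 0.25)

  # Glivenko-Cantelli: D shrinks with sample size under the fitted law
  d_n <- vapply(c(300, 30000), function(n) {
    x <- rpowerlaw_discrete(n, 1.5, 10, 10000, seed = n)
    ks_statistic(x, 1.5, n_system = 1000)
  }, numeric(1))
  expect_lt(d_n[2], d_n[1])
  expect_lt(d_n[2], 0.05)
  expect_true(all(d_n >= 0 & d_n <= 1))

  # invariant to duplication/reordering of the sample
  x <- rpowerlaw_discrete(2000, 1.6, 10, 900, seed = 4)
  d1 <- ks_statistic(x, 1.6, 1000)
  d2 <- ks_statistic(sample(rep(x, 2)), 1.6, 1000)
  expect_equal(d1, d2)
})

test_that("the supercriticality indicator detects tail bumps", {
  # subcritical-like samples (power law with an exponential cutoff well
  # below 0.6 N): no tail bump
  set.seed(21)
  supp <- 10:1000
  w_sub <- supp^(-1.5) * exp(-supp / 100)
  x_sub <- sample(supp, 5e4, replace = TRUE, prob = w_sub / sum(w_sub))
  expect_equal(gamma_indicator(x_sub, 1.5, 1000), 0L)

  # a point mass at s = N on top of a power law: bump detected
  x <- rpowerlaw_discrete(5e4, 1.5, 10, 1000, seed = 21)
  x_bump <- c(x, rep(1000L, round(0.1 * length(x))))
  expect_equal(gamma_indicator(x_bump, 1.5, 1000), 1L)

  # exact equality of the rescaled fit fails the strict inequality
  f <- function(s) powerlaw_cdf(s, 1.5, 10)
  expect_equal(gamma_indicator(n_system = 1000, f_emp = f, f_fit = f), 0L)
})

test_that("the scaling relation residual is exact arithmetic", {
  expect_equal(scaling_relation_residual(1.5, 2.0, 2.0), 0)
  expect_equal(scaling_relation_residual(1.5, 2.0, 1.9), 0.1)
  expect_error(scaling_relation_residual(1, 2, 1), "undefined")
})

test_that("criticality_fit assembles the full characterisation", {
  sizes <- rpowerlaw_discrete(2e4, 1.5, 1, 1000, seed = 23)
  durs <- pmax(1, round(sizes^(1 / 2)))
  av <- tibble::tibble(size = sizes, duration = durs)
  fit <- criticality_fit(av, n_system = 1000)
  expect_true(fit$tau_hat >= 1.1 && fit$tau_hat <= 4)
  expect_true(fit$ks_d >= 0 && fit$ks_d <= 1)
  expect_true(fit$gamma %in% c(0L, 1L))
  expect_equal(fit$s_min, 10)
  expect_equal(fit$s_max, 600)
  gl <- glance(fit)
  expect_named(gl, c("tau_hat", "alpha_hat", "inv_snz", "ks_d", "gamma",
                     "n_events"))
})

test_that("bootstrap exponents are reproducible and sized correctly", {
  sizes <- rpowerlaw_discrete(5000, 1.5, 1, 1000, seed = 25)
  av <- tibble::tibble(size = sizes, duration = pmax(1, round(sqrt(sizes))))
  b1 <- bootstrap_exponents(av, 1000, n_boot = 5, seed = 1)
  b2 <- bootstrap_exponents(av, 1000, n_boot = 5, seed = 1)
  expect_equal(b1, b2)
  expect_equal(nrow(b1), 5)
  expect_true(all(is.finite(b1$lhs)))
})
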