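test_that("coupling matrix is a directed Erdos-Renyi graph with the exact E/I split", {
  w <- build_coupling(2500, p = 0.02, eps = 4, seed = 42)
  n_edges <- nrow(w$edges)
  mu <- 2500^2 * 0.02
  sigma <- sqrt(2500^2 * 0.02 * 0.98)
  expect_lt(abs(n_edges - mu), 5 * sigma)
  expect_equal(w$n_exc, 2000L)
  expect_equal(w$n_inh, 500L)

  w0 <- build_coupling(100, p = 0, seed = 1)
  expect_equal(nrow(w0$edges), 0L)

  w1 <- build_coupling(1000, p = 0.02, eps = 4, seed = 7)
  expect_equal(w1$n_exc / w1$n_inh, 4)

  expect_error(build_coupling(1001, p = 0.02, eps = 4), "divisible")
  expect_error(build_coupling(1000, p = 1.5), "\\[0, 1\\]")
})

test_that("stimulus subsets have fixed size, stay in range, and may overlap", {
  stims <- draw_stimulus_set(2500, 1000, 6, seed = 3)
  expect_length(stims, 6)
  for (s in stims) {
    expect_length(s$active_set, 1000)
    expect_false(is.unsorted(s$active_set))
    expect_true(all(s$active_set >= 1 & s$active_set <= 2500))
    expect_equal(anyDuplicated(s$active_set), 0L)
  }
  # forced full coverage: every subset is the whole network
  full <- draw_stimulus_set(10, 10, 3, seed = 1)
  for (s in full) expect_equal(s$active_set, 1:10)
  expect_error(draw_stimulus_set(10, 11, 1), "exceed")
})

test_that("initial potentials follow the constant-drive sojourn density", {
  cfg <- network_config("full", n = 5000, n_active = 1000)
  v0 <- init_membrane(cfg, seed = 9)
  expect_true(all(v0 >= cfg$v_r & v0 < cfg$v_theta))
  # analytic CDF of V along the trajectory with uniform phase
  v_star <- cfg$v_r + 2 * (cfg$v_theta - cfg$v_r)
  t_p <- cfg$tau_mem * log((v_star - cfg$v_r) / (v_star - cfg$v_theta))
  cdf <- function(v) cfg$tau_mem / t_p * log((v_star - cfg$v_r) / (v_star - v))
  ks <- suppressWarnings(stats::ks.test(v0, cdf))
  expect_gt(ks$p.value, 0.01)
  # seeds must matter
  expect_false(identical(init_membrane(cfg, seed = 1),
                         init_membrane(cfg, seed = 2)))
  expect_error(init_membrane(cfg, v_star = cfg$v_theta), "exceed")
})

test_that("subthreshold rest without drive stays silent", {
  cfg <- network_config("full", n = 10, n_active = 0, t_total = 100,
                        t_transient = 0)
  w <- build_coupling(10, p = 0.3, seed = 1)
  r <- simulate_full(cfg, w, stimulus = NULL, v0 = rep(cfg$v_r, 10), seed = 1)
  expect_equal(nrow(r$spikes), 0L)
  expect_true(all(r$ext_counts == 0))
})

test_that("isolated neuron is fluctuation-driven at the mean-drive threshold", {
  # mean asymptotic drive: v_r + tau * j_ext * f_max = -60 + 10 = -50 mV
  cfg <- network_config("full", n = 5, n_active = 1, t_total = 10000,
                        t_transient = 0)
  expect_equal(cfg$v_r + cfg$tau_mem * cfg$j_ext * cfg$f_max, cfg$v_theta)
  w <- build_coupling(5, p = 0, seed = 1)
  stim <- list(active_set = 1L, stimulus_id = 1L)
  class(stim) <- "stimulus_drive"
  r <- simulate_full(cfg, w, stim, v0 = rep(cfg$v_r, 5), seed = 21)
  n_pkg <- nrow(r$spikes)
  set.seed(22)
  n_ref <- reference_isolated_neuron(n_steps = 100000)
  expect_gt(n_pkg, 0)
  expect_lt(abs(n_pkg - n_ref), 5 * sqrt(max(n_pkg, n_ref)))
  expect_true(all(r$spikes$neuron == 1L))
})

test_that("recurrent spikes are delivered at the next integration step", {
  cfg <- network_config("full", n = 5, n_active = 0, t_total = 10,
                        t_transient = 0, j_exc = 15, f_max = 0)
  w <- make_coupling(5, list(from = 1, to = 2))
  v0 <- rep(cfg$v_r, 5)
  v0[1] <- cfg$v_theta + 1  # forced to cross at the first step
  r <- simulate_full(cfg, w, stimulus = NULL, v0 = v0, seed = 1)
  sp <- r$spikes[order(r$spikes$time_ms), ]
  expect_equal(sp$neuron[1:2], c(1L, 2L))
  expect_equal(sp$time_ms[2] - sp$time_ms[1], cfg$dt)
})

test_that("fixed seeds give bit-identical rasters", {
  cfg <- network_config("full", n = 100, n_active = 40, t_total = 300,
                        t_transient = 0, j_exc = 0.3)
  w <- build_coupling(100, p = 0.05, seed = 5)
  stim <- draw_stimulus_set(100, 40, 1, seed = 6)[[1]]
  r1 <- simulate_full(cfg, w, stim, seed = 77)
  r2 <- simulate_full(cfg, w, stim, seed = 77)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$ext_counts, r2$ext_counts)
})

test_that("avalanche cascades are traced generation by generation", {
  base <- network_config("avalanche", n = 5, t_total = 1, t_transient = 0,
                         j_exc = 15, f_max = 0)
  v0 <- rep(base$v_theta - 0.5, 5)
  v0[1] <- base$v_theta + 1

  # chain 1 -> 2 -> 3: one avalanche of size 3, duration 3
  chain <- make_coupling(5, list(from = c(1, 2), to = c(2, 3)))
  run <- simulate_avalanche_mode(base, chain, v0 = v0, seed = 1)
  expect_equal(nrow(run$avalanches), 1L)
  expect_equal(run$avalanches$size, 3L)
  expect_equal(run$avalanches$duration, 3L)

  # complete graph with everyone one increment below threshold: s = N, T = 2
  all_pairs <- expand.grid(from = 1:5, to = 1:5)
  full <- make_coupling(5, all_pairs)
  run2 <- simulate_avalanche_mode(base, full, v0 = v0, seed = 1)
  expect_equal(run2$avalanches$size, 5L)
  expect_equal(run2$avalanches$duration, 2L)

  # no coupling: nothing propagates, so every cascade lasts one
  # generation; simultaneous independent triggers (rare at N = 5) merge
  # into one size > 1 event by the tie-break convention
  none <- make_coupling(5, list(from = integer(0), to = integer(0)))
  cfg3 <- network_config("avalanche", n = 5, t_total = 2000, t_transient = 0)
  run3 <- simulate_avalanche_mode(cfg3, none, seed = 2)
  expect_gt(nrow(run3$avalanches), 10)
  expect_true(all(run3$avalanches$duration == 1L))
  expect_gt(mean(run3$avalanches$size == 1L), 0.98)
})

test_that("avalanche size and duration respect the system-size bounds", {
  cfg <- network_config("avalanche", n = 200, t_total = 2000,
                        t_transient = 100, j_exc = 0.8, j_inh = 0.3)
  w <- build_coupling(200, p = 0.05, seed = 31)
  run <- simulate_avalanche_mode(cfg, w, seed = 32)
  av <- run$avalanches
  expect_true(all(av$size >= 1 & av$size <= 200))
  expect_true(all(av$duration >= 1 & av$duration <= av$size))
  # within one cascade no neuron fires twice: per-step spike uniqueness
  sp <- run$raster$spikes
  expect_equal(anyDuplicated(sp[c("time_ms", "neuron")]), 0L)
})

test_that("full and avalanche modes agree on spike counts when deeply subcritical", {
  n <- 100
  w <- build_coupling(n, p = 0.02, seed = 41)
  stim <- list(active_set = seq_len(n), stimulus_id = 1L)
  class(stim) <- "stimulus_drive"
  cfg_f <- network_config("full", n = n, n_active = n, t_total = 4000,
                          t_transient = 0, j_exc = 0.01, j_inh = 1)
  cfg_a <- network_config("avalanche", n = n, t_total = 4000,
                          t_transient = 0, j_exc = 0.01, j_inh = 1)
  nf <- nrow(simulate_full(cfg_f, w, stim, seed = 43)$spikes)
  na <- nrow(simulate_avalanche_mode(cfg_a, w, seed = 44)$raster$spikes)
  expect_lt(abs(nf - na) / max(nf, na), 0.1)
})

test_that("rasters round-trip through the plain-text store", {
  cfg <- network_config("full", n = 50, n_active = 20, t_total = 200,
                        t_transient = 50)
  w <- build_coupling(50, p = 0.05, seed = 8)
  stim <- draw_stimulus_set(50, 20, 1, seed = 9)[[1]]
  r <- simulate_full(cfg, w, stim, seed = 10)
  stem <- file.path(withr::local_tempdir(), "run1")
  write_raster(r, stem)
  r2 <- read_raster(stem)
  expect_equal(r2$spikes$time_ms, r$spikes$time_ms)
  expect_equal(r2$spikes$neuron, r$spikes$neuron)
  expect_equal(r2$ext_counts, as.integer(r$ext_counts))
  expect_equal(r2$mode, r$mode)
  expect_equal(r2$t_transient, r$t_transient)
})

test_that("configuration is validated and round-trips through yaml", {
  expect_error(network_config(v_r = -50, v_theta = -60), "below")
  expect_error(network_config(p = 2), "\\[0, 1\\]")
  expect_error(network_config(n = 2500, n_active = 3000), "exceed")
  cfg <- network_config("full", j_exc = 0.35, j_inh = 0.72)
  expect_equal(coupling_inh(cfg), 4 * 0.35 * 0.72)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2, cfg)
  cfg3 <- read_config(path, overrides = list(j_inh = 0.80))
  expect_equal(cfg3$j_inh, 0.80)
})
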