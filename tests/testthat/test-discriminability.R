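test_that("perfectly separable one-hot spectra classify at accuracy 1", {
  spectra <- make_spectra(function(i, tr, f) as.numeric(f == i),
                          n_stim = 4, n_tr = 5, freqs = 1:6)
  expect_equal(svm_loo_accuracy(spectra, seed = 1), 1)
})

test_that("label-shuffled spectra classify at chance", {
  set.seed(31)
  base <- make_spectra(function(i, tr, f) 5 + i * f + rnorm(length(f), sd = 0.1),
                       n_stim = 6, n_tr = 20, freqs = 1:10)
  # permute stimulus labels within each trial: features become uninformative
  shuffled <- dplyr::group_by(base, trial, freq_hz)
  shuffled <- dplyr::mutate(shuffled, power = power[sample.int(6)][stimulus])
  shuffled <- dplyr::ungroup(shuffled)
  acc <- svm_loo_accuracy(shuffled, seed = 2)
  # binomial error around 1/6 over 120 held-out classifications
  expect_lt(abs(acc - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / 120) + 0.02)
})

test_that("two-class accuracy approaches the analytic Bayes rate", {
  set.seed(32)
  d <- 2  # mean separation in units of the noise sd, on one feature only
  accs <- vapply(1:3, function(rep) {
    spectra <- make_spectra(function(i, tr, f) {
      shift <- if (i == 1) rep(0, length(f)) else d * (f == 1)
      rnorm(length(f)) + shift
    }, n_stim = 2, n_tr = 60, freqs = 1:2)
    svm_loo_accuracy(spectra, seed = 3)
  }, numeric(1))
  bayes <- pnorm(d / 2)
  expect_lt(abs(mean(accs) - bayes), 0.08)
})

test_that("degenerate all-identical spectra still run and score near chance", {
  spectra <- make_spectra(function(i, tr, f) rep(1, length(f)),
                          n_stim = 6, n_tr = 5, freqs = 1:4)
  acc <- svm_loo_accuracy(spectra, seed = 4)
  expect_lte(acc, 0.34)
  expect_equal(discriminability_index(spectra)$di, 0.5)
})

test_that("identical spectra give DI exactly 0.5 and saturation gives 1", {
  same <- make_spectra(function(i, tr, f) f * 2, n_stim = 3, n_tr = 4)
  expect_equal(discriminability_index(same)$di, 0.5)

  # deterministic per-stimulus spectra separated by far more than the
  # (zero) trial noise: zero denominator with positive numerator
  apart <- make_spectra(function(i, tr, f) i * 1000 + f, n_stim = 3, n_tr = 4)
  expect_equal(discriminability_index(apart)$di, 1)

  # huge separation relative to small noise saturates the erf
  set.seed(33)
  sep <- make_spectra(function(i, tr, f) i * 1000 + rnorm(length(f), sd = 1e-3),
                      n_stim = 3, n_tr = 6)
  expect_gt(discriminability_index(sep)$di, 0.999)
})

test_that("the finite-trial null bias matches the Gaussian closed form", {
  set.seed(34)
  dis <- replicate(60, {
    spectra <- make_spectra(function(i, tr, f) rnorm(length(f), 10, 2),
                            n_stim = 6, n_tr = 36, freqs = 1:20)
    discriminability_index(spectra)$di
  })
  expect_equal(mean(dis), di_null_bias(), tolerance = 0.01)
  expect_equal(di_null_bias(), (1 + (2 / pi) * atan(2^(-0.5))) / 2)
})

test_that("DI is invariant under common per-frequency affine rescalings", {
  set.seed(35)
  spectra <- make_spectra(function(i, tr, f) i + rnorm(length(f)),
                          n_stim = 4, n_tr = 8, freqs = 1:6)
  di0 <- discriminability_index(spectra)$di
  scaled <- dplyr::mutate(spectra, power = power * (freq_hz * 3) + freq_hz^2)
  expect_equal(discriminability_index(scaled)$di, di0, tolerance = 1e-12)
})

test_that("DI is non-decreasing in mean separation at fixed variances", {
  # identical trial-noise patterns in both classes: the across-trial sds
  # are fixed and every per-trial difference equals the mean separation,
  # so DI must increase deterministically with it
  set.seed(36)
  delta <- rnorm(12)
  di_at <- function(d) {
    spectra <- make_spectra(function(i, tr, f)
      delta[tr] + ifelse(i == 2, d, 0), n_stim = 2, n_tr = 12, freqs = 1:5)
    discriminability_index(spectra)$di
  }
  ds <- c(0, 0.5, 1, 2, 4)
  dis <- vapply(ds, di_at, numeric(1))
  expect_true(all(diff(dis) > 0))
  expect_equal(dis[1], 0.5)
  expect_equal(dis, pnorm(ds / (2 * sd(delta))), tolerance = 1e-12)
})

test_that("tidy and glance expose the pairwise structure", {
  set.seed(37)
  spectra <- make_spectra(function(i, tr, f) i + rnorm(length(f)),
                          n_stim = 4, n_tr = 6)
  di <- discriminability_index(spectra)
  td <- tidy(di)
  expect_equal(nrow(td), choose(4, 2))
  expect_true(all(td$discriminability >= 0.5 & td$discriminability <= 1))
  gl <- glance(di)
  expect_equal(gl$di, di$di)
  expect_equal(gl$n_trials, 6)
})

test_that("incomplete designs are rejected", {
  spectra <- make_spectra(function(i, tr, f) f, n_stim = 3, n_tr = 4)
  expect_error(spectrum_set(spectra[-1, ]), "incomplete")
  expect_error(spectrum_set(spectra[, -1]), "columns")
})
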