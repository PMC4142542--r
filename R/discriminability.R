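#' Assemble a spectrum set
#'
#' A spectrum set is the long-format table of per-trial power spectra on a
#' complete rectangular design: every stimulus has the same number of
#' trials and every `(stimulus, trial)` cell carries the same frequency
#' grid.
#'
#' @param spectra a tibble with columns `stimulus`, `trial`, `freq_hz`,
#'   `power`.
#' @return The validated tibble with class `spectrum_set` and attributes
#'   `n_stimuli`, `n_trials`, `n_freq`.
#' @export
spectrum_set <- function(spectra) {
  need <- c("stimulus", "trial", "freq_hz", "power")
  if (!all(need %in% names(spectra)))
    stop("spectra must have columns stimulus, trial, freq_hz, power",
         call. = FALSE)
  counts <- dplyr::count(spectra, .data$stimulus, .data$trial)
  if (length(unique(counts$n)) != 1)
    stop("incomplete design: unequal frequency grids per cell", call. = FALSE)
  per_stim <- dplyr::count(dplyr::distinct(spectra, .data$stimulus, .data$trial),
                           .data$stimulus)
  if (length(unique(per_stim$n)) != 1)
    stop("incomplete design: unequal trial counts per stimulus", call. = FALSE)
  out <- dplyr::as_tibble(spectra)
  attr(out, "n_stimuli") <- nrow(per_stim)
  attr(out, "n_trials") <- per_stim$n[1]
  attr(out, "n_freq") <- counts$n[1]
  class(out) <- c("spectrum_set", class(out))
  out
}

# stimulus x trial x frequency array; frequencies flagged invalid in any
# cell (all samples inside the cone of influence) are dropped for every
# cell so the design stays rectangular
spectra_array <- function(spectra) {
  spectra <- spectrum_set(spectra)
  freqs <- sort(unique(spectra$freq_hz))
  stims <- sort(unique(spectra$stimulus))
  trials <- sort(unique(spectra$trial))
  a <- array(NA_real_, dim = c(length(stims), length(trials), length(freqs)),
             dimnames = list(stims, trials, freqs))
  i <- cbind(match(spectra$stimulus, stims), match(spectra$trial, trials),
             match(spectra$freq_hz, freqs))
  a[i] <- spectra$power
  bad <- apply(a, 3, anyNA)
  if (all(bad)) stop("no valid frequencies in the spectrum set", call. = FALSE)
  a[, , !bad, drop = FALSE]
}

#' Leave-one-out linear SVM stimulus classification accuracy
#'
#' Trains a multi-class support vector machine with a linear kernel
#' (libsvm's quadratic-programming solver via e1071, one-against-one
#' voting, cost `C = 1`) on the per-trial spectra and reports the mean
#' leave-one-out test accuracy: in each of the `N_tr` folds one trial per
#' stimulus is held out, the classifier is trained on the remaining
#' `(N_tr - 1) * N_a` spectra, and the held-out spectra are classified.
#' Features are the raw per-frequency time-averaged powers, without
#' normalisation.
#'
#' @param spectra a long spectra tibble (see [spectrum_set()]).
#' @param seed integer seed controlling the random assignment of trials to
#'   folds.
#' @return Fraction of held-out spectra classified correctly, in `[0, 1]`.
#' @export
svm_loo_accuracy <- function(spectra, seed = NULL) {
  a <- spectra_array(spectra)
  n_stim <- dim(a)[1]; n_tr <- dim(a)[2]
  if (n_tr < 2) stop("need at least two trials per stimulus", call. = FALSE)
  # fold membership: one randomly chosen trial per stimulus per fold
  folds <- with_seed(seed, {
    vapply(seq_len(n_stim), function(i) sample.int(n_tr), integer(n_tr))
  })  # n_tr x n_stim: folds[k, i] = trial of stimulus i held out in fold k
  correct <- 0L
  for (k in seq_len(n_tr)) {
    test_idx <- folds[k, ]
    train_x <- NULL; train_y <- NULL; test_x <- NULL
    for (i in seq_len(n_stim)) {
      tr <- setdiff(seq_len(n_tr), test_idx[i])
      train_x <- rbind(train_x, a[i, tr, , drop = TRUE])
      train_y <- c(train_y, rep(i, n_tr - 1L))
      test_x <- rbind(test_x, a[i, test_idx[i], ])
    }
    fit <- e1071::svm(x = train_x, y = factor(train_y, levels = seq_len(n_stim)),
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- stats::predict(fit, test_x)
    correct <- correct + sum(pred == factor(seq_len(n_stim),
                                            levels = seq_len(n_stim)))
  }
  correct / (n_tr * n_stim)
}

#' Discriminability index of a spectrum set
#'
#' For every unordered stimulus pair, frequency and trial, forms the
#' standardised separation
#' `Z = |p_i(f, tr) - p_j(f, tr)| / (sd_tr(p_i(f)) + sd_tr(p_j(f)))`
#' (`sd_tr` is the standard deviation over trials of that stimulus at
#' frequency `f`) and scores it with the Gaussian overlap
#' `Phi(Z) = (erf(Z / sqrt(2)) + 1) / 2`, the area under the ROC curve of
#' two unit-separation normal distributions.  The index is the mean score
#' over pairs, frequencies and trials and is bounded in `[0.5, 1]`.
#'
#' A zero denominator with a positive numerator scores 1 (`Z = +Inf`); a
#' zero denominator with a zero numerator scores 0.5 (`Z = 0`).  With a
#' finite number of trials the index carries a positive bias under the
#' null of identically distributed spectra: for Gaussian power values it
#' converges to `(1 + (2 / pi) * atan(1 / sqrt(2))) / 2`, about 0.696.
#'
#' @param spectra a long spectra tibble (see [spectrum_set()]).
#' @return An object of class `di_result`: list with `di` (scalar in
#'   `[0.5, 1]`), `pairwise` (stimulus-pair matrix of mean pairwise
#'   discriminabilities), `n_stimuli`, `n_trials`, `n_freq`.
#' @export
discriminability_index <- function(spectra) {
  a <- spectra_array(spectra)
  n_stim <- dim(a)[1]; n_tr <- dim(a)[2]; n_f <- dim(a)[3]
  if (n_tr < 2) stop("need at least two trials per stimulus", call. = FALSE)
  sds <- apply(a, c(1, 3), sd)                     # n_stim x n_f
  pairwise <- matrix(NA_real_, n_stim, n_stim)
  for (i in seq_len(n_stim - 1)) {
    for (j in (i + 1):n_stim) {
      num <- abs(a[i, , ] - a[j, , ])              # n_tr x n_f
      den <- matrix(sds[i, ] + sds[j, ], n_tr, n_f, byrow = TRUE)
      z <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
      pairwise[i, j] <- pairwise[j, i] <- mean(pnorm(z))
    }
  }
  out <- list(di = mean(pairwise[upper.tri(pairwise)]), pairwise = pairwise,
              n_stimuli = n_stim, n_trials = n_tr, n_freq = n_f)
  class(out) <- "di_result"
  out
}

#' Closed-form null bias of the discriminability index
#'
#' Large-trial limit of the index when all stimuli share one Gaussian
#' spectral distribution: `(1 + (2 / pi) * atan(1 / sqrt(2))) / 2`.
#'
#' @return Scalar, about 0.6959.
#' @export
di_null_bias <- function() (1 + (2 / pi) * atan(1 / sqrt(2))) / 2

#' @export
print.di_result <- function(x, ...) {
  cat(sprintf("<di_result: DI = %.4f over %d stimuli x %d trials x %d frequencies>\n",
              x$di, x$n_stimuli, x$n_trials, x$n_freq))
  invisible(x)
}

#' Tidy and summarise a discriminability result
#'
#' `tidy()` returns one row per unordered stimulus pair with its mean
#' pairwise discriminability; `glance()` returns a one-row summary.
#'
#' @param x a `di_result`.
#' @param ... unused.
#' @export
tidy.di_result <- function(x, ...) {
  idx <- which(upper.tri(x$pairwise), arr.ind = TRUE)
  tibble::tibble(stimulus_i = idx[, 1], stimulus_j = idx[, 2],
                 discriminability = x$pairwise[idx])
}

#' @rdname tidy.di_result
#' @export
glance.di_result <- function(x, ...) {
  tibble::tibble(di = x$di, n_stimuli = x$n_stimuli, n_trials = x$n_trials,
                 n_freq = x$n_freq)
}
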