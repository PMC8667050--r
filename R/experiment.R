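#' The study's condition grid
#'
#' Carriers crossed with relative bandwidths: by default 4, 8, 12 kHz
#' times 0.5-3 ERB in 0.5 steps, the 18-condition design.
#'
#' @param center_freqs_hz carrier frequencies, Hz.
#' @param bandwidths_erb relative bandwidths, ERB units.
#' @return tibble with columns `center_freq_hz`, `bandwidth_erb`.
#' @export
condition_grid <- function(center_freqs_hz = c(4000, 8000, 12000),
                           bandwidths_erb = seq(0.5, 3, by = 0.5)) {
  g <- expand.grid(bandwidth_erb = bandwidths_erb,
                   center_freq_hz = center_freqs_hz)
  tibble::tibble(center_freq_hz = g$center_freq_hz,
                 bandwidth_erb = g$bandwidth_erb)
}

#' Run the full simulated experiment
#'
#' For each synthetic listener drawn from the population model, runs
#' `reps` blocks, each a uniformly random permutation of the whole
#' condition grid, one adaptive staircase per condition per block (so 54
#' staircases per listener on the default grid). Track-level lognormal
#' jitter is applied to the listener's true threshold per staircase.
#' Per-listener randomness derives from the master seed by a counter
#' scheme, so adding listeners does not perturb existing ones.
#'
#' @param pop a [population_model].
#' @param n_listeners number of synthetic listeners.
#' @param config a [staircase_config].
#' @param grid condition grid (default [condition_grid()]).
#' @param reps staircase repetitions (blocks) per condition.
#' @param seed master integer seed.
#' @return tibble of staircase summaries: `listener_id`, `block`,
#'   `center_freq_hz`, `bandwidth_erb`, `threshold_us`, `n_trials`,
#'   `ceiling_hits`.
#' @export
run_experiment <- function(pop, n_listeners = 9,
                           config = staircase_config(),
                           grid = condition_grid(), reps = 3, seed) {
  stopifnot(inherits(pop, "population_model"), n_listeners >= 1)
  nc <- nrow(grid)
  out <- vector("list", n_listeners)
  for (i in seq_len(n_listeners)) {
    listener <- sample_listener(pop, grid, seed = derive_seed(seed, i))
    rows <- with_seed(derive_seed(seed, 1000000L + i), {
      acc <- vector("list", reps * nc)
      k <- 0L
      for (b in seq_len(reps)) {
        ord <- sample.int(nc)
        for (ci in ord) {
          k <- k + 1L
          a <- listener$alpha_us[ci] * 10^stats::rnorm(1, 0, pop$track_sd)
          lp <- psychometric_params(a, pop$beta, pop$lapse)
          res <- run_staircase(lp, config,
                               seed = sample.int(2147483646L, 1),
                               record_trials = FALSE)
          acc[[k]] <- c(i, b, listener$center_freq_hz[ci],
                        listener$bandwidth_erb[ci], res$threshold_us,
                        res$n_trials, res$ceiling_hits)
        }
      }
      acc
    })
    m <- do.call(rbind, rows)
    out[[i]] <- m
  }
  m <- do.call(rbind, out)
  tibble::tibble(listener_id = as.integer(m[, 1]),
                 block = as.integer(m[, 2]),
                 center_freq_hz = m[, 3],
                 bandwidth_erb = m[, 4],
                 threshold_us = m[, 5],
                 n_trials = as.integer(m[, 6]),
                 ceiling_hits = as.integer(m[, 7]))
}

#' Simulate staircase thresholds for ideal integrator observers
#'
#' For each channel count `n`, sets the observer's true threshold to
#' `single_channel_alpha_us / sqrt(n)` and runs replicate staircases;
#' regressing the log median threshold on log n recovers the
#' signal-detection-theoretic slope of -0.5.
#'
#' @param n_channels vector of channel counts (default 1:8).
#' @param single_channel_alpha_us single-channel threshold,
#'   microseconds.
#' @param n_tracks staircases per channel count.
#' @param config a [staircase_config].
#' @param seed master integer seed.
#' @param beta,lapse psychometric parameters of the observers.
#' @return tibble with `n_channels`, `true_alpha_us`,
#'   `median_threshold_us`; attribute `fit` holds the log10-log10
#'   `lm` fit.
#' @export
integrator_staircase_slope <- function(n_channels = 1:8,
                                       single_channel_alpha_us = 300,
                                       n_tracks = 200,
                                       config = staircase_config(),
                                       seed = 1,
                                       beta = 0.8, lapse = 0.02) {
  med <- vapply(seq_along(n_channels), function(j) {
    n <- n_channels[j]
    lp <- psychometric_params(
      integrator_threshold(single_channel_alpha_us, n), beta, lapse)
    thr <- vapply(seq_len(n_tracks), function(t) {
      run_staircase(lp, config,
                    seed = derive_seed(seed, j * 100000L + t),
                    record_trials = FALSE)$threshold_us
    }, numeric(1))
    stats::median(thr)
  }, numeric(1))
  out <- tibble::tibble(n_channels = n_channels,
                        true_alpha_us =
                          integrator_threshold(single_channel_alpha_us,
                                               n_channels),
                        median_threshold_us = med)
  fit <- stats::lm(log10(median_threshold_us) ~ log10(n_channels),
                   data = out)
  attr(out, "fit") <- fit
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  out
}
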