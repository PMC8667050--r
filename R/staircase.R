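#' Configuration of the 3-down-1-up adaptive staircase
#'
#' The transformed up-down track used to estimate ITD thresholds: start
#' at 2500 microseconds with a multiplicative step factor of 2, drop to
#' sqrt(2) after the second reversal, stop after 10 reversals, and take
#' the geometric mean of the last six reversal magnitudes as the
#' threshold. Upward steps are capped at `itd_cap_us`; capped steps are
#' counted so ceiling-limited tracks remain identifiable.
#'
#' @param initial_itd_us starting ITD magnitude, microseconds.
#' @param step_factor_initial multiplicative step before the switch.
#' @param step_factor_final multiplicative step after
#'   `switch_after_reversals` reversals.
#' @param switch_after_reversals reversal count triggering the smaller
#'   step.
#' @param stop_reversals total reversals ending the track.
#' @param threshold_reversals how many final reversals enter the
#'   geometric-mean threshold.
#' @param itd_cap_us ceiling for upward steps, microseconds.
#' @return object of class `staircase_config`.
#' @export
staircase_config <- function(initial_itd_us = 2500,
                             step_factor_initial = 2,
                             step_factor_final = sqrt(2),
                             switch_after_reversals = 2,
                             stop_reversals = 10,
                             threshold_reversals = 6,
                             itd_cap_us = 3000) {
  stopifnot(step_factor_initial > 1, step_factor_final > 1,
            threshold_reversals <= stop_reversals,
            initial_itd_us > 0, initial_itd_us <= itd_cap_us)
  structure(list(initial_itd_us = initial_itd_us,
                 step_factor_initial = step_factor_initial,
                 step_factor_final = step_factor_final,
                 switch_after_reversals = switch_after_reversals,
                 stop_reversals = stop_reversals,
                 threshold_reversals = threshold_reversals,
                 itd_cap_us = itd_cap_us),
            class = "staircase_config")
}

#' Initialize a staircase track
#'
#' @param config a [staircase_config].
#' @return a `staircase_state`: current ITD, consecutive-correct
#'   counter, reversal log, last step direction, completion flag.
#' @export
staircase_new <- function(config = staircase_config()) {
  structure(list(config = config,
                 itd_us = config$initial_itd_us,
                 n_correct = 0L,
                 reversal_itds_us = numeric(0),
                 last_dir = 0L,      # 0 = no step yet, -1 down, +1 up
                 ceiling_hits = 0L,
                 n_trials = 0L,
                 complete = FALSE),
            class = "staircase_state")
}

#' Advance a staircase by one trial outcome
#'
#' Implements the 3-down-1-up rule: after three consecutive correct
#' responses the ITD magnitude is divided by the current step factor and
#' the counter resets; after any incorrect response it is multiplied by
#' the factor (capped at the ceiling) and the counter resets. A reversal
#' is logged -- at the ITD of the triggering trial -- whenever the step
#' direction differs from the previous step's; the first step
#' establishes a direction without a reversal. Once the reversal count
#' reaches the switch point the final (smaller) step factor is used. The
#' track completes at `stop_reversals` reversals, with the threshold set
#' to the geometric mean of the last `threshold_reversals` reversal
#' magnitudes.
#'
#' @param state a `staircase_state`.
#' @param correct logical: was the response correct?
#' @return the updated `staircase_state` (with `$trial_itd_us` and
#'   `$trial_reversal` describing the trial just consumed); stepping a
#'   completed staircase is an error.
#' @export
staircase_step <- function(state, correct) {
  if (state$complete) stop("staircase is already complete")
  cfg <- state$config
  state$n_trials <- state$n_trials + 1L
  state$trial_itd_us <- state$itd_us
  state$trial_reversal <- FALSE
  step_dir <- 0L
  if (correct) {
    state$n_correct <- state$n_correct + 1L
    if (state$n_correct == 3L) step_dir <- -1L
  } else {
    step_dir <- +1L
  }
  if (step_dir != 0L) {
    if (state$last_dir != 0L && step_dir != state$last_dir) {
      state$reversal_itds_us <- c(state$reversal_itds_us, state$itd_us)
      state$trial_reversal <- TRUE
    }
    factor <- if (length(state$reversal_itds_us) >=
                  cfg$switch_after_reversals)
      cfg$step_factor_final else cfg$step_factor_initial
    if (step_dir < 0L) {
      state$itd_us <- state$itd_us / factor
    } else {
      up <- state$itd_us * factor
      if (up > cfg$itd_cap_us) {
        state$ceiling_hits <- state$ceiling_hits + 1L
        up <- cfg$itd_cap_us
      }
      state$itd_us <- up
    }
    state$n_correct <- 0L
    state$last_dir <- step_dir
    if (length(state$reversal_itds_us) >= cfg$stop_reversals)
      state$complete <- TRUE
  }
  state
}

# Threshold of a completed staircase: geometric mean of the last
# threshold_reversals reversal magnitudes.
staircase_threshold <- function(state) {
  cfg <- state$config
  r <- state$reversal_itds_us
  stopifnot(length(r) >= cfg$threshold_reversals)
  geomean(utils::tail(r, cfg$threshold_reversals))
}

#' Run one adaptive staircase against a simulated listener
#'
#' Simulates the two-interval lateralization task: each trial presents a
#' reference with zero ITD and a target whose lead side (left or right)
#' is drawn uniformly; the listener responds correctly with probability
#' given by the psychometric function at the current ITD magnitude, and
#' otherwise reports the wrong side. The track runs until the staircase
#' completes. Deterministic given (listener parameters, config, seed).
#'
#' @param listener a [psychometric_params].
#' @param config a [staircase_config].
#' @param seed integer seed.
#' @param max_trials abort guard for non-terminating tracks.
#' @param record_trials keep the per-trial log (set `FALSE` in bulk
#'   simulation for speed).
#' @return a `staircase_result` list: `threshold_us`,
#'   `reversal_itds_us`, `n_trials`, `ceiling_hits`, and (if recorded)
#'   `trials`, a tibble with columns `trial`, `itd_us` (signed by lead
#'   side), `lead_side`, `response`, `correct`, `reversal`.
#' @export
run_staircase <- function(listener, config = staircase_config(), seed,
                          max_trials = 10000, record_trials = TRUE) {
  stopifnot(inherits(listener, "psychometric_params"))
  with_seed(seed, {
    st <- staircase_new(config)
    itd <- integer(0); lead <- character(0); resp <- character(0)
    corr <- logical(0); revs <- logical(0)
    if (record_trials) {
      itd <- numeric(max_trials); lead <- character(max_trials)
      resp <- character(max_trials); corr <- logical(max_trials)
      revs <- logical(max_trials)
    }
    n <- 0L
    while (!st$complete) {
      n <- n + 1L
      if (n > max_trials)
        stop(sprintf(
          "staircase did not terminate within %d trials (%d reversals so far)",
          max_trials, length(st$reversal_itds_us)))
      side <- if (stats::runif(1) < 0.5) "left" else "right"
      p <- p_correct(listener, st$itd_us)
      ok <- stats::runif(1) < p
      st <- staircase_step(st, ok)
      if (record_trials) {
        itd[n] <- st$trial_itd_us * (if (side == "left") 1 else -1)
        lead[n] <- side
        resp[n] <- if (ok) side else setdiff(c("left", "right"), side)
        corr[n] <- ok
        revs[n] <- st$trial_reversal
      }
    }
    out <- list(threshold_us = staircase_threshold(st),
                reversal_itds_us = st$reversal_itds_us,
                n_trials = st$n_trials,
                ceiling_hits = st$ceiling_hits)
    if (record_trials)
      out$trials <- tibble::tibble(trial = seq_len(n),
                                   itd_us = itd[seq_len(n)],
                                   lead_side = lead[seq_len(n)],
                                   response = resp[seq_len(n)],
                                   correct = corr[seq_len(n)],
                                   reversal = revs[seq_len(n)])
    structure(out, class = "staircase_result")
  })
}

#' Run the training phase for one listener
#'
#' Training consists of feedback-enabled staircases on a single
#' condition. After the third track, training stops as soon as the most
#' recent threshold lies within +/-15% of the running mean of all
#' previous thresholds (performance saturation); a configurable cap
#' guards against non-stationary listeners.
#'
#' @param listener a [psychometric_params] for the training condition.
#' @param config a [staircase_config].
#' @param seed integer seed.
#' @param track_sd between-track SD of log10 threshold (lognormal
#'   jitter on the listener's alpha per track).
#' @param tolerance stopping tolerance relative to the moving average.
#' @param max_tracks cap on the number of tracks (with a warning when
#'   hit).
#' @return list with `n_tracks` and the per-track `thresholds_us`.
#' @export
run_training <- function(listener, config = staircase_config(), seed,
                         track_sd = 0.08, tolerance = 0.15,
                         max_tracks = 20) {
  thresholds <- numeric(0)
  k <- 0L
  repeat {
    k <- k + 1L
    a_k <- listener$alpha_us *
      10^with_seed(derive_seed(seed, 2L * k - 1L),
                   stats::rnorm(1, 0, track_sd))
    track_listener <- psychometric_params(a_k, listener$beta,
                                          listener$lapse)
    res <- run_staircase(track_listener, config,
                         seed = derive_seed(seed, 2L * k),
                         record_trials = FALSE)
    thresholds <- c(thresholds, res$threshold_us)
    if (k >= 3L) {
      avg <- mean(thresholds[seq_len(k - 1L)])
      if (abs(thresholds[k] - avg) <= tolerance * avg) break
    }
    if (k >= max_tracks) {
      warning("training did not saturate within max_tracks tracks")
      break
    }
  }
  list(n_tracks = k, thresholds_us = thresholds)
}
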