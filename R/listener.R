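#' Psychometric parameters of a simulated listener in one condition
#'
#' The observer model for the two-interval lateralization task: a
#' lapse-contaminated cumulative-normal psychometric function on the
#' log-ITD axis,
#' `P(correct | ITD) = 0.5 + (0.5 - lapse) * Phi((ln ITD - ln alpha) / beta)`.
#' `alpha_us` is the 75%-correct point for a lapse-free observer; `beta`
#' sets the slope in log-ITD units; `lapse` caps asymptotic performance
#' at `1 - lapse`.
#'
#' @param alpha_us threshold location parameter, microseconds (> 0).
#' @param beta psychometric slope on the log-ITD axis (> 0).
#' @param lapse lapse rate in `[0, 0.1)`.
#' @return object of class `psychometric_params`.
#' @export
psychometric_params <- function(alpha_us, beta = 0.8, lapse = 0.02) {
  stopifnot(alpha_us > 0, beta > 0, lapse >= 0, lapse < 0.1)
  structure(list(alpha_us = alpha_us, beta = beta, lapse = lapse),
            class = "psychometric_params")
}

#' Probability of a correct lateralization response
#'
#' @param params a [psychometric_params].
#' @param itd_us ITD magnitude, microseconds (>= 0; vectorised).
#' @return probability in `[0.5, 1 - lapse]`; 0.5 at `itd_us = 0`.
#' @export
p_correct <- function(params, itd_us) {
  stopifnot(inherits(params, "psychometric_params"), all(itd_us >= 0))
  p <- ifelse(itd_us == 0, 0.5,
              0.5 + (0.5 - params$lapse) *
                stats::pnorm((log(itd_us) - log(params$alpha_us)) /
                               params$beta))
  unname(p)
}

#' ITD at which a listener reaches a target percent correct
#'
#' Inverts the psychometric function:
#' `ITD = alpha * exp(beta * qnorm((p - 0.5) / (0.5 - lapse)))`.
#' The 3-down-1-up staircase converges on `p = (1/2)^(1/3)` (79.4%
#' correct), so `itd_at_pc(params)` is the quantity the staircase
#' estimates.
#'
#' @param params a [psychometric_params].
#' @param p target probability correct, in `(0.5, 1 - lapse)`.
#' @return ITD in microseconds.
#' @export
itd_at_pc <- function(params, p = 0.5^(1 / 3)) {
  stopifnot(p > 0.5, p < 1 - params$lapse)
  z <- stats::qnorm((p - 0.5) / (0.5 - params$lapse))
  params$alpha_us * exp(params$beta * z)
}

#' Population model for synthetic listeners
#'
#' The generative model the analysis assumes: expected log10 threshold
#' is linear in bandwidth (ERB) with optional per-carrier offsets, plus
#' Gaussian between-listener and between-track variation on the log10
#' scale,
#' `log10 alpha(cf, erb) = intercept + slope * erb + cf_effect[cf] +
#'  listener effect`,
#' with track-level lognormal jitter applied per staircase. Defaults put
#' the 8-kHz 1-ERB threshold near 300 microseconds with the bandwidth
#' slope at -0.20 log10 units per ERB and no carrier effect.
#'
#' @param intercept_log10us mean log10 threshold at 0 ERB.
#' @param slope_per_erb change in log10 threshold per ERB.
#' @param listener_sd between-listener SD of log10 threshold.
#' @param track_sd within-listener between-track SD of log10 threshold.
#' @param cf_effect named numeric vector of per-carrier offsets in log10
#'   units (default all zero: no centre-frequency effect).
#' @param beta,lapse psychometric slope and lapse rate shared by all
#'   listeners.
#' @return object of class `population_model`.
#' @export
population_model <- function(intercept_log10us = log10(300) + 0.20,
                             slope_per_erb = -0.20,
                             listener_sd = 0.15,
                             track_sd = 0.08,
                             cf_effect = c(`4000` = 0, `8000` = 0,
                                           `12000` = 0),
                             beta = 0.8, lapse = 0.02) {
  stopifnot(listener_sd >= 0, track_sd >= 0, beta > 0,
            lapse >= 0, lapse < 0.1)
  structure(list(intercept_log10us = intercept_log10us,
                 slope_per_erb = slope_per_erb,
                 listener_sd = listener_sd,
                 track_sd = track_sd,
                 cf_effect = cf_effect,
                 beta = beta, lapse = lapse),
            class = "population_model")
}

#' Draw one synthetic listener from the population model
#'
#' Samples a listener-level random intercept and returns the listener's
#' true per-condition psychometric parameters over the design grid.
#' Track-level jitter is applied later, per staircase, by the experiment
#' runner.
#'
#' @param pop a [population_model].
#' @param grid data frame of conditions with columns `center_freq_hz`
#'   and `bandwidth_erb` (default: the 18-condition study grid).
#' @param seed integer seed; the same seed reproduces the listener.
#' @return a tibble with the grid columns plus `alpha_us`, `beta`,
#'   `lapse`.
#' @export
sample_listener <- function(pop, grid = condition_grid(), seed) {
  stopifnot(inherits(pop, "population_model"))
  u <- with_seed(seed, stats::rnorm(1, 0, pop$listener_sd))
  cf_off <- pop$cf_effect[as.character(grid$center_freq_hz)]
  cf_off[is.na(cf_off)] <- 0
  l10 <- pop$intercept_log10us + pop$slope_per_erb * grid$bandwidth_erb +
    as.numeric(cf_off) + u
  tibble::tibble(center_freq_hz = grid$center_freq_hz,
                 bandwidth_erb = grid$bandwidth_erb,
                 alpha_us = 10^l10,
                 beta = pop$beta,
                 lapse = pop$lapse)
}

#' Effective threshold of an ideal across-channel integrator
#'
#' Under signal detection theory, combining `n` independent auditory
#' channels improves sensitivity by `sqrt(n)`, so the effective ITD
#' threshold is `single_channel_alpha_us / sqrt(n)`. Regressing
#' log threshold on log n therefore gives a slope of exactly -0.5 --
#' the ideal-observer prediction against which the fitted bandwidth
#' slope can be compared.
#'
#' @param single_channel_alpha_us threshold with one channel,
#'   microseconds.
#' @param n_channels number of independent channels recruited (>= 1;
#'   vectorised).
#' @return effective threshold(s) in microseconds.
#' @export
integrator_threshold <- function(single_channel_alpha_us, n_channels) {
  if (any(n_channels < 1)) stop("n_channels must be >= 1")
  stopifnot(single_channel_alpha_us > 0)
  single_channel_alpha_us / sqrt(n_channels)
}
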