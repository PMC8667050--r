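#' Aggregate staircase summaries into the threshold table
#'
#' Per (listener, condition) cell, the reported threshold is the
#' geometric mean of the repetition-track thresholds. The result must be
#' complete and balanced: every listener contributes every condition.
#'
#' @param raw staircase-summary tibble from [run_experiment()] (columns
#'   `listener_id`, `center_freq_hz`, `bandwidth_erb`, `threshold_us`).
#' @return tibble with one row per (listener, condition):
#'   `listener_id`, `center_freq_hz`, `bandwidth_erb`, `threshold_us`.
#' @export
aggregate_thresholds <- function(raw) {
  stopifnot(all(c("listener_id", "center_freq_hz", "bandwidth_erb",
                  "threshold_us") %in% names(raw)),
            all(raw$threshold_us > 0))
  key <- interaction(raw$listener_id, raw$center_freq_hz,
                     raw$bandwidth_erb, drop = TRUE)
  agg <- stats::aggregate(list(threshold_us = raw$threshold_us),
                          by = list(listener_id = raw$listener_id,
                                    center_freq_hz = raw$center_freq_hz,
                                    bandwidth_erb = raw$bandwidth_erb),
                          FUN = geomean)
  # balance check: every listener x condition combination present
  ids <- unique(agg$listener_id)
  conds <- unique(agg[, c("center_freq_hz", "bandwidth_erb")])
  expected <- length(ids) * nrow(conds)
  if (nrow(agg) != expected) {
    full <- merge(expand.grid(listener_id = ids,
                              idx = seq_len(nrow(conds))),
                  cbind(conds, idx = seq_len(nrow(conds))))
    have <- paste(agg$listener_id, agg$center_freq_hz, agg$bandwidth_erb)
    want <- paste(full$listener_id, full$center_freq_hz,
                  full$bandwidth_erb)
    miss <- setdiff(want, have)
    stop("missing cells in threshold table: ",
         paste(utils::head(miss, 5), collapse = "; "))
  }
  agg <- agg[order(agg$listener_id, agg$center_freq_hz,
                   agg$bandwidth_erb), ]
  tibble::as_tibble(agg)
}

#' Fit the bandwidth slope of log10 ITD thresholds
#'
#' Ordinary least squares of log10 threshold on bandwidth, either
#' linear in ERB (`predictor = "erb"`) or in log10(ERB)
#' (`predictor = "log_erb"`). By default the fit uses the condition
#' means: the geometric mean threshold across listeners per (carrier,
#' bandwidth) cell, 18 points on the study grid. Set
#' `per_listener = TRUE` to fit each listener separately instead (the
#' summary slope is then the mean of listener slopes with a t-based CI).
#'
#' @param table threshold table from [aggregate_thresholds()].
#' @param predictor `"erb"` or `"log_erb"`.
#' @param per_listener fit per listener instead of on condition means.
#' @return a `slope_fit` list: `slope`, `intercept`, `ci95_lo`,
#'   `ci95_hi`, `r_squared`, `predictor`, and the underlying `fit`.
#' @export
fit_slope <- function(table, predictor = c("erb", "log_erb"),
                      per_listener = FALSE) {
  predictor <- match.arg(predictor)
  xfun <- function(erb) if (predictor == "erb") erb else log10(erb)
  if (per_listener) {
    slopes <- vapply(split(table, table$listener_id), function(d) {
      m <- stats::aggregate(list(y = log10(d$threshold_us)),
                            by = list(erb = d$bandwidth_erb,
                                      cf = d$center_freq_hz), FUN = mean)
      unname(stats::coef(stats::lm(y ~ xfun(erb), data = m))[2])
    }, numeric(1))
    ci <- if (stats::sd(slopes) < 1e-12) rep(mean(slopes), 2)
          else stats::t.test(slopes)$conf.int
    return(structure(list(slope = mean(slopes),
                          intercept = NA_real_,
                          ci95_lo = ci[1],
                          ci95_hi = ci[2],
                          r_squared = NA_real_,
                          predictor = predictor,
                          listener_slopes = slopes),
                     class = "slope_fit"))
  }
  cond <- stats::aggregate(list(y = log10(table$threshold_us)),
                           by = list(erb = table$bandwidth_erb,
                                     cf = table$center_freq_hz),
                           FUN = mean)
  if (length(unique(xfun(cond$erb))) < 3)
    stop("need at least 3 distinct predictor values")
  fit <- stats::lm(y ~ x, data = data.frame(y = cond$y,
                                            x = xfun(cond$erb)))
  ci <- stats::confint(fit)["x", ]
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci95_lo = unname(ci[1]),
                 ci95_hi = unname(ci[2]),
                 r_squared = summary(fit)$r.squared,
                 predictor = predictor,
                 fit = fit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "slope fit (log10 threshold ~ %s): slope %.3f [%.3f, %.3f], R2 = %s\n",
    x$predictor, x$slope, x$ci95_lo, x$ci95_hi,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  invisible(x)
}

# Orthonormal contrast matrix (k x (k-1)) with columns orthogonal to the
# unit vector.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# Greenhouse-Geisser epsilon from a contrast-score covariance matrix.
gg_epsilon <- function(S_c) {
  p <- ncol(S_c)
  sum(diag(S_c))^2 / (p * sum(S_c * S_c))
}

# Mauchly's sphericity test on a contrast-score covariance matrix with
# n_sub subjects. Returns NA when the matrix is singular (n - 1 < p).
mauchly_p <- function(S_c, n_sub) {
  p <- ncol(S_c)
  if (n_sub - 1 < p) return(NA_real_)
  d <- determinant(S_c, logarithm = TRUE)
  if (d$sign <= 0) return(NA_real_)
  logW <- as.numeric(d$modulus) - p * log(sum(diag(S_c)) / p)
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * (n_sub - 1))
  stat <- -rho * (n_sub - 1) * logW
  df <- p * (p + 1) / 2 - 1
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Two-way repeated-measures ANOVA on log10 ITD thresholds
#'
#' Classical within-subject decomposition with factors bandwidth (ERB)
#' and centre frequency, on log10-transformed thresholds. Each effect is
#' tested against its own subject-by-effect error term. Sphericity is
#' assessed per effect with Mauchly's test on the orthonormal-contrast
#' covariance; when it rejects at 0.05 -- or cannot be computed because
#' the contrast covariance is singular (fewer subjects than contrast
#' dimensions, as happens for the interaction with 9 listeners) -- the
#' Greenhouse-Geisser epsilon scales both degrees of freedom. Partial
#' eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table balanced threshold table from [aggregate_thresholds()].
#' @return a tibble with one row per effect (`bandwidth`,
#'   `center_frequency`, `interaction`): sums of squares, uncorrected
#'   and reported df, `F`, `p`, `epsilon_gg`, `mauchly_p`, `gg_applied`,
#'   `partial_eta_sq`. Attribute `ss_partition` carries the full SS
#'   decomposition (including subject strata) for audit.
#' @export
rm_anova <- function(table) {
  ids <- sort(unique(table$listener_id))
  bws <- sort(unique(table$bandwidth_erb))
  cfs <- sort(unique(table$center_freq_hz))
  n <- length(ids); a <- length(bws); b <- length(cfs)
  if (n < 2) stop("need at least 2 listeners")
  if (nrow(table) != n * a * b)
    stop("threshold table is not balanced")
  Y <- array(NA_real_, dim = c(n, a, b))
  Y[cbind(match(table$listener_id, ids),
          match(table$bandwidth_erb, bws),
          match(table$center_freq_hz, cfs))] <- log10(table$threshold_us)
  if (any(is.na(Y))) stop("threshold table is not balanced")

  grand <- mean(Y)
  m_s <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean)
  m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean); m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb

  # contrast-score covariances for sphericity / epsilon
  Ma <- orthonormal_contrasts(a); Mb <- orthonormal_contrasts(b)
  Sa <- stats::cov(m_sa %*% Ma)
  Sb <- stats::cov(m_sb %*% Mb)
  # per-subject cell matrix in (bw, cf) order matching kronecker(Ma, Mb)
  cells <- matrix(aperm(Y, c(1, 3, 2)), nrow = n)   # columns: bw-major
  Mab <- kronecker(Ma, Mb)
  Sab <- stats::cov(cells %*% Mab)

  eff <- function(name, ss_e, df_e, ss_err, df_err, S_c) {
    eps <- gg_epsilon(S_c)
    mp <- mauchly_p(S_c, n)
    apply_gg <- (!is.na(mp) && mp < 0.05) || (is.na(mp) && eps < 1)
    sc <- if (apply_gg) eps else 1
    Fv <- (ss_e / df_e) / (ss_err / df_err)
    p <- stats::pf(Fv, df_e * sc, df_err * sc, lower.tail = FALSE)
    tibble::tibble(effect = name, ss_effect = ss_e, ss_error = ss_err,
                   df_num = df_e * sc, df_den = df_err * sc,
                   F = Fv, p = p, epsilon_gg = eps, mauchly_p = mp,
                   gg_applied = apply_gg,
                   partial_eta_sq = ss_e / (ss_e + ss_err))
  }
  res <- rbind(
    eff("bandwidth", ss_a, a - 1, ss_sa, (a - 1) * (n - 1), Sa),
    eff("center_frequency", ss_b, b - 1, ss_sb, (b - 1) * (n - 1), Sb),
    eff("interaction", ss_ab, (a - 1) * (b - 1), ss_sab,
        (a - 1) * (b - 1) * (n - 1), Sab))
  attr(res, "ss_partition") <-
    c(subjects = ss_s, bandwidth = ss_a, center_frequency = ss_b,
      interaction = ss_ab, err_bandwidth = ss_sa,
      err_center_frequency = ss_sb, err_interaction = ss_sab,
      total = ss_tot)
  res
}

#' Bonferroni-corrected post hoc comparisons across bandwidths
#'
#' All pairwise paired two-sample t-tests between bandwidth levels on
#' listener-mean log10 thresholds (collapsed over carrier); p-values are
#' multiplied by the number of comparisons (15 for six levels) and
#' clipped at 1.
#'
#' @param table threshold table from [aggregate_thresholds()].
#' @return tibble with one row per pair: `bw1`, `bw2`,
#'   `mean_diff_log10` (bw1 minus bw2), `t`, `df`, `p_raw`, `p_bonf`.
#' @export
posthoc_bandwidth <- function(table) {
  agg <- stats::aggregate(list(y = log10(table$threshold_us)),
                          by = list(listener_id = table$listener_id,
                                    bw = table$bandwidth_erb),
                          FUN = mean)
  bws <- sort(unique(agg$bw))
  ids <- sort(unique(agg$listener_id))
  Y <- matrix(NA_real_, length(ids), length(bws))
  Y[cbind(match(agg$listener_id, ids), match(agg$bw, bws))] <- agg$y
  pairs <- utils::combn(length(bws), 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- Y[, i1] - Y[, i2]
    if (stats::sd(d) < 1e-15) {
      tt <- list(statistic = c(t = if (abs(mean(d)) < 1e-15) 0 else
                                 sign(mean(d)) * Inf),
                 parameter = c(df = length(d) - 1),
                 p.value = if (abs(mean(d)) < 1e-15) 1 else 0)
    } else {
      tt <- stats::t.test(Y[, i1], Y[, i2], paired = TRUE)
    }
    tibble::tibble(bw1 = bws[i1], bw2 = bws[i2],
                   mean_diff_log10 = mean(d),
                   t = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   p_bonf = min(1, tt$p.value * m))
  })
  do.call(rbind, out)
}

#' Draw a threshold table directly from the population model
#'
#' Bypasses the staircase layer: per listener, log10 thresholds are the
#' population line plus the listener random effect plus independent
#' per-cell noise. Used for statistical calibration (type-I error,
#' power) where the staircase adds run time but no systematic effects.
#'
#' @param pop a [population_model].
#' @param n_listeners number of listeners.
#' @param grid condition grid.
#' @param cell_sd per-cell residual SD of log10 threshold.
#' @param seed integer seed.
#' @return a threshold table tibble.
#' @export
simulate_threshold_table <- function(pop, n_listeners = 9,
                                     grid = condition_grid(),
                                     cell_sd = 0.05, seed) {
  nc <- nrow(grid)
  with_seed(seed, {
    rows <- lapply(seq_len(n_listeners), function(i) {
      u <- stats::rnorm(1, 0, pop$listener_sd)
      cf_off <- pop$cf_effect[as.character(grid$center_freq_hz)]
      cf_off[is.na(cf_off)] <- 0
      l10 <- pop$intercept_log10us +
        pop$slope_per_erb * grid$bandwidth_erb + as.numeric(cf_off) +
        u + stats::rnorm(nc, 0, cell_sd)
      tibble::tibble(listener_id = i,
                     center_freq_hz = grid$center_freq_hz,
                     bandwidth_erb = grid$bandwidth_erb,
                     threshold_us = 10^l10)
    })
    do.call(rbind, rows)
  })
}

#' Type-I error calibration of the repeated-measures ANOVA
#'
#' Simulates experiments under the null population model (zero
#' bandwidth slope, zero carrier effect) and records how often each
#' ANOVA effect rejects at the given alpha. With a correctly calibrated
#' test each rate should sit near alpha.
#'
#' @param n_experiments number of simulated experiments.
#' @param n_listeners listeners per experiment. The default of 12 keeps
#'   the interaction contrast covariance non-singular (n - 1 >= 10) so
#'   sphericity is actually tested rather than assumed violated.
#' @param grid condition grid.
#' @param cell_sd,listener_sd noise components of log10 threshold.
#' @param alpha nominal test level.
#' @param seed master integer seed.
#' @return named numeric vector of rejection rates per effect.
#' @export
anova_type1_rates <- function(n_experiments = 1000, n_listeners = 12,
                              grid = condition_grid(), cell_sd = 0.05,
                              listener_sd = 0.15, alpha = 0.05,
                              seed = 1) {
  pop <- population_model(slope_per_erb = 0, listener_sd = listener_sd,
                          cf_effect = c(`4000` = 0, `8000` = 0,
                                        `12000` = 0))
  rej <- matrix(0L, n_experiments, 3)
  for (r in seq_len(n_experiments)) {
    tab <- simulate_threshold_table(pop, n_listeners, grid, cell_sd,
                                    seed = derive_seed(seed, r))
    res <- rm_anova(tab)
    rej[r, ] <- as.integer(res$p < alpha)
  }
  stats::setNames(colMeans(rej),
                  c("bandwidth", "center_frequency", "interaction"))
}
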