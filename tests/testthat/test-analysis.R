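test_that("aggregation takes geometric means per cell and checks balance", {
  raw <- tibble::tibble(listener_id = rep(1, 3),
                        center_freq_hz = rep(8000, 3),
                        bandwidth_erb = rep(1, 3),
                        threshold_us = c(100, 100, 100))
  expect_equal(aggregate_thresholds(raw)$threshold_us, 100)
  raw2 <- raw[1:2, ]; raw2$threshold_us <- c(100, 400)
  expect_equal(aggregate_thresholds(raw2)$threshold_us, 200)

  pop <- population_model()
  full <- run_experiment(pop, n_listeners = 2, seed = 31)
  tab <- aggregate_thresholds(full)
  expect_equal(nrow(tab), 36)
  # permutation invariance over listener relabeling
  relab <- full
  relab$listener_id <- 3 - relab$listener_id
  tab2 <- aggregate_thresholds(relab)
  expect_equal(tab$threshold_us,
               tab2$threshold_us[order(3 - tab2$listener_id,
                                       tab2$center_freq_hz,
                                       tab2$bandwidth_erb)])
  # dropping an entire cell is a named error
  drop <- full$listener_id == 1 & full$center_freq_hz == 4000 &
    full$bandwidth_erb == 0.5
  expect_error(aggregate_thresholds(full[!drop, ]), "missing cell")
})

test_that("slope fit recovers an exact line and the cross-predictor ratio", {
  tab <- exact_line_table(slope = -0.2)
  f <- fit_slope(tab, "erb")
  expect_equal(f$slope, -0.200, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # same data against log10(ERB) at design points 0.5..3
  g <- fit_slope(tab, "log_erb")
  expect_equal(g$slope, -0.629, tolerance = 0.001 / 0.629)
  # design-geometry identity: slope ratio = cov(erb, log10 erb)/var(log10 erb)
  e <- seq(0.5, 3, 0.5)
  ratio <- stats::cov(e, log10(e)) / stats::var(log10(e))
  expect_equal(g$slope / f$slope, ratio, tolerance = 1e-9)
  # doubling thresholds shifts the intercept only
  tab2 <- tab; tab2$threshold_us <- tab2$threshold_us * 2
  f2 <- fit_slope(tab2, "erb")
  expect_equal(f2$slope, f$slope, tolerance = 1e-12)
  expect_equal(f2$intercept - f$intercept, log10(2), tolerance = 1e-12)
  # per-listener fitting agrees on noise-free data
  fl <- fit_slope(tab, "erb", per_listener = TRUE)
  expect_equal(fl$slope, -0.2, tolerance = 1e-9)
})

test_that("RM-ANOVA matches the car oracle on a 12-listener table", {
  pop <- population_model()
  tab <- simulate_threshold_table(pop, n_listeners = 12, seed = 7)
  mine <- rm_anova(tab)

  ids <- sort(unique(tab$listener_id))
  bws <- sort(unique(tab$bandwidth_erb))
  cfs <- sort(unique(tab$center_freq_hz))
  Y <- matrix(NA_real_, length(ids), 18)
  k <- 0
  for (bw in bws) for (cf in cfs) {
    k <- k + 1
    sel <- tab$bandwidth_erb == bw & tab$center_freq_hz == cf
    Y[, k] <- log10(tab$threshold_us[sel][order(tab$listener_id[sel])])
  }
  idata <- expand.grid(cf = factor(cfs), bw = factor(bws))
  av <- car::Anova(stats::lm(Y ~ 1), idata = idata,
                   idesign = ~ bw * cf, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  u <- s$univariate.tests
  expect_equal(mine$F,
               unname(u[c("bw", "cf", "bw:cf"), "F value"]),
               tolerance = 1e-8)
  expect_equal(mine$ss_effect,
               unname(u[c("bw", "cf", "bw:cf"), "Sum Sq"]),
               tolerance = 1e-8)
  expect_equal(mine$ss_error,
               unname(u[c("bw", "cf", "bw:cf"), "Error SS"]),
               tolerance = 1e-8)
  expect_equal(mine$epsilon_gg,
               unname(s$pval.adjustments[c("bw", "cf", "bw:cf"),
                                         "GG eps"]),
               tolerance = 1e-8)
  # GG-corrected p agrees where the correction applies
  gg_p <- unname(s$pval.adjustments[c("bw", "cf", "bw:cf"),
                                    "Pr(>F[GG])"])
  for (j in which(mine$gg_applied))
    expect_equal(mine$p[j], gg_p[j], tolerance = 1e-8)
})

test_that("ANOVA sums of squares partition exactly", {
  pop <- population_model()
  tab <- simulate_threshold_table(pop, n_listeners = 9, seed = 13)
  res <- rm_anova(tab)
  ss <- attr(res, "ss_partition")
  expect_equal(sum(ss[1:7]) / ss["total"], 1, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
  expect_true(all(res$epsilon_gg <= 1 + 1e-9))
  # invariant to listener relabeling
  relab <- tab
  relab$listener_id <- max(tab$listener_id) + 1 - relab$listener_id
  expect_equal(rm_anova(relab)$F, res$F, tolerance = 1e-12)
})

test_that("compound-symmetric data yield epsilon 1 and uncorrected df", {
  tab <- compound_symmetric_table()
  res <- rm_anova(tab)
  expect_equal(res$epsilon_gg, rep(1, 3), tolerance = 0.02)
  expect_false(any(res$gg_applied))
  expect_equal(res$df_num, c(5, 2, 10))
  expect_equal(res$df_den, c(5, 2, 10) * 19)
})

test_that("with 9 listeners the interaction is GG-corrected as in small samples", {
  # n - 1 = 8 < 10 interaction contrasts: Mauchly is incomputable and
  # the epsilon correction is applied with fractional df
  pop <- population_model()
  tab <- simulate_threshold_table(pop, n_listeners = 9, seed = 21)
  res <- rm_anova(tab)
  inter <- res[res$effect == "interaction", ]
  expect_true(is.na(inter$mauchly_p))
  expect_true(inter$gg_applied)
  expect_lt(inter$df_num, 10)
})

test_that("post hoc bandwidth comparisons are complete and Bonferroni-corrected", {
  pop <- population_model()
  tab <- simulate_threshold_table(pop, n_listeners = 9, seed = 3)
  ph <- posthoc_bandwidth(tab)
  expect_equal(nrow(ph), choose(6, 2))
  expect_true(all(ph$p_bonf >= ph$p_raw - 1e-15))
  expect_true(all(ph$p_bonf <= 1))
  expect_equal(ph$p_bonf, pmin(1, ph$p_raw * 15))
  # identical data in two levels give corrected p = 1
  tab2 <- tab
  src <- tab2$bandwidth_erb == 0.5
  dst <- tab2$bandwidth_erb == 1.0
  tab2$threshold_us[dst] <- tab2$threshold_us[src]
  ph2 <- posthoc_bandwidth(tab2)
  expect_equal(ph2$p_bonf[ph2$bw1 == 0.5 & ph2$bw2 == 1.0], 1)
})
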