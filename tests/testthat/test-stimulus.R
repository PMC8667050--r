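test_that("ERB bandwidth follows the Glasberg-Moore formula", {
  expect_equal(erb_bandwidth_hz(0), 24.7)
  expect_equal(erb_bandwidth_hz(4000), 456.5, tolerance = 0.1 / 456.5)
  expect_equal(erb_bandwidth_hz(12000), 1319.9, tolerance = 0.1 / 1319.9)
  f <- seq(0, 16000, by = 500)
  expect_true(all(diff(erb_bandwidth_hz(f)) > 0))
  expect_error(erb_bandwidth_hz(-1), "non-negative")
})

test_that("Gabor sigma-bandwidth relation holds to 1e-12 relative", {
  for (bw in c(100, 456.5, 2000)) {
    gp <- gabor_params(8000, bw)
    expect_equal(gp$sigma_s, sqrt(log(2)) / (pi * bw), tolerance = 1e-12)
  }
})

test_that("synthesized Gabor pulse has the requested spectrum and envelope", {
  fs <- 400000
  for (bw in c(456.5, 888.2, 1320)) {
    x <- make_gabor_pulse(8000, bw, fs, peak_time_s = 0.05,
                          duration_s = 0.1)
    expect_equal(measured_bw3db_hz(x, fs), bw, tolerance = 0.01)
    env <- ref_envelope(x)
    ipk <- which.max(env)
    expect_equal(max(env), 1, tolerance = 1e-6)
    # half-amplitude points of the Gaussian envelope sit where
    # exp(-t^2 / (2 sigma^2)) = 0.5
    sigma <- gabor_params(8000, bw)$sigma_s
    t_half <- sigma * sqrt(2 * log(2))
    off <- round(t_half * fs)
    expect_equal(env[ipk + off] / env[ipk], 0.5, tolerance = 0.01)
    expect_equal(env[ipk - off] / env[ipk], 0.5, tolerance = 0.01)
    # even symmetry of the envelope about the peak
    k <- round(2 * sigma * fs)
    expect_equal(env[ipk + seq_len(k)], env[ipk - seq_len(k)],
                 tolerance = 1e-6)
  }
})

test_that("pulse over-wide for the sampling band is rejected", {
  expect_error(make_gabor_pulse(500, 2000, 8000, 0.05, 0.1), "clips")
})

test_that("pulse train has the right pulse count, ITD and symmetry", {
  w0 <- make_pulse_train(pulse_train_spec(8000, 1, itd_us = 0))
  expect_identical(w0$left, w0$right)
  expect_equal(count_envelope_peaks(w0$left), 3)
  expect_equal(w0$sample_rate_hz, 100000)

  # 250 us at 400 kHz is exactly 100 synthesis samples
  sp <- pulse_train_spec(8000, 1, itd_us = 250)
  expect_equal(round(sp$itd_us * 1e-6 * sp$synth_rate_hz), 100)
  w <- make_pulse_train(sp)
  expect_equal(interaural_lag_us(w), 250, tolerance = 10 / 250)

  # sign flip swaps the channels exactly
  wm <- make_pulse_train(pulse_train_spec(8000, 1, itd_us = -250))
  expect_equal(wm$left, w$right)
  expect_equal(wm$right, w$left)

  # off-grid ITD is rejected
  expect_error(pulse_train_spec(8000, 1, itd_us = 251.3), "grid")
})

test_that("cross-correlation lag matches the requested ITD across conditions", {
  for (cf in c(4000, 12000)) {
    for (itd in c(-500, 100, 1000)) {
      w <- make_pulse_train(pulse_train_spec(cf, 1.5, itd_us = itd))
      expect_equal(interaural_lag_us(w), itd, tolerance = 10 / abs(itd))
    }
  }
})

test_that("decimation is safe: negligible energy above the output Nyquist", {
  g <- condition_grid()
  for (i in seq_len(nrow(g))) {
    bw <- g$bandwidth_erb[i] * erb_bandwidth_hz(g$center_freq_hz[i])
    sf <- gabor_params(g$center_freq_hz[i], bw)$sigma_f_hz
    frac <- itdsim:::spectral_energy_outside(g$center_freq_hz[i], sf,
                                             0, 50000)
    expect_lt(frac, 1e-4)
  }
  # empirical check on the widest, highest condition
  sp <- pulse_train_spec(12000, 3)
  x <- itdsim:::gabor_train_ifft(120000, 400000, 12000,
                                 gabor_params(12000, sp$bw3db_hz)$sigma_f_hz,
                                 c(0.05, 0.15, 0.25))
  X2 <- Mod(stats::fft(x))^2
  f <- (0:(length(x) - 1)) * 400000 / length(x)
  hi <- f > 50000 & f < 350000
  expect_lt(sum(X2[hi]) / sum(X2), 1e-4)
})

test_that("bandwidth-duration reciprocity: doubling BW halves the rise time", {
  fs <- 400000
  x1 <- make_gabor_pulse(8000, 500, fs, 0.05, 0.1)
  x2 <- make_gabor_pulse(8000, 1000, fs, 0.05, 0.1)
  r1 <- as.numeric(empirical_rise_time(x1, fs))
  r2 <- as.numeric(empirical_rise_time(x2, fs))
  expect_equal(r1 / r2, 2, tolerance = 0.02)
})

test_that("spectral peak normalization equates spectral maxima", {
  ref <- make_pulse_train(pulse_train_spec(8000, 1))
  w <- make_pulse_train(pulse_train_spec(8000, 3))
  out <- spectral_peak_normalize(w, ref)
  r <- max(Mod(stats::fft(out$left))) / max(Mod(stats::fft(ref$left)))
  expect_equal(r, 1, tolerance = 1e-6)
  # identity on the reference itself
  same <- spectral_peak_normalize(ref, ref)
  expect_equal(same$left, ref$left, tolerance = 1e-12)
  # gain invariance: scaling the input by 10 does not change the output
  w10 <- stereo_waveform(w$left * 10, w$right * 10, w$sample_rate_hz)
  out10 <- spectral_peak_normalize(w10, ref)
  expect_equal(out10$left, out$left, tolerance = 1e-9)
  silent <- stereo_waveform(numeric(100), numeric(100), 100000)
  expect_error(spectral_peak_normalize(silent, ref), "silent")
})

test_that("masking noise is reproducible, uncorrelated and low-passed", {
  a <- make_masking_noise(500, 20000, seed = 5)
  b <- make_masking_noise(500, 20000, seed = 5)
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)

  long <- make_masking_noise(10000, 20000, seed = 6)
  rho <- stats::cor(long$left, long$right)
  expect_lt(abs(rho), 0.05)

  # analytic cascade rolloff: 4 kHz at least 40 dB below 100 Hz
  expect_lt(masker_response_db(4000) - masker_response_db(100), -40)
  # asymptotic slope approaches -24 dB/octave above 1 kHz
  slope <- masker_response_db(16000) - masker_response_db(8000)
  expect_equal(slope, -24, tolerance = 0.02)

  # empirical band power ratio on the long draw
  X2 <- Mod(stats::fft(long$left))^2
  f <- (0:(length(long$left) - 1)) * 20000 / length(long$left)
  p_lo <- mean(X2[f >= 80 & f <= 120])
  p_hi <- mean(X2[f >= 3900 & f <= 4100])
  expect_lt(10 * log10(p_hi / p_lo), -40)
})

test_that("waveform invariants are enforced", {
  expect_error(stereo_waveform(1:3, 1:4, 100), "equal length")
  expect_error(stereo_waveform(c(1, NA), c(1, 2), 100), "finite")
  expect_error(pulse_train_spec(8000, -1), "bandwidth_erb")
  # carrier + 4 spectral SDs must stay below the output Nyquist
  expect_error(pulse_train_spec(16000, 40), "Nyquist")
})

test_that("WAV files round-trip through the float32 writer", {
  w <- make_pulse_train(pulse_train_spec(8000, 1, itd_us = 250))
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate_hz, w$sample_rate_hz)
  expect_equal(back$left, w$left, tolerance = 1e-6)
  expect_equal(back$right, w$right, tolerance = 1e-6)
})
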