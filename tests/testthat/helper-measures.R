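# Shared measurement helpers for the test suite. These are independent
# of the package's own signal path where they serve as oracles.

# -3-dB full width of the magnitude spectrum of a real signal, by
# linear interpolation of the half-power crossings around the peak.
measured_bw3db_hz <- function(x, fs) {
  n <- length(x)
  X <- Mod(stats::fft(x))[1:(floor(n / 2) + 1)]
  f <- (0:floor(n / 2)) * fs / n
  ipk <- which.max(X)
  thr <- X[ipk] / sqrt(2)
  i_lo <- max(which(X[1:ipk] < thr))
  i_hi <- ipk - 1 + min(which(X[ipk:length(X)] < thr))
  f_lo <- f[i_lo] + (thr - X[i_lo]) / (X[i_lo + 1] - X[i_lo]) * (f[2] - f[1])
  f_hi <- f[i_hi - 1] +
    (X[i_hi - 1] - thr) / (X[i_hi - 1] - X[i_hi]) * (f[2] - f[1])
  f_hi - f_lo
}

# Hilbert envelope via FFT, written independently of the package.
ref_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Count envelope peaks exceeding a fraction of the global maximum.
count_envelope_peaks <- function(x, frac = 0.5) {
  env <- ref_envelope(x)
  pk <- which(diff(sign(diff(env))) == -2) + 1
  sum(env[pk] > frac * max(env))
}

# Threshold table lying exactly on a log10-linear line in ERB.
exact_line_table <- function(n_listeners = 4, intercept = 3,
                             slope = -0.2) {
  g <- condition_grid()
  do.call(rbind, lapply(seq_len(n_listeners), function(i)
    tibble::tibble(listener_id = i,
                   center_freq_hz = g$center_freq_hz,
                   bandwidth_erb = g$bandwidth_erb,
                   threshold_us = 10^(intercept +
                                        slope * g$bandwidth_erb))))
}

# Threshold table whose sample covariance across the 18 conditions is
# exactly compound symmetric (a*J + b*I): residual columns are built
# orthonormal and orthogonal to both the unit vector and the subject
# effect, so every effect's contrast covariance is spherical.
compound_symmetric_table <- function(n_listeners = 20, seed = 99) {
  g <- condition_grid()
  nc <- nrow(g)
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n_listeners * (nc + 1)),
                               n_listeners))))
  u <- Q[, 2]              # subject effect, orthonormal to 1 and E
  E <- Q[, 3:(nc + 2)]     # residuals: E'E = I, colSums = 0
  nu <- 2.5 - 0.1 * g$bandwidth_erb
  Y <- outer(rep(1, n_listeners), nu) + 0.4 * u %*% t(rep(1, nc)) +
    0.15 * E
  do.call(rbind, lapply(seq_len(n_listeners), function(i)
    tibble::tibble(listener_id = i,
                   center_freq_hz = g$center_freq_hz,
                   bandwidth_erb = g$bandwidth_erb,
                   threshold_us = 10^Y[i, ])))
}
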