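#' Equivalent rectangular bandwidth at a centre frequency
#'
#' Glasberg--Moore ERB scale: `ERB(f) = 24.7 * (4.37 * f_kHz + 1)` Hz.
#' This is the bandwidth of the idealised rectangular auditory filter at
#' `center_freq_hz`, and the unit in which relative stimulus bandwidths
#' are specified throughout the package.
#'
#' @param center_freq_hz centre frequency in Hz (vectorised, must be >= 0).
#' @return bandwidth of one ERB in Hz.
#' @examples
#' erb_bandwidth_hz(4000)   # ~456.5 Hz
#' erb_bandwidth_hz(12000)  # ~1320 Hz
#' @export
erb_bandwidth_hz <- function(center_freq_hz) {
  if (any(!is.finite(center_freq_hz)) || any(center_freq_hz < 0))
    stop("center_freq_hz must be finite and non-negative")
  24.7 * (4.37 * center_freq_hz / 1000 + 1)
}

#' Gaussian envelope parameters of a Gabor pulse
#'
#' A Gabor pulse is a cosine carrier under a Gaussian temporal envelope;
#' its magnitude spectrum is Gaussian. The half-power (-3 dB) full
#' spectral width `BW` fixes the temporal envelope standard deviation:
#' `sigma = sqrt(ln 2) / (pi * BW)`.
#'
#' @param center_freq_hz carrier frequency in Hz.
#' @param bw3db_hz -3-dB full bandwidth of the magnitude spectrum, Hz.
#' @return list with `sigma_s` (envelope SD, seconds), `sigma_f_hz`
#'   (spectral SD, Hz), `bw3db_hz`, `center_freq_hz`.
#' @export
gabor_params <- function(center_freq_hz, bw3db_hz) {
  stopifnot(bw3db_hz > 0, center_freq_hz > 0)
  sigma_f <- bw3db_hz / (2 * sqrt(log(2)))
  list(sigma_s = sqrt(log(2)) / (pi * bw3db_hz),
       sigma_f_hz = sigma_f,
       bw3db_hz = bw3db_hz,
       center_freq_hz = center_freq_hz)
}
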