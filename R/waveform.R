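#' Two-channel sampled waveform
#'
#' The container all signal processing operates on: left and right
#' sample vectors (dimensionless amplitude) plus a sample rate.
#'
#' @param left,right numeric sample vectors of equal length.
#' @param sample_rate_hz samples per second.
#' @return an object of class `stereo_waveform`.
#' @export
stereo_waveform <- function(left, right, sample_rate_hz) {
  if (length(left) != length(right))
    stop("left and right channels must have equal length")
  if (!all(is.finite(left)) || !all(is.finite(right)))
    stop("all samples must be finite")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 sample_rate_hz = sample_rate_hz),
            class = "stereo_waveform")
}

#' @export
print.stereo_waveform <- function(x, ...) {
  cat(sprintf("<stereo_waveform: %d samples @ %g kHz (%.1f ms)>\n",
              length(x$left), x$sample_rate_hz / 1000,
              1000 * length(x$left) / x$sample_rate_hz))
  invisible(x)
}

#' @export
length.stereo_waveform <- function(x) length(x$left)

#' Lag of the interaural cross-correlation maximum
#'
#' Finds the lag (in microseconds) at which the cross-correlation of the
#' left and right channels peaks. Positive values mean the left channel
#' leads. Used to verify applied ITDs.
#'
#' @param wave a [stereo_waveform].
#' @param max_lag_us search window, microseconds.
#' @return lag in microseconds (resolution = one sample period).
#' @export
interaural_lag_us <- function(wave, max_lag_us = 4000) {
  fs <- wave$sample_rate_hz
  max_lag <- ceiling(max_lag_us * 1e-6 * fs)
  cc <- stats::ccf(wave$left, wave$right, lag.max = max_lag,
                   plot = FALSE, demean = FALSE)
  lag <- cc$lag[which.max(cc$acf)]
  # ccf lag k correlates left[t+k] with right[t]; a left-leading channel
  # (right delayed) peaks at negative k, so flip the sign.
  -lag / fs * 1e6
}

#' Write a stereo waveform as 32-bit float WAV
#'
#' Minimal RIFF/WAVE writer (IEEE float, format code 3), interleaved
#' stereo at the waveform's own sample rate.
#'
#' @param wave a [stereo_waveform].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  n <- length(wave$left)
  fs <- as.integer(round(wave$sample_rate_hz))
  data_bytes <- n * 2L * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16L)
  w_u16(3L)                 # IEEE float
  w_u16(2L)                 # channels
  w_u32(fs)
  w_u32(fs * 8L)            # byte rate
  w_u16(8L)                 # block align
  w_u16(32L)                # bits per sample
  writeChar("data", con, eos = NULL); w_u32(data_bytes)
  interleaved <- as.vector(rbind(wave$left, wave$right))
  writeBin(interleaved, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 32-bit float stereo WAV written by [write_wav()]
#'
#' @param path file path.
#' @return a [stereo_waveform].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r_u16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  r_u32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- r_u32()
    if (id == "fmt ") {
      fmt <- r_u16(); nch <- r_u16(); fs <- r_u32()
      r_u32(); r_u16(); bits <- r_u16()
      if (fmt != 3L || nch != 2L || bits != 32L)
        stop("only 32-bit float stereo WAV is supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      x <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
      m <- matrix(x, nrow = 2)
      return(stereo_waveform(m[1, ], m[2, ], fs))
    } else {
      readBin(con, "raw", sz)
    }
  }
}
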