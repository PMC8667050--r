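#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed and a counter. Keeps results
# independent of how many earlier streams were consumed, so adding
# listeners or blocks does not perturb existing ones.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 100003 + as.numeric(counter)) %% 2147483647)
}

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal of a real vector (negative
#' frequencies zeroed, positive doubled); its modulus is the Hilbert
#' envelope.
#'
#' @param x real numeric vector.
#' @return complex vector, same length as `x`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Hilbert envelope of a real signal.
envelope <- function(x) Mod(analytic_signal(x))

# Linear FFT convolution, output trimmed to the length of x (causal
# filter alignment: y[n] = sum h[k] x[n-k]).
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                       stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_along(x)]
}

# Geometric mean.
geomean <- function(x) exp(mean(log(x)))
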