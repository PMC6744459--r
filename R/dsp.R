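# Internal DSP primitives shared by preprocessing, phase extraction and the
# wavelet transform.  Filtering is done spectrally: the signal's FFT is
# multiplied by the *squared* Butterworth magnitude response, which is the
# exact zero-phase (forward-backward) response of the named filter without
# the numerical instability of transfer-function recursions at band edges
# far below Nyquist.

# next power of two >= n (FFT-friendly length)
next_pow2 <- function(n) 2^ceiling(log2(n))

# frequency axis of an n-point FFT at sampling rate fs (two-sided, Hz)
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

# |H(f)|^2 of an order-n Butterworth band-pass (product of low- and
# high-pass prototypes); low = NULL -> pure low-pass, high = NULL -> pure
# high-pass.  `order` is the analog prototype order of EACH pass; applying
# the square makes the result the two-pass (zero-phase) response.
butterworth_mag2 <- function(f, low, high, order) {
  af <- abs(f)
  h <- rep(1, length(f))
  if (!is.null(low) && low > 0) {
    r <- ifelse(af == 0, Inf, (low / af)^(2 * order))
    h <- h / (1 + r)
    h[af == 0] <- 0
  }
  if (!is.null(high)) {
    h <- h / (1 + (af / high)^(2 * order))
  }
  h
}

# zero-phase band-pass via spectral multiplication; returns real series of
# the original length.  Mirror-pads to soften edge discontinuities.
spectral_bandpass <- function(x, fs, low, high, order) {
  n <- length(x)
  mu <- mean(x)
  x <- x - mu          # removed anyway by the high-pass; keeps padding flat
  npad <- min(n, 4096L)
  left <- rev(x[seq_len(npad)])
  right <- rev(x[(n - npad + 1):n])
  xe <- c(left, x, right)
  ne <- next_pow2(length(xe))
  xe <- c(xe, rep(0, ne - length(xe)))
  f <- fft_freqs(ne, fs)
  h <- butterworth_mag2(f, low, high, order)
  y <- Re(stats::fft(stats::fft(xe) * h, inverse = TRUE)) / ne
  y[(npad + 1):(npad + n)]
}

# analytic signal via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  ne <- next_pow2(n)
  X <- stats::fft(c(x - mean(x), rep(0, ne - n)))
  h <- rep(0, ne)
  h[1] <- 1
  if (ne %% 2 == 0) {
    h[ne / 2 + 1] <- 1
    h[2:(ne / 2)] <- 2
  } else {
    h[2:((ne + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / ne
  z[seq_len(n)]
}

# centered moving mean with shrinking windows at the edges; w odd
moving_mean <- function(x, w) {
  n <- length(x)
  k <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# centered moving standard deviation, same edge policy
moving_sd <- function(x, w) {
  n <- length(x)
  k <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  m <- hi - lo + 1
  mu <- (cs[hi + 1] - cs[lo]) / m
  v <- (cs2[hi + 1] - cs2[lo]) / m - mu^2
  v <- pmax(v, 0) * m / pmax(m - 1, 1)
  sqrt(v)
}

# Ornstein-Uhlenbeck path: stationary SD `sd`, correlation time tau (s)
ou_process <- function(n, dt, sd, tau) {
  if (sd == 0) return(rep(0, n))
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x1 <- stats::rnorm(1, 0, sd)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  c(x1, as.numeric(stats::filter(eps, a, method = "recursive", init = x1)))
}
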