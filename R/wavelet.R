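#' Default wavelet frequency grid
#'
#' Log-spaced frequencies from 2 Hz down to 0.005 Hz at `voices` voices per
#' octave (default 16, enough to resolve the endothelial interval, which is
#' barely one octave wide).
#'
#' @param f_min,f_max Grid limits, Hz.
#' @param voices Voices per octave.
#' @return Strictly decreasing numeric vector of frequencies, Hz.
#' @export
wavelet_freqs <- function(f_min = 0.005, f_max = 2, voices = 16) {
  n_oct <- log2(f_max / f_min)
  2^seq(log2(f_max), log2(f_min), length.out = ceiling(n_oct * voices) + 1)
}

#' Morlet continuous wavelet transform of one channel
#'
#' Complex coefficients by frequency-domain convolution with scaled,
#' L1-normalized analytic Morlet wavelets
#' \eqn{\psi(u) = \pi^{-1/4} e^{i \omega_0 u} e^{-u^2/2}} with
#' \eqn{\omega_0 = 2\pi f_0}.  Coefficients are scaled so a unit-amplitude
#' sinusoid at a scale's center frequency yields unit magnitude, making the
#' band-averaged amplitude directly interpretable in the signal's units.
#' The cone of influence is the e-folding time of the wavelet envelope,
#' \eqn{\sqrt{2}\,s} at scale \eqn{s}.
#'
#' @param x Numeric series (one channel).
#' @param fs Sampling rate, Hz.
#' @param f0 Wavelet center-frequency parameter (default 1, the convention
#'   of the cardiovascular-oscillation literature; \eqn{\omega_0 = 2\pi}).
#' @param freqs Analysis frequencies, Hz (default [wavelet_freqs()]).
#' @return List of class `band_decomposition`: `coeffs` (complex matrix,
#'   freq x time), `freqs`, `coi` (per-frequency trustworthy-time margin,
#'   s), `fs`, `f0`, `time` (s).
#' @export
cwt_morlet <- function(x, fs, f0 = 1, freqs = wavelet_freqs()) {
  n <- length(x)
  if (any(freqs <= 0) || any(freqs > fs / 2)) {
    stop("analysis frequencies must lie in (0, fs/2]", call. = FALSE)
  }
  if (n < 2 * fs / min(freqs)) {
    warning("series shorter than two cycles of the slowest frequency")
  }
  omega0 <- 2 * pi * f0
  # pad enough that wrap-around from the slowest wavelets' tails stays
  # below ~1e-3 and only touches edge samples already inside the COI
  ne <- next_pow2(n + 4096L)
  X <- stats::fft(c(x - mean(x), rep(0, ne - n)))
  w <- 2 * pi * fft_freqs(ne, fs)               # rad/s, two-sided
  nf <- length(freqs)
  # L1 normalization: FT of (1/s) psi(t/s) is psihat(s w); analytic wavelet
  # (positive frequencies only).  Rescaled so |W| = A for A*cos at center.
  # All scales are inverse-transformed in one batched call.
  pos <- w > 0
  spec <- matrix(0i, ne, nf)
  for (i in seq_len(nf)) {
    s <- f0 / freqs[i]                           # scale: f = f0 / s
    psihat <- exp(-0.5 * (s * w[pos] - omega0)^2)
    spec[pos, i] <- X[pos] * psihat
  }
  Y <- stats::mvfft(spec, inverse = TRUE) / ne
  coeffs <- t(2 * Y[seq_len(n), , drop = FALSE])
  structure(
    list(coeffs = coeffs, freqs = freqs,
         coi = sqrt(2) * f0 / freqs,             # e-folding time, s
         fs = fs, f0 = f0, time = (seq_len(n) - 1) / fs),
    class = "band_decomposition"
  )
}

# indices of grid frequencies inside an interval
interval_rows <- function(dec, interval) {
  iv <- get_interval(interval)
  which(dec$freqs >= iv$f_low & dec$freqs <= iv$f_high)
}

# logical time mask excluding the cone of influence at one frequency;
# mult > 1 trims more conservatively (mult e-folding times per edge)
coi_mask <- function(dec, row, mult = 1) {
  t <- dec$time
  margin <- mult * dec$coi[row]
  t >= margin & t <= (t[length(t)] - margin)
}

# default COI policy: edge effects matter for the slow intervals, where a
# 15-min recording holds only ~13 cycles
default_coi_policy <- function(interval) {
  get_interval(interval)$id %in% c("IV", "V")
}

#' Time-averaged wavelet amplitude in one frequency interval
#'
#' Mean over time of the coefficient magnitude (optionally restricted to
#' times outside the cone of influence), then the unweighted mean over the
#' grid frequencies inside the interval.
#'
#' @param dec A `band_decomposition` from [cwt_morlet()].
#' @param interval Frequency-interval id (I--V) or interval row.
#' @param exclude_coi Mask the cone of influence?  Default: yes for
#'   intervals IV and V, no otherwise.
#' @return Nonnegative amplitude scalar (same units as the input signal).
#' @export
wavelet_amplitude <- function(dec, interval,
                              exclude_coi = default_coi_policy(interval)) {
  rows <- interval_rows(dec, interval)
  if (!length(rows)) stop("interval outside the frequency grid",
                          call. = FALSE)
  vals <- vapply(rows, function(r) {
    m <- if (exclude_coi) coi_mask(dec, r) else rep(TRUE, ncol(dec$coeffs))
    if (!any(m)) return(NA_real_)
    mean(Mod(dec$coeffs[r, m]))
  }, numeric(1))
  if (all(is.na(vals))) {
    stop("interval entirely inside the cone of influence (series too short)",
         call. = FALSE)
  }
  mean(vals, na.rm = TRUE)
}

#' Wavelet amplitude of every channel in every interval
#'
#' @param rec A (preprocessed) `fnirs_recording`.
#' @param freqs Analysis frequency grid.
#' @param f0 Morlet center-frequency parameter.
#' @return Numeric matrix channels x intervals (I--V).
#' @export
wa_by_channel <- function(rec, freqs = wavelet_freqs(), f0 = 1) {
  validate_recording(rec)
  ids <- frequency_intervals()$id
  out <- matrix(NA_real_, nrow(rec$data), length(ids),
                dimnames = list(rec$montage$channels, ids))
  for (ch in seq_len(nrow(rec$data))) {
    dec <- cwt_morlet(rec$data[ch, ], rec$fs, f0 = f0, freqs = freqs)
    for (iv in ids) {
      out[ch, iv] <- tryCatch(wavelet_amplitude(dec, iv),
                              error = function(e) NA_real_)
    }
  }
  out
}

#' Aggregate channel wavelet amplitudes to regions
#'
#' @param wa Channel x interval matrix from [wa_by_channel()].
#' @param montage The montage the channels belong to.
#' @return Region x interval matrix; each region value is the mean of its
#'   member channels.
#' @export
region_wa <- function(wa, montage) {
  if (!setequal(rownames(wa), montage$channels)) {
    stop("channel set does not match montage", call. = FALSE)
  }
  regs <- REGIONS[REGIONS %in% unique(montage$region)]
  out <- matrix(NA_real_, length(regs), ncol(wa),
                dimnames = list(regs, colnames(wa)))
  for (r in regs) {
    out[r, ] <- colMeans(wa[region_channels(montage, r), , drop = FALSE])
  }
  out
}
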