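# shared fixtures and independent oracles used across test files

fs_default <- 10

# deterministic multiband signal: one cosine per physiological band
multiband <- function(n, fs = fs_default, phase = 0,
                      freqs = c(1, 0.25, 0.1, 0.03, 0.015)) {
  t <- (seq_len(n) - 1) / fs
  rowSums(vapply(freqs, function(f) cos(2 * pi * f * t - phase),
                 numeric(n)))
}

# independent periodogram oracle (raw FFT, no package code)
periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  nf <- floor(n / 2)
  list(freq = (1:nf) * fs / n, power = Mod(X[2:(nf + 1)])^2)
}

# fraction of periodogram power inside [lo, hi] Hz
pg_band_fraction <- function(x, fs, lo, hi) {
  pg <- periodogram(x, fs)
  sum(pg$power[pg$freq >= lo & pg$freq <= hi]) / sum(pg$power)
}

# tiny two-group long table for ANOVA tests
make_metric_table <- function(v1, v2, unit = "u1", interval = "IV") {
  data.frame(
    unit = unit, interval = interval,
    value = c(v1, v2),
    group = rep(c("a", "b"), c(length(v1), length(v2))),
    stringsAsFactors = FALSE
  )
}
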