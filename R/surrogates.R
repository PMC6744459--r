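#' Amplitude-adjusted Fourier transform (AAFT) surrogates
#'
#' Each surrogate keeps exactly the empirical amplitude distribution of the
#' original series (its sorted values are the original's sorted values) and
#' approximately its power spectrum / autocorrelation, while destroying any
#' phase relation with other signals: the series is rank-remapped to a
#' Gaussian, phase-randomized in the Fourier domain, and rank-remapped back.
#'
#' @param x Numeric series (length >= 16, non-constant).
#' @param n Number of surrogates (default 50).
#' @param seed Integer seed; the ensemble is a pure function of it.
#' @return List of class `surrogate_ensemble` with `series` (n x length
#'   matrix), `n` and `seed`.
#' @export
aaft <- function(x, n = 50, seed = 1) {
  len <- length(x)
  if (len < 16) stop("series too short for AAFT (need >= 16 samples)",
                     call. = FALSE)
  if (stats::sd(x) == 0) stop("constant series: AAFT ranks undefined",
                              call. = FALSE)
  xs <- sort(x)
  withr_seed(seed, {
    out <- matrix(0, n, len)
    for (s in seq_len(n)) {
      # 1. rank-remap to a Gaussian
      g <- stats::qnorm((rank(x, ties.method = "random") - 0.5) / len)
      # 2. phase-randomize the Gaussian's spectrum (conjugate-symmetric)
      G <- stats::fft(g)
      half <- floor(len / 2)
      ph <- stats::runif(half - if (len %% 2 == 0) 1 else 0, 0, 2 * pi)
      rot <- rep(1 + 0i, len)
      idx <- 2:(if (len %% 2 == 0) half else half + 1)
      rot[idx] <- exp(1i * ph)
      rot[len + 2 - idx] <- Conj(rot[idx])
      gs <- Re(stats::fft(G * rot, inverse = TRUE)) / len
      # 3. rank-remap back to the empirical distribution of x
      out[s, ] <- xs[rank(gs, ties.method = "random")]
    }
    structure(list(series = out, n = n, seed = seed),
              class = "surrogate_ensemble")
  })
}

#' Surrogate-based significance threshold for a pairwise statistic
#'
#' Recomputes `stat_fn(x, y_surrogate)` over `n` AAFT surrogates of `y`
#' (the original `x` is kept fixed, preserving its dynamics) and returns
#' the mean + 2 SD gate: an observed statistic is taken as significant when
#' it exceeds two standard deviations above the surrogate mean.  Setting
#' `surrogate_both = TRUE` pairs independent surrogates of both signals
#' instead.
#'
#' @param stat_fn Function of two series returning a scalar.
#' @param x,y Numeric series.
#' @param n Number of surrogates (default 50).
#' @param seed Integer seed.
#' @param surrogate_both Surrogate both members of the pair?
#' @return List with `threshold` (mean + 2 SD), `mean`, `sd` and the raw
#'   surrogate `stats`.
#' @export
significance_threshold <- function(stat_fn, x, y, n = 50, seed = 1,
                                   surrogate_both = FALSE) {
  ys <- aaft(y, n = n, seed = seed)$series
  xs <- if (surrogate_both) aaft(x, n = n, seed = seed + 1)$series else NULL
  stats_v <- vapply(seq_len(n), function(i) {
    xi <- if (surrogate_both) xs[i, ] else x
    stat_fn(xi, ys[i, ])
  }, numeric(1))
  m <- mean(stats_v)
  s <- stats::sd(stats_v)
  list(threshold = m + 2 * s, mean = m, sd = s, stats = stats_v)
}
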