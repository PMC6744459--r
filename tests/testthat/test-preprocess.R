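make_intensity <- function(hbo, hhb, baseline = 100) {
  # forward Beer-Lambert model with the package's own extinction table;
  # the inverse step is what is under test
  eps <- nirscoupling:::extinction_table()
  A <- eps * 3 * 7                       # 30 mm = 3 cm, DPF 7
  n <- length(hbo)
  I <- array(0, c(14, n, 3))
  for (ch in 1:14) {
    for (w in 1:3) {
      od <- (A[w, 1] * hbo + A[w, 2] * hhb) * 1e-6
      I[ch, , w] <- baseline * 10^(-od)
    }
  }
  recording(I, fs = 10, kind = "intensity")
}

test_that("Beer-Lambert conversion inverts a forward model to numerical precision", {
  n <- 300
  t <- (1:n) / 10
  hbo <- 0.8 * sin(2 * pi * 0.05 * t)
  hhb <- -0.3 * sin(2 * pi * 0.05 * t + 1.2)
  conv <- mbll_convert(make_intensity(hbo, hhb))
  # concentrations are recovered relative to the mean baseline
  dm <- function(v) v - mean(v)
  for (ch in c(1, 7, 14)) {
    expect_lt(max(abs(dm(conv$data[ch, ]) - dm(hbo))) / max(abs(hbo)),
              1e-9)
    expect_lt(max(abs(dm(conv$hhb[ch, ]) - dm(hhb))) / max(abs(hhb)),
              1e-9)
  }
})

test_that("Beer-Lambert conversion is linear and rejects bad input", {
  n <- 100
  t <- (1:n) / 10
  hbo <- 0.4 * sin(2 * pi * 0.1 * t)
  hhb <- 0.1 * cos(2 * pi * 0.1 * t)
  c1 <- mbll_convert(make_intensity(hbo, hhb))
  c2 <- mbll_convert(make_intensity(2 * hbo, 2 * hhb))
  dm <- function(v) v - mean(v)
  expect_equal(dm(c2$data[1, ]), 2 * dm(c1$data[1, ]), tolerance = 1e-8)
  # constant intensity -> zero concentration change
  flat <- mbll_convert(make_intensity(rep(0, 50), rep(0, 50)))
  expect_equal(max(abs(flat$data)), 0)
  # non-positive intensity is an error naming the location
  bad <- make_intensity(hbo, hhb)
  bad$data[3, 17, 2] <- -1
  expect_error(mbll_convert(bad), "channel 3, sample 17")
})

test_that("moving average follows the window rounding rule and edge policy", {
  expect_equal(moving_average(rep(4, 50), 3, 10), rep(4, 50))
  x <- rep(0, 101); x[51] <- 1
  y <- moving_average(x, 3, 10)          # 3 s at 10 Hz -> 31 samples
  expect_equal(sum(y > 0), 31)
  expect_equal(unique(round(y[y > 0], 12)), round(1 / 31, 12))
  # shrinking edge windows: first sample averages its right half-window
  z <- moving_average(c(1, rep(0, 40)), 3, 10)
  expect_equal(z[1], 1 / 16)
})

test_that("motion-artifact repair flags injected spikes and nothing on clean input", {
  set.seed(21)
  clean <- rnorm(2000)
  res <- remove_motion_artifacts(clean, 1, 3, 10)
  expect_lt(length(res$flagged) / 2000, 0.01)
  expect_identical(remove_motion_artifacts(rep(2, 500), 1, 3, 10)$flagged,
                   integer())
  # injected 10-SD spikes are all inside the flagged set and repaired
  rec <- gen_banded_recording(duration = 400, seed = 4)
  inj <- inject_artifacts(rec, 6, spike_sd_mult = 10, seed = 9)
  for (ch in unique(inj$truth$channel)) {
    idx <- inj$truth$sample[inj$truth$channel == ch]
    fix <- remove_motion_artifacts(inj$rec$data[ch, ], 1, 3, 10)
    expect_true(all(idx %in% fix$flagged))
    s0 <- sd(rec$data[ch, ])
    expect_lt(max(abs(fix$x - mean(rec$data[ch, ]))), 4 * s0)
  }
})

test_that("ICA reconstructs exactly with nothing rejected and removes cardiac sources", {
  set.seed(5)
  n <- 3000
  t <- (1:n) / 10
  S <- rbind(sin(2 * pi * 0.015 * t), sin(2 * pi * 1 * t + 0.5))
  A <- matrix(rnorm(28), 14, 2)
  X <- A %*% S + matrix(rnorm(14 * n, 0, 0.02), 14)
  rec <- recording(X, fs = 10)
  r0 <- ica_denoise(rec, reject = integer())
  expect_lt(max(abs(r0$data - X)), 1e-8)
  # deterministic under a fixed seed
  ra <- ica_denoise(rec, reject = "auto-cardiac", seed = 3)
  rb <- ica_denoise(rec, reject = "auto-cardiac", seed = 3)
  expect_identical(ra$data, rb$data)
  # cardiac band variance drops by at least 80 %
  cardiac_var <- function(M) sum(apply(M, 1, function(x) {
    var(x) * pg_band_fraction(x, 10, 0.6, 2)
  }))
  expect_lt(cardiac_var(ra$data), 0.2 * cardiac_var(X))
  expect_error(ica_denoise(rec, reject = 1:14), "all")
})

test_that("zero-phase band-pass meets its gain contract", {
  fs <- 10
  t <- (0:8999) / fs
  y <- bandpass(sin(2 * pi * 0.1 * t), 0.005, 2, 6, fs)
  expect_equal(max(abs(y[1000:8000])), 1, tolerance = 0.02)
  t2 <- (0:17999) / fs
  y2 <- bandpass(sin(2 * pi * 0.001 * t2), 0.005, 2, 6, fs)
  expect_lt(max(abs(y2[3000:15000])), 0.1)
  expect_equal(mean(abs(bandpass(rep(5, 1000), 0.005, 2, 6, fs))), 0,
               tolerance = 1e-6 * 5)
  expect_error(bandpass(t, 0, 2, 6, fs), "low")
  expect_error(bandpass(t, 0.1, 8, 6, fs), "fs/2")
})

test_that("the full chain preserves shape and is nearly idempotent on clean band-limited input", {
  rec <- gen_banded_recording(duration = 600, seed = 13)
  cfg <- preprocess_config()
  p1 <- preprocess(rec, cfg)
  expect_equal(dim(p1$data), dim(rec$data))
  expect_true(all(is.finite(p1$data)))
  # a clean slow oscillation passes through almost unchanged twice
  slow <- recording(matrix(rep(sin(2 * pi * 0.02 * (1:6000) / 10),
                               each = 14), 14, byrow = FALSE), fs = 10)
  slow$data <- slow$data + matrix(rnorm(14 * 6000, 0, 1e-3), 14)
  a <- preprocess(slow, cfg)
  b <- preprocess(a, cfg)
  rel <- sqrt(mean((b$data - a$data)^2)) / sqrt(mean(a$data^2))
  expect_lt(rel, 0.02)
})
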