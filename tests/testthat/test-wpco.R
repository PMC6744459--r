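test_that("phase coherence is exactly one for identical signals in every interval", {
  fs <- 10
  dec <- cwt_morlet(multiband(9000), fs)
  for (iv in c("I", "II", "III", "IV", "V")) {
    expect_equal(wpco_pair(dec, dec, iv), 1)
  }
})

test_that("a constant phase lag gives coherence one within 1e-6", {
  fs <- 10
  t <- (0:8999) / fs
  iv_grid <- wavelet_freqs(0.08, 0.125)  # rows the carrier powers
  dx <- cwt_morlet(sin(2 * pi * 0.1 * t), fs, freqs = iv_grid)
  dy <- cwt_morlet(sin(2 * pi * 0.1 * (t - 1.7)), fs, freqs = iv_grid)
  expect_gte(wpco_pair(dx, dy, "III", exclude_coi = TRUE, coi_mult = 3),
             1 - 1e-6)
  # with edge samples included the deficit is only third decimal
  expect_gte(wpco_pair(dx, dy, "III"), 0.99)
})

test_that("coherence ignores amplitude scaling of either signal", {
  fs <- 10
  set.seed(17)
  x <- multiband(4000) + 0.2 * rnorm(4000)
  y <- multiband(4000, phase = 1) + 0.2 * rnorm(4000)
  w0 <- wpco_pair(cwt_morlet(x, fs), cwt_morlet(y, fs), "III")
  w1 <- wpco_pair(cwt_morlet(5 * x, fs), cwt_morlet(0.1 * y, fs), "III")
  expect_equal(w0, w1, tolerance = 1e-10)
  expect_error(
    wpco_pair(cwt_morlet(x, fs), cwt_morlet(y, fs, freqs = c(0.1)), "III"),
    "grid")
})

test_that("channel-pair matrix covers all pairs, is symmetric and matches the pairwise op", {
  rec <- gen_banded_recording(duration = 400, seed = 6)
  res <- wpco_matrix(rec, n_surr = 0)
  expect_equal(nrow(res$pairs), choose(14, 2))
  expect_true(all(res$wpco >= 0 & res$wpco <= 1))
  # fast path equals the reference pairwise implementation
  d3 <- cwt_morlet(rec$data[3, ], rec$fs)
  d8 <- cwt_morlet(rec$data[8, ], rec$fs)
  p <- which(res$pairs$channel_i == "CH03" & res$pairs$channel_j == "CH08")
  for (iv in c("I", "III", "V")) {
    expect_equal(unname(res$wpco[p, iv]), wpco_pair(d3, d8, iv),
                 tolerance = 1e-12)
    expect_equal(wpco_pair(d3, d8, iv), wpco_pair(d8, d3, iv))
  }
})

test_that("surrogate gating marks engineered coherence and spares other intervals", {
  r <- gen_banded_recording(
    coherence = list(list(i = 1, j = 3, rho = 1, interval = "IV")),
    duration = 600, noise_sd = 0.05, seed = 10)
  res <- wpco_matrix(r, n_surr = 8, seed = 2)
  p <- which(res$pairs$channel_i == "CH01" & res$pairs$channel_j == "CH03")
  expect_true(res$significant[p, "IV"])
  expect_gt(res$wpco[p, "IV"], 0.9)
  # significance implies exceeding the stored threshold
  expect_true(all(res$wpco[res$significant] >
                    res$threshold[res$significant]))
})

test_that("region aggregation averages cross-region channel pairs", {
  rec <- gen_banded_recording(duration = 400, seed = 6)
  res <- wpco_matrix(rec, n_surr = 0)
  rw <- region_wpco(res)
  expect_equal(nrow(rw), 15 * 5)
  m <- rec$montage
  chs <- stats::setNames(m$region, m$channels)
  ri <- chs[res$pairs$channel_i]; rj <- chs[res$pairs$channel_j]
  member <- (ri == "LPFC" & rj == "RPFC") | (ri == "RPFC" & rj == "LPFC")
  expect_equal(sum(member), 4)           # 2 x 2 cross-region pairs
  hand <- mean(res$wpco[member, "III"])
  expect_equal(rw$wpco[rw$region_i == "LPFC" & rw$region_j == "RPFC" &
                         rw$interval == "III"], hand)
})
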