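test_that("Morlet transform localizes a sinusoid within one voice", {
  fs <- 10
  t <- (0:5999) / fs
  dec <- cwt_morlet(sin(2 * pi * 0.1 * t), fs)
  pk <- dec$freqs[which.max(rowMeans(Mod(dec$coeffs)))]
  expect_lt(abs(log2(pk / 0.1)), 1 / 16)
  # frequency grid covers all five intervals at >= 10 voices per octave
  expect_true(min(dec$freqs) <= 0.0095 && max(dec$freqs) >= 2 - 1e-9)
  expect_gt(1 / median(abs(diff(log2(dec$freqs)))), 10)
  expect_error(cwt_morlet(t, fs, freqs = c(6)), "fs/2")
})

test_that("transform is linear and zero on zero input", {
  fs <- 10
  x <- multiband(3000)
  d1 <- cwt_morlet(x, fs)
  d2 <- cwt_morlet(2 * x, fs)
  expect_equal(Mod(d2$coeffs), 2 * Mod(d1$coeffs), tolerance = 1e-10)
  d0 <- cwt_morlet(rep(0, 500), fs)
  expect_equal(max(Mod(d0$coeffs)), 0)
})

test_that("wavelet amplitude is band-selective and proportional to amplitude", {
  fs <- 10
  t <- (0:8999) / fs
  amps <- c(1, 2, 4)
  wa3 <- vapply(amps, function(a) {
    wavelet_amplitude(cwt_morlet(a * sin(2 * pi * 0.1 * t), fs), "III")
  }, numeric(1))
  fit <- lm(wa3 ~ amps)
  expect_gt(summary(fit)$r.squared, 0.999)
  dec <- cwt_morlet(sin(2 * pi * 0.1 * t), fs)
  expect_gt(wavelet_amplitude(dec, "III"),
            10 * wavelet_amplitude(dec, "V"))
  # DC offsets do not move band amplitudes (no zero-frequency row)
  dec_dc <- cwt_morlet(sin(2 * pi * 0.1 * t) + 5, fs)
  expect_equal(wavelet_amplitude(dec_dc, "III"),
               wavelet_amplitude(dec, "III"), tolerance = 1e-6)
  expect_equal(wavelet_amplitude(cwt_morlet(rep(0, 4000), fs), "IV"), 0)
})

test_that("cone-of-influence exclusion rejects series too short for the band", {
  fs <- 10
  dec <- suppressWarnings(cwt_morlet(rnorm(600), fs))  # 60 s
  expect_error(wavelet_amplitude(dec, "V", exclude_coi = TRUE),
               "cone of influence")
  # inclusive policy still yields a number
  expect_true(is.finite(wavelet_amplitude(dec, "V", exclude_coi = FALSE)))
})

test_that("region aggregation is the member-channel mean", {
  m <- default_montage()
  wa <- matrix(seq_len(14 * 5), 14, 5,
               dimnames = list(m$channels, c("I", "II", "III", "IV", "V")))
  rw <- region_wa(wa, m)
  ch <- region_channels(m, "LPFC")
  expect_equal(rw["LPFC", "III"], mean(wa[ch, "III"]))
  # permuting channels within a region leaves the region value unchanged
  wa2 <- wa
  wa2[ch, ] <- wa[rev(ch), ]
  expect_equal(region_wa(wa2, m)["LPFC", ], rw["LPFC", ])
  # identical channels collapse to the channel value
  wa3 <- wa
  wa3[ch, ] <- rep(wa[ch[1], ], each = length(ch))
  expect_equal(region_wa(wa3, m)["LPFC", ], wa[ch[1], ])
  expect_error(region_wa(wa[1:13, ], m), "match")
})
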