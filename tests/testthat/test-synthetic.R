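test_that("generators are pure functions of their seed", {
  r1 <- suppressWarnings(gen_banded_recording(duration = 60, seed = 5))
  r2 <- suppressWarnings(gen_banded_recording(duration = 60, seed = 5))
  r3 <- suppressWarnings(gen_banded_recording(duration = 60, seed = 6))
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
  s1 <- gen_coupled_phases(duration = 50, seed = 9)
  s2 <- gen_coupled_phases(duration = 50, seed = 9)
  expect_identical(s1$phi1, s2$phi1)
  inj1 <- inject_artifacts(r1, 3, seed = 2)
  inj2 <- inject_artifacts(r1, 3, seed = 2)
  expect_identical(inj1$rec$data, inj2$rec$data)
  expect_identical(inj1$truth, inj2$truth)
})

test_that("band power concentrates in the specified interval", {
  bands <- default_bands()[3, ]          # myogenic, 0.1 Hz
  r <- gen_banded_recording(bands = bands, n_channels = 2, duration = 600,
                            noise_sd = 0, seed = 1,
                            montage = default_montage())
  frac <- pg_band_fraction(r[1, ], 10, 0.052, 0.145)
  expect_gt(frac, 0.7)
  # spectral peak inside interval III
  pg <- periodogram(r[1, ], 10)
  pk <- pg$freq[which.max(pg$power)]
  expect_gt(pk, 0.052)
  expect_lt(pk, 0.145)
})

test_that("band specification is validated against its interval", {
  bad <- default_bands()
  bad$center_freq[1] <- 0.3              # cardiac band outside 0.6-2 Hz
  expect_error(suppressWarnings(gen_banded_recording(bands = bad, duration = 60)),
               "interval")
  expect_error(
    suppressWarnings(
      gen_banded_recording(coherence = list(list(i = 1, j = 2, rho = 1.5)),
                           duration = 60)),
    "unreachable")
})

test_that("uncoupled oscillators drift at their natural frequencies", {
  sim <- gen_coupled_phases(a12 = 0, a21 = 0, noise_sd = 0.02,
                            duration = 600, seed = 4)
  h <- 1 / sim$fs
  expect_equal(mean(diff(sim$phi1)), sim$omega1 * h, tolerance = 0.02)
  expect_equal(mean(diff(sim$phi2)), sim$omega2 * h, tolerance = 0.02)
  # ground-truth coefficients sit where the basis layout says
  expect_equal(sim$c_true[1, 1], sim$omega1)
  expect_equal(sum(sim$c_true != 0), 2)  # only the two constants
})

test_that("ground-truth coupling coefficients match the basis layout", {
  sim <- gen_coupled_phases(a12 = 0.2, a21 = 0.5, duration = 20, seed = 1)
  nm <- colnames(sim$c_true)
  k <- which(nm == "sin(1p1-1p2)")
  expect_equal(unname(sim$c_true[1, k]), -0.2)  # +a12 sin(p2 - p1)
  expect_equal(unname(sim$c_true[2, k]), 0.5)
})

test_that("artifact injection returns exact ground truth", {
  r <- suppressWarnings(gen_banded_recording(duration = 120, seed = 3))
  r0 <- inject_artifacts(r, 0)
  expect_identical(r0$rec$data, r$data)
  inj <- inject_artifacts(r, 5, spike_sd_mult = 8, seed = 12)
  expect_true(all(inj$truth$sample >= 1 &
                    inj$truth$sample <= n_samples(r)))
  expect_true(all(inj$truth$channel %in% 1:14))
  # spikes actually moved the data
  expect_false(identical(inj$rec$data, r$data))
  expect_error(inject_artifacts(r, 1000), "too many")
})

test_that("cohort generator injects the configured coherence offsets", {
  recs <- suppressWarnings(
    gen_cohort(n_per_group = 2, duration = 60, seed = 8,
               group_effect = c("LPFC-RPFC|IV" = 0.3),
               state_effect = c("LMC-RMC|III" = 0.2)))
  expect_length(recs, 8)
  groups <- vapply(recs, function(r) r$group, character(1))
  states <- vapply(recs, function(r) r$state, character(1))
  expect_equal(sort(unique(groups)), c("control", "trained"))
  expect_equal(sort(unique(states)), c("movement", "resting"))
  tg <- t(vapply(recs, function(r) unlist(attr(r, "targets")),
                 numeric(2)))
  # trained targets exceed control targets by about the offset
  d_group <- mean(tg[groups == "trained", 1]) -
    mean(tg[groups == "control", 1])
  expect_equal(d_group, 0.3, tolerance = 0.15)
  d_state <- mean(tg[states == "movement", 2]) -
    mean(tg[states == "resting", 2])
  expect_equal(d_state, 0.2, tolerance = 0.15)
})

test_that("coherence knob is monotone in measured phase coherence", {
  levels <- c(0.05, 0.4, 0.75, 1)
  means <- vapply(levels, function(rho) {
    mean(vapply(1:3, function(s) {
      r <- gen_banded_recording(
        bands = default_bands()[3, ],
        coherence = list(list(i = 1, j = 2, rho = rho, interval = "III")),
        n_channels = 2, duration = 400, noise_sd = 0.05, seed = s,
        montage = default_montage())
      wpco_series(r[1, ], r[2, ], 10, "III")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
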