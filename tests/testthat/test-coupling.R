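test_that("Fourier basis has the documented layout", {
  for (K in 1:3) {
    info <- fourier_basis_info(K)
    expect_equal(info$M, 1 + 4 * K + 4 * K^2)
    expect_false(anyDuplicated(info$names) > 0)
    expect_equal(length(info$involves_p1), 2 * K + 4 * K^2)
    expect_false(1 %in% info$involves_p1)   # constant is not a coupling term
  }
})

test_that("phase extraction recovers frequency, quadrature and flags silence", {
  fs <- 10
  t <- (0:11999) / fs
  ph <- extract_phase(sin(2 * pi * 0.03 * t), "IV", fs)
  vel <- mean(diff(ph$phi)) * fs
  expect_equal(vel, 2 * pi * 0.03, tolerance = 0.02)
  expect_true(ph$reliable)
  # cos leads sin by pi/2 at every sample
  pc <- extract_phase(cos(2 * pi * 0.03 * t), "IV", fs)
  dd <- (pc$phi - ph$phi) %% (2 * pi)
  expect_equal(stats::median(dd), pi / 2, tolerance = 0.02)
  expect_warning(extract_phase(rnorm(6000) * 1e-12 +
                                 sin(2 * pi * 1 * (0:5999) / fs),
                               "IV", fs), "unreliable")
})

test_that("noiseless constant-velocity phases yield pure drift", {
  t <- (0:5999) / 10
  m <- infer_coupling(2 * pi * 0.03 * t, 2 * pi * 0.045 * t, fs = 10)
  w <- m$windows[[1]]
  expect_equal(w$c1[1], 2 * pi * 0.03, tolerance = 0.02)
  expect_equal(w$c2[1], 2 * pi * 0.045, tolerance = 0.02)
  expect_lt(coupling_strength(m, "1->2"), 0.02)
  expect_lt(coupling_strength(m, "2->1"), 0.02)
})

test_that("the driving coefficient is recovered within 20 percent", {
  sim <- gen_coupled_phases(a21 = 0.5, a12 = 0, noise_sd = 0.05, seed = 2)
  m <- infer_coupling(sim$phi1, sim$phi2, fs = sim$fs)
  w <- m$windows[[1]]
  k <- which(m$info$names == "sin(1p1-1p2)")
  expect_equal(w$c2[k], 0.5, tolerance = 0.2)
  expect_gt(coupling_strength(m, "1->2"),
            3 * coupling_strength(m, "2->1"))
})

test_that("strength and direction closed forms hold", {
  info <- fourier_basis_info(1)
  c2 <- rep(0, info$M)
  c2[info$involves_p1[1:2]] <- c(0.3, 0.4)
  model <- structure(
    list(windows = list(list(skipped = FALSE, c1 = rep(0, info$M),
                             c2 = c2, E = diag(2), n = 100)),
         info = info, K = 1, fs = 10, window_len = Inf, prop_const = 0.2),
    class = "coupling_model")
  expect_equal(coupling_strength(model, "1->2"), 0.5)
  expect_equal(coupling_strength(model, "2->1"), 0)
  expect_equal(coupling_direction(0.4, 0), 1)
  expect_equal(coupling_direction(0.25, 0.25), 0)
  d0 <- coupling_direction(0, 0)
  expect_true(is.na(d0))
  expect_true(attr(d0, "undefined"))
  expect_true(abs(coupling_direction(0.1, 0.7)) <= 1)
})

test_that("relabeling the oscillators swaps strengths and negates D", {
  sim <- gen_coupled_phases(a21 = 0.4, a12 = 0.1, noise_sd = 0.05,
                            duration = 600, seed = 5)
  ma <- infer_coupling(sim$phi1, sim$phi2, fs = 10)
  mb <- infer_coupling(sim$phi2, sim$phi1, fs = 10)
  qa_f <- coupling_strength(ma, "1->2"); qa_r <- coupling_strength(ma, "2->1")
  qb_f <- coupling_strength(mb, "1->2"); qb_r <- coupling_strength(mb, "2->1")
  expect_equal(qa_f, qb_r, tolerance = 1e-10)
  expect_equal(qa_r, qb_f, tolerance = 1e-10)
  expect_equal(coupling_direction(qa_f, qa_r),
               -coupling_direction(qb_f, qb_r), tolerance = 1e-9)
})

test_that("strength is invariant to constant phase offsets", {
  sim <- gen_coupled_phases(a21 = 0.4, duration = 600, seed = 6)
  m0 <- infer_coupling(sim$phi1, sim$phi2, fs = 10)
  m1 <- infer_coupling(sim$phi1 + 2.5, sim$phi2 - 0.9, fs = 10)
  expect_equal(coupling_strength(m0, "1->2"),
               coupling_strength(m1, "1->2"), tolerance = 1e-9)
})

test_that("windowed inference tracks and averages over windows", {
  sim <- gen_coupled_phases(a21 = 0.5, a12 = 0, noise_sd = 0.05, seed = 3)
  m <- infer_coupling(sim$phi1, sim$phi2, fs = 10, window_len = 200)
  expect_gte(length(m$windows), 5)
  q <- coupling_strength(m, "1->2")
  expect_equal(q, 0.5, tolerance = 0.3)
  expect_gt(q, coupling_strength(m, "2->1"))
})

test_that("coupling classification follows the two significance flags", {
  expect_equal(classify_coupling(TRUE, TRUE), "bidirectional")
  expect_equal(classify_coupling(TRUE, FALSE), "unidirectional 1->2")
  expect_equal(classify_coupling(FALSE, TRUE), "unidirectional 2->1")
  expect_equal(classify_coupling(FALSE, FALSE), "none")
  expect_equal(
    classify_coupling(list(significant_fwd = TRUE,
                           significant_rev = FALSE)),
    "unidirectional 1->2")
})

test_that("surrogate gate detects strong coupling through the signal path", {
  sim <- gen_coupled_phases(a21 = 1, a12 = 0, noise_sd = 0.03, seed = 4)
  res <- suppressWarnings(
    ec_significance(cos(sim$phi1), cos(sim$phi2), "IV", 10,
                    n_surr = 10, seed = 8))
  expect_true(res$significant_fwd)
  expect_true(res$q_fwd > res$threshold_fwd)
  expect_true(res$label %in% c("bidirectional", "unidirectional 1->2"))
})
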