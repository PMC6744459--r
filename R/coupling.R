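#' @title Effective connectivity by dynamic Bayesian inference
#' @description The phases of two interacting oscillatory processes are
#'   modeled as coupled stochastic differential equations
#'   \deqn{\dot\phi_l = \sum_k c_k^{(l)} P_k(\phi_1, \phi_2) + \xi_l,}
#'   with a Fourier basis \eqn{P_k} up to order K and white noise of
#'   covariance E.  A Gaussian posterior over the coefficients is updated
#'   window by window (dynamic Bayesian inference); the coupling strength
#'   from oscillator i to k is the Euclidean norm of all coefficients in
#'   k's equation through which \eqn{\phi_i} acts, and the direction index
#'   \eqn{D = (q_{i\to k} - q_{k\to i}) / (q_{i\to k} + q_{k\to i})}
#'   lies in \[-1, 1\], positive when i drives k.
#' @name effective_connectivity
NULL

#' Layout of the Fourier basis used by the coupling model
#'
#' Shared basis over both phases, M = 1 + 2K + 2K + 4K^2 functions:
#' the constant; sin/cos of m phi_1 and of m phi_2 (m = 1..K); and the
#' cross terms sin/cos of (m phi_1 +/- n phi_2) for m, n = 1..K.  The
#' returned index sets say which coefficients involve each phase -- these
#' are the terms whose Euclidean norm defines the coupling strengths.
#'
#' @param K Fourier order.
#' @return List with `M` (basis size), `names`, `K`, and index vectors
#'   `involves_p1`, `involves_p2`.
#' @export
fourier_basis_info <- function(K) {
  nm <- "1"
  for (m in 1:K) nm <- c(nm, sprintf("sin(%dp1)", m), sprintf("cos(%dp1)", m))
  for (m in 1:K) nm <- c(nm, sprintf("sin(%dp2)", m), sprintf("cos(%dp2)", m))
  for (m in 1:K) for (n in 1:K) {
    nm <- c(nm,
            sprintf("sin(%dp1+%dp2)", m, n), sprintf("cos(%dp1+%dp2)", m, n),
            sprintf("sin(%dp1-%dp2)", m, n), sprintf("cos(%dp1-%dp2)", m, n))
  }
  M <- 1 + 4 * K + 4 * K^2
  # coefficient indices through which the partner phase acts
  p1_block <- 2:(1 + 2 * K)
  p2_block <- (2 + 2 * K):(1 + 4 * K)
  cross <- (2 + 4 * K):M
  list(M = M, names = nm, K = K,
       involves_p1 = c(p1_block, cross),   # terms in which phi_1 appears
       involves_p2 = c(p2_block, cross))
}

# evaluate basis and its phase derivatives at phase vectors (length N)
# returns P, D1 = dP/dphi1, D2 = dP/dphi2, each M x N
fourier_basis_eval <- function(phi1, phi2, K) {
  N <- length(phi1)
  info <- fourier_basis_info(K)
  P <- matrix(0, info$M, N)
  D1 <- matrix(0, info$M, N)
  D2 <- matrix(0, info$M, N)
  P[1, ] <- 1
  r <- 1
  for (m in 1:K) {
    r <- r + 1; P[r, ] <- sin(m * phi1); D1[r, ] <- m * cos(m * phi1)
    r <- r + 1; P[r, ] <- cos(m * phi1); D1[r, ] <- -m * sin(m * phi1)
  }
  for (m in 1:K) {
    r <- r + 1; P[r, ] <- sin(m * phi2); D2[r, ] <- m * cos(m * phi2)
    r <- r + 1; P[r, ] <- cos(m * phi2); D2[r, ] <- -m * sin(m * phi2)
  }
  for (m in 1:K) for (n in 1:K) {
    ap <- m * phi1 + n * phi2
    am <- m * phi1 - n * phi2
    r <- r + 1; P[r, ] <- sin(ap); D1[r, ] <- m * cos(ap)
    D2[r, ] <- n * cos(ap)
    r <- r + 1; P[r, ] <- cos(ap); D1[r, ] <- -m * sin(ap)
    D2[r, ] <- -n * sin(ap)
    r <- r + 1; P[r, ] <- sin(am); D1[r, ] <- m * cos(am)
    D2[r, ] <- -n * cos(am)
    r <- r + 1; P[r, ] <- cos(am); D1[r, ] <- -m * sin(am)
    D2[r, ] <- n * sin(am)
  }
  list(P = P, D1 = D1, D2 = D2, info = info)
}

# unwrap phase angles to a continuous series
unwrap_phase <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(theta[1], theta[1] + cumsum(d))
}

#' Extract the instantaneous phase of one frequency interval
#'
#' Zero-phase band-pass to the interval (order 2 per pass), analytic-signal
#' phase, unwrapped; half a cycle of the interval's center frequency is
#' trimmed from each end to drop filter edge effects.
#'
#' @param x Numeric series (preprocessed).
#' @param interval Frequency-interval id (typically `"IV"` or `"V"`).
#' @param fs Sampling rate, Hz.
#' @return List of class `phase_series`: `phi` (unwrapped, rad), `fs`,
#'   `interval`, `f_center` (Hz) and `reliable` (FALSE when the band
#'   holds < 1\% of total variance or the mean phase velocity is more than
#'   a factor 3 away from the interval's center angular frequency).
#' @export
extract_phase <- function(x, interval, fs) {
  iv <- get_interval(interval)
  f_c <- interval_center(iv)
  if (length(x) < 10 * fs / f_c) {
    warning(sprintf("series holds < 10 cycles of %.4g Hz", f_c))
  }
  frac <- band_power_fraction(x, fs, iv$f_low, iv$f_high)
  xb <- spectral_bandpass(x, fs, iv$f_low, iv$f_high, order = 2)
  z <- analytic_signal(xb)
  phi <- unwrap_phase(Arg(z))
  trim <- round(0.5 * fs / f_c)
  if (length(phi) <= 2 * trim + 2) {
    stop("series too short for phase extraction in this interval",
         call. = FALSE)
  }
  phi <- phi[(trim + 1):(length(phi) - trim)]
  vel <- mean(diff(phi)) * fs
  omega_c <- 2 * pi * f_c
  reliable <- is.finite(frac) && frac >= 0.01 &&
    vel > omega_c / 3 && vel < omega_c * 3
  if (!reliable) {
    warning(sprintf(
      "unreliable phase in interval %s (band power fraction %.3g, mean velocity %.3g vs center %.3g rad/s)",
      iv$id, frac, vel, omega_c))
  }
  structure(list(phi = phi, fs = fs, interval = iv$id, f_center = f_c,
                 reliable = reliable),
            class = "phase_series")
}

as_phase_vector <- function(phi) {
  if (inherits(phi, "phase_series")) phi$phi else as.numeric(phi)
}

#' Infer the coupled phase model by dynamic Bayesian inference
#'
#' Per time window, the phase increments are modeled with midpoint-rule
#' discretization: coefficients get a closed-form Gaussian posterior given
#' the noise covariance E, and E is re-estimated from the residuals, the
#' two alternating to convergence.  Between consecutive windows the
#' posterior becomes the next prior with its covariance inflated by
#' `prop_const^2` times its diagonal, so the model can track slow drift.
#'
#' @param phi1,phi2 Unwrapped phases (`phase_series` or numeric, rad).
#' @param fs Sampling rate, Hz (taken from `phi1` when it is a
#'   `phase_series`).
#' @param K Fourier order (default 1; see Details).
#' @param window_len Window length, s; `Inf` (default) fits one window on
#'   the whole series.
#' @param prop_const Propagation constant controlling how much the prior
#'   is diffused between windows.
#' @param prior_precision Precision (inverse variance) of the zero-mean
#'   Gaussian prior on the coefficients in the first window.  Slow
#'   hemodynamic oscillators often phase-lock or sit near resonant
#'   frequency ratios, where parts of the Fourier basis become collinear
#'   along the observed trajectory; a moderate proper prior pins those
#'   unidentifiable directions to zero instead of letting coefficient mass
#'   slosh between them, while identified directions (data curvature
#'   several orders larger) are essentially untouched.
#' @param max_iter,tol Convergence controls for the E / coefficient
#'   iteration.
#'
#' @details With `K = 2` and oscillators near a low-order resonance (e.g.
#'   frequency ratio 3:4) several cross terms evolve at the same beat
#'   frequency along the trajectory and the coefficient vector is not
#'   identifiable; `K = 1` spans the physically dominant sinusoidal
#'   coupling and stays identifiable, hence the default.
#' @return List of class `coupling_model`: per-window coefficient matrices
#'   (`c1`, `c2`), noise covariance `E`, basis `info`, and the settings.
#' @export
infer_coupling <- function(phi1, phi2, fs = NULL, K = 1, window_len = Inf,
                           prop_const = 0.2, prior_precision = 10,
                           max_iter = 100, tol = 1e-6) {
  if (inherits(phi1, "phase_series") && is.null(fs)) fs <- phi1$fs
  if (is.null(fs)) stop("fs required when phases are plain vectors",
                        call. = FALSE)
  p1 <- as_phase_vector(phi1)
  p2 <- as_phase_vector(phi2)
  if (length(p1) != length(p2)) stop("phase series differ in length",
                                     call. = FALSE)
  h <- 1 / fs
  N <- length(p1)
  wlen <- if (!is.finite(window_len)) N - 1 else
    max(round(window_len * fs), 16)
  starts <- seq(1, N - 1, by = wlen)
  if (length(starts) > 1 && (N - 1) - starts[length(starts)] < wlen / 2) {
    starts <- starts[-length(starts)]      # fold a short tail into last
  }
  info <- fourier_basis_info(K)
  M <- info$M
  Xi_p <- diag(prior_precision, 2 * M)
  c_p <- rep(0, 2 * M)
  windows <- list()
  for (wi in seq_along(starts)) {
    a <- starts[wi]
    b <- if (wi == length(starts)) N - 1 else
      min(starts[wi] + wlen - 1, N - 1)
    seg <- a:b
    d1 <- (p1[seg + 1] - p1[seg]) / h
    d2 <- (p2[seg + 1] - p2[seg]) / h
    if (mean(d1) < 0 || mean(d2) < 0) {
      windows[[wi]] <- list(skipped = TRUE, n = length(seg))
      next
    }
    mid1 <- (p1[seg + 1] + p1[seg]) / 2
    mid2 <- (p2[seg + 1] + p2[seg]) / 2
    bas <- fourier_basis_eval(mid1, mid2, K)
    P <- bas$P
    n <- length(seg)
    PPT <- tcrossprod(P)
    Pd1 <- as.numeric(P %*% d1)
    Pd2 <- as.numeric(P %*% d2)
    v1 <- (h / 2) * rowSums(bas$D1)
    v2 <- (h / 2) * rowSums(bas$D2)
    cc <- c_p
    E <- diag(c(stats::var(d1), stats::var(d2)) * h + 1e-12, 2)
    for (it in seq_len(max_iter)) {
      c1 <- cc[1:M]; c2 <- cc[(M + 1):(2 * M)]
      r1 <- d1 - as.numeric(crossprod(P, c1))
      r2 <- d2 - as.numeric(crossprod(P, c2))
      E <- (h / n) * matrix(c(sum(r1 * r1), sum(r1 * r2),
                              sum(r1 * r2), sum(r2 * r2)), 2, 2)
      Ei <- tryCatch(solve(E), error = function(e)
        solve(E + diag(1e-12, 2)))
      Xi <- Xi_p + h * rbind(
        cbind(Ei[1, 1] * PPT, Ei[1, 2] * PPT),
        cbind(Ei[2, 1] * PPT, Ei[2, 2] * PPT))
      rhs <- as.numeric(Xi_p %*% c_p) +
        c(h * (Ei[1, 1] * Pd1 + Ei[1, 2] * Pd2) - v1,
          h * (Ei[2, 1] * Pd1 + Ei[2, 2] * Pd2) - v2)
      cc_new <- tryCatch(solve(Xi, rhs), error = function(e) {
        # ridge fallback for singular normal equations
        solve(Xi + diag(1e-8 * mean(diag(Xi)), 2 * M), rhs)
      })
      delta <- max(abs(cc_new - cc)) / max(max(abs(cc_new)), 1e-12)
      cc <- cc_new
      if (delta < tol) break
    }
    Sigma <- tryCatch(solve(Xi), error = function(e)
      solve(Xi + diag(1e-8 * mean(diag(Xi)), 2 * M)))
    windows[[wi]] <- list(skipped = FALSE,
                          c1 = cc[1:M], c2 = cc[(M + 1):(2 * M)],
                          E = E, n = n)
    # propagate posterior -> next prior with diffusion
    c_p <- cc
    Sig_next <- Sigma + prop_const^2 * diag(diag(Sigma), 2 * M)
    Xi_p <- tryCatch(solve(Sig_next), error = function(e)
      solve(Sig_next + diag(1e-10, 2 * M)))
  }
  if (!any(vapply(windows, function(w) !isTRUE(w$skipped), logical(1)))) {
    stop("all windows skipped (phase-slip dominated)", call. = FALSE)
  }
  structure(list(windows = windows, info = info, K = K, fs = fs,
                 window_len = window_len, prop_const = prop_const),
            class = "coupling_model")
}

#' Coupling strength along one direction
#'
#' Euclidean norm of all coefficients in the target oscillator's equation
#' through which the source phase acts (partner and cross terms); window
#' values are averaged over non-skipped windows.
#'
#' @param model A `coupling_model` from [infer_coupling()].
#' @param direction `"1->2"` or `"2->1"`.
#' @return Nonnegative scalar (rad/s).
#' @export
coupling_strength <- function(model, direction = c("1->2", "2->1")) {
  direction <- match.arg(direction)
  idx <- if (direction == "1->2") model$info$involves_p1 else
    model$info$involves_p2
  vals <- vapply(model$windows, function(w) {
    if (isTRUE(w$skipped)) return(NA_real_)
    cc <- if (direction == "1->2") w$c2 else w$c1
    sqrt(sum(cc[idx]^2))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Coupling direction index
#'
#' \eqn{D = (q_{fwd} - q_{rev}) / (q_{fwd} + q_{rev}) \in [-1, 1]};
#' positive when the first oscillator drives the second.
#'
#' @param q_fwd,q_rev Coupling strengths for the two directions.
#' @return Scalar in \[-1, 1\], or `NA` (with attribute
#'   `undefined = TRUE`) when both strengths are zero.
#' @export
coupling_direction <- function(q_fwd, q_rev) {
  if (q_fwd + q_rev <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (q_fwd - q_rev) / (q_fwd + q_rev)
}

#' Fit the coupling model for a pair of band-limited signals
#'
#' Convenience wrapper: extracts interval phases from both series, fits
#' the model, and returns strengths and direction.
#'
#' @param x,y Numeric series.
#' @param interval Frequency-interval id.
#' @param fs Sampling rate, Hz.
#' @param K,window_len,prop_const See [infer_coupling()].
#' @return List with `model`, `q_fwd` (x drives y), `q_rev`, `D` and the
#'   phase reliability flags.
#' @export
ec_pair <- function(x, y, interval, fs, K = 1, window_len = Inf,
                    prop_const = 0.2) {
  px <- extract_phase(x, interval, fs)
  py <- extract_phase(y, interval, fs)
  model <- infer_coupling(px, py, fs = fs, K = K, window_len = window_len,
                          prop_const = prop_const)
  q_fwd <- coupling_strength(model, "1->2")
  q_rev <- coupling_strength(model, "2->1")
  list(model = model, q_fwd = q_fwd, q_rev = q_rev,
       D = coupling_direction(q_fwd, q_rev),
       reliable = c(x = px$reliable, y = py$reliable))
}

#' Surrogate significance of the two coupling directions
#'
#' The strength of each direction is recomputed with AAFT surrogates of
#' the putative driver (the other series kept intact); a direction is
#' significant when the original strength exceeds the surrogate
#' mean + 2 SD.
#'
#' @param x,y Numeric series.
#' @param interval Frequency-interval id.
#' @param fs Sampling rate, Hz.
#' @param n_surr Number of surrogates per direction (default 50).
#' @param seed Integer seed.
#' @param K,window_len,prop_const Model settings, as in [ec_pair()].
#' @return List with the original `q_fwd`, `q_rev`, `D`, logical
#'   `significant_fwd` / `significant_rev`, the surrogate thresholds, and
#'   the classification label.
#' @export
ec_significance <- function(x, y, interval, fs, n_surr = 50, seed = 1,
                            K = 1, window_len = Inf, prop_const = 0.2) {
  orig <- ec_pair(x, y, interval, fs, K, window_len, prop_const)
  q_of <- function(a, b, dir) {
    fit <- infer_coupling(extract_phase(a, interval, fs),
                          extract_phase(b, interval, fs), fs = fs, K = K,
                          window_len = window_len, prop_const = prop_const)
    coupling_strength(fit, dir)
  }
  xs <- aaft(x, n = n_surr, seed = seed)$series
  ys <- aaft(y, n = n_surr, seed = seed + 1)$series
  sf <- vapply(seq_len(n_surr),
               function(i) q_of(xs[i, ], y, "1->2"), numeric(1))
  sr <- vapply(seq_len(n_surr),
               function(i) q_of(x, ys[i, ], "2->1"), numeric(1))
  thr_f <- mean(sf) + 2 * stats::sd(sf)
  thr_r <- mean(sr) + 2 * stats::sd(sr)
  sig_f <- orig$q_fwd > thr_f
  sig_r <- orig$q_rev > thr_r
  list(q_fwd = orig$q_fwd, q_rev = orig$q_rev, D = orig$D,
       significant_fwd = sig_f, significant_rev = sig_r,
       threshold_fwd = thr_f, threshold_rev = thr_r,
       label = classify_coupling(sig_f, sig_r))
}

#' Classify a coupling relation from its significance flags
#'
#' @param significant_fwd,significant_rev Logical flags (or a list with
#'   those fields as first argument).
#' @return `"bidirectional"`, `"unidirectional 1->2"`,
#'   `"unidirectional 2->1"` or `"none"`.
#' @export
classify_coupling <- function(significant_fwd, significant_rev) {
  if (is.list(significant_fwd)) {
    significant_rev <- significant_fwd$significant_rev
    significant_fwd <- significant_fwd$significant_fwd
  }
  if (significant_fwd && significant_rev) return("bidirectional")
  if (significant_fwd) return("unidirectional 1->2")
  if (significant_rev) return("unidirectional 2->1")
  "none"
}

#' Region-level effective connectivity of a recording
#'
#' Effective connectivity is computed on region-mean signals (one series
#' per region), for every unordered region pair in the slow intervals
#' where neurogenic and endothelial coupling lives.
#'
#' @param rec A preprocessed `fnirs_recording`.
#' @param intervals Interval ids (default `c("IV", "V")`).
#' @param n_surr Surrogates per direction; 0 skips significance.
#' @param seed Integer seed.
#' @param K,window_len,prop_const Model settings.
#' @return Data frame: `region_i`, `region_k`, `interval`, `q_fwd`
#'   (i drives k), `q_rev`, `D`, `sig_fwd`, `sig_rev`, `label`.
#' @export
region_ec <- function(rec, intervals = c("IV", "V"), n_surr = 50,
                      seed = 1, K = 1, window_len = Inf,
                      prop_const = 0.2) {
  validate_recording(rec)
  regs <- REGIONS[REGIONS %in% unique(rec$montage$region)]
  series <- lapply(regs, function(r) {
    colMeans(rec$data[rec$montage$region == r, , drop = FALSE])
  })
  names(series) <- regs
  rp <- region_pairs(rec$montage)
  out <- list()
  for (k in seq_len(nrow(rp))) {
    a <- rp$region_i[k]; b <- rp$region_j[k]
    for (iv in intervals) {
      res <- if (n_surr > 0) {
        ec_significance(series[[a]], series[[b]], iv, rec$fs,
                        n_surr = n_surr, seed = seed + k, K = K,
                        window_len = window_len, prop_const = prop_const)
      } else {
        r0 <- ec_pair(series[[a]], series[[b]], iv, rec$fs, K,
                      window_len, prop_const)
        c(r0[c("q_fwd", "q_rev", "D")],
          list(significant_fwd = NA, significant_rev = NA, label = NA))
      }
      out[[length(out) + 1]] <- data.frame(
        region_i = a, region_k = b, interval = iv,
        q_fwd = res$q_fwd, q_rev = res$q_rev, D = as.numeric(res$D),
        sig_fwd = res$significant_fwd, sig_rev = res$significant_rev,
        label = as.character(res$label), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
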