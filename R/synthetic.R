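#' @title Synthetic hemodynamic data with known ground truth
#' @description Generators for every input the analysis consumes: five-band
#'   oscillatory recordings with controllable pairwise phase coherence,
#'   coupled stochastic phase oscillators with known coupling coefficients,
#'   motion-artifact injection, and two-group/two-state cohorts with
#'   injected coherence effects.  All generators are pure functions of
#'   their seed.
#' @name synthetic
NULL

#' Default band specification, one oscillator per frequency interval
#'
#' Center frequencies sit inside the printed intervals (cardiac 1 Hz,
#' respiratory 0.25 Hz, myogenic 0.1 Hz, neurogenic 0.03 Hz, endothelial
#' 0.015 Hz).  Amplitudes are order-of-magnitude placeholders for
#' spontaneous oxygenation oscillations (fractions of a micromolar); the
#' analyses downstream are amplitude-invariant (phase statistics) or linear
#' in amplitude (wavelet amplitude), so only their ratios matter.
#'
#' @return Data frame with columns `interval`, `center_freq` (Hz),
#'   `amplitude` (uM), `freq_jitter` (relative SD of slow frequency
#'   modulation).
#' @export
default_bands <- function() {
  data.frame(
    interval = c("I", "II", "III", "IV", "V"),
    center_freq = c(1.0, 0.25, 0.1, 0.03, 0.015),
    amplitude = c(0.3, 0.3, 0.5, 0.5, 0.5),
    freq_jitter = 0.03,
    stringsAsFactors = FALSE
  )
}

check_band_spec <- function(bands) {
  tab <- frequency_intervals()
  for (i in seq_len(nrow(bands))) {
    iv <- tab[match(bands$interval[i], tab$id), ]
    if (is.na(iv$f_low) || bands$center_freq[i] < iv$f_low ||
        bands$center_freq[i] > iv$f_high) {
      stop(sprintf("band %d center %g Hz outside interval %s",
                   i, bands$center_freq[i], bands$interval[i]),
           call. = FALSE)
    }
  }
  invisible(bands)
}

# Per-band phases for n_channels channels with pairwise phase-locking
# targets.  Channels joined by a coherence entry share a common phase and
# receive independent Ornstein-Uhlenbeck phase jitter with stationary SD
# sigma_ch; the expected phase-locking of a pair is
# exp(-(sigma_i^2 + sigma_j^2)/2), so sigma_ch^2 = -log(rho) makes the
# expectation hit the target exactly.  Channels not named in any entry get
# their own independent phase.
band_phases <- function(n_channels, n, fs, f_c, jitter, coh_pairs) {
  dt <- 1 / fs
  # phase jitter decorrelates over ~3 cycles: slow enough to stay
  # narrowband, fast enough that a 10-15 min recording averages over many
  # independent excursions (keeps the subject-level coherence estimate
  # close to its expectation exp(-(sigma_i^2+sigma_j^2)/2))
  tau <- max(3 / f_c, 5)
  # slowly modulated common instantaneous frequency
  base_phase <- function() {
    mod <- ou_process(n, dt, jitter * f_c, tau)
    2 * pi * cumsum(f_c + mod) * dt + stats::runif(1, 0, 2 * pi)
  }
  # connected components of the coherence graph
  comp <- seq_len(n_channels)
  sigma2 <- rep(NA_real_, n_channels)
  if (length(coh_pairs)) {
    for (p in coh_pairs) {
      if (p$rho > 1) stop("coherence target > 1 is unreachable",
                          call. = FALSE)
      if (p$rho < 0) stop("coherence target must be in [0, 1]",
                          call. = FALSE)
      rho <- max(p$rho, 1e-6)
      s2 <- -log(rho)
      sigma2[p$i] <- min(sigma2[p$i], s2, na.rm = TRUE)
      sigma2[p$j] <- min(sigma2[p$j], s2, na.rm = TRUE)
      if (p$rho > 0.01) {        # rho ~ 0 means: leave channels independent
        ci <- comp[p$i]; cj <- comp[p$j]
        comp[comp == cj] <- ci
      }
    }
  }
  phases <- matrix(0, n_channels, n)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    shared <- base_phase()
    for (ch in members) {
      if (length(members) == 1 || is.na(sigma2[ch])) {
        # independent channel: fresh phase of its own
        phases[ch, ] <- if (length(members) == 1 && is.na(sigma2[ch]))
          base_phase() else shared + ou_process(n, dt, sqrt(sigma2[ch]), tau)
      } else {
        phases[ch, ] <- shared + ou_process(n, dt, sqrt(sigma2[ch]), tau)
      }
    }
  }
  phases
}

#' Generate a multi-band recording with controlled phase coherence
#'
#' Each channel is a sum over bands of `amplitude * cos(phase)` plus white
#' noise.  Within a band, channels named in `coherence` share a common
#' slowly-frequency-modulated phase plus independent stationary phase
#' jitter whose variance is chosen in closed form so the expected pairwise
#' phase-locking equals the target; unnamed channels get fully independent
#' phases.
#'
#' @param bands Band specification as in [default_bands()] (any subset of
#'   rows).
#' @param coherence List of coherence targets, each a list
#'   `list(i =, j =, rho =, interval =)` with channel indices `i < j`,
#'   target phase-locking `rho` in \[0, 1\] and the band interval id the
#'   target applies to (default: all bands).
#' @param n_channels Number of channels.
#' @param duration Length in seconds.
#' @param fs Sampling rate, Hz (default 10 to mirror the instrument).
#' @param noise_sd White-noise SD, uM.
#' @param seed Integer seed; output is a pure function of it.
#' @param montage Montage to attach when `n_channels` matches it
#'   (otherwise a NULL montage check is skipped and a bare matrix is
#'   returned in the recording slot).
#' @return An `fnirs_recording` (when `n_channels` equals the montage size)
#'   or a plain channels-x-samples matrix with attributes `fs`.
#' @export
gen_banded_recording <- function(bands = default_bands(),
                                 coherence = list(),
                                 n_channels = 14, duration = 900, fs = 10,
                                 noise_sd = 0.1, seed = 1,
                                 montage = default_montage()) {
  check_band_spec(bands)
  slow <- min(bands$center_freq)
  if (duration < 10 / slow) {
    warning(sprintf("duration %gs gives < 10 cycles of the %g Hz band",
                    duration, slow))
  }
  if (fs < 2 * max(bands$center_freq)) {
    stop("fs must be at least twice the fastest band frequency",
         call. = FALSE)
  }
  n <- round(duration * fs)
  withr_seed(seed, {
    x <- matrix(0, n_channels, n)
    for (b in seq_len(nrow(bands))) {
      cp <- Filter(function(p) is.null(p$interval) ||
                     p$interval == bands$interval[b], coherence)
      ph <- band_phases(n_channels, n, fs, bands$center_freq[b],
                        bands$freq_jitter[b], cp)
      x <- x + bands$amplitude[b] * cos(ph)
    }
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n_channels * n, 0, noise_sd),
                      n_channels, n)
    }
    if (n_channels == length(montage$channels)) {
      recording(x, fs = fs, montage = montage)
    } else {
      structure(x, fs = fs)
    }
  })
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate two coupled stochastic phase oscillators
#'
#' Euler-Maruyama integration of
#' \deqn{d\phi_1 = (\omega_1 + a_{12}\sin(\phi_2-\phi_1))\,dt + \xi_1,
#'       \quad
#'       d\phi_2 = (\omega_2 + a_{21}\sin(\phi_1-\phi_2))\,dt + \xi_2,}
#' with independent white phase noise of amplitude `noise_sd` (rad/sqrt(s)).
#' The returned ground-truth coefficient vectors use the Fourier-basis
#' layout of the coupling-inference module, so recovered coefficients can
#' be compared element-wise.
#'
#' @param omega1,omega2 Natural angular frequencies, rad/s.
#' @param a12 Coupling of `sin(phi2 - phi1)` into oscillator 1.
#' @param a21 Coupling of `sin(phi1 - phi2)` into oscillator 2.
#' @param noise_sd Diffusion amplitude, rad per sqrt(s).
#' @param fs Sampling rate, Hz.
#' @param duration Length, s.
#' @param seed Integer seed.
#' @param K Fourier order used for the ground-truth coefficient layout.
#' @return List with unwrapped `phi1`, `phi2`, `fs`, the generating
#'   parameters, and `c_true` (2 x M matrix of true coefficients in the
#'   inference basis; row 1 = oscillator 1's equation).
#' @export
gen_coupled_phases <- function(omega1 = 2 * pi * 0.03,
                               omega2 = 2 * pi * 0.04,
                               a12 = 0, a21 = 0.5, noise_sd = 0.05,
                               fs = 10, duration = 1200, seed = 1, K = 1) {
  stopifnot(omega1 > 0, omega2 > 0, noise_sd >= 0, duration * fs >= 2)
  h <- 1 / fs
  n <- round(duration * fs)
  withr_seed(seed, {
    phi1 <- numeric(n)
    phi2 <- numeric(n)
    phi1[1] <- stats::runif(1, 0, 2 * pi)
    phi2[1] <- stats::runif(1, 0, 2 * pi)
    e1 <- stats::rnorm(n - 1, 0, noise_sd * sqrt(h))
    e2 <- stats::rnorm(n - 1, 0, noise_sd * sqrt(h))
    for (i in seq_len(n - 1)) {
      d <- phi2[i] - phi1[i]
      phi1[i + 1] <- phi1[i] + (omega1 + a12 * sin(d)) * h + e1[i]
      phi2[i + 1] <- phi2[i] + (omega2 - a21 * sin(d)) * h + e2[i]
    }
    basis <- fourier_basis_info(K)
    c_true <- matrix(0, 2, basis$M,
                     dimnames = list(c("osc1", "osc2"), basis$names))
    c_true[1, 1] <- omega1
    c_true[2, 1] <- omega2
    # sin(phi2 - phi1) = -sin(1*phi1 - 1*phi2): basis term sin(m phi1 - n phi2)
    k_sd <- which(basis$names == "sin(1p1-1p2)")
    c_true[1, k_sd] <- -a12          # eq 1: +a12 sin(phi2 - phi1)
    c_true[2, k_sd] <- a21           # eq 2: +a21 sin(phi1 - phi2)
    list(phi1 = phi1, phi2 = phi2, fs = fs,
         omega1 = omega1, omega2 = omega2, a12 = a12, a21 = a21,
         noise_sd = noise_sd, K = K, c_true = c_true)
  })
}

#' Inject motion-artifact spikes into a recording
#'
#' Adds half-cosine bumps 2--5 samples wide at random positions on random
#' channels; the bump peak is `spike_sd_mult` times that channel's SD.
#' Ground-truth indices are returned for detector scoring.
#'
#' @param rec An `fnirs_recording`.
#' @param n_spikes Number of spikes (must be < samples / 10).
#' @param spike_sd_mult Peak height as a multiple of the channel SD.
#' @param seed Integer seed.
#' @return List with `rec` (spiked recording) and `truth`, a data frame of
#'   `channel` (row index) and `sample` indices touched by each spike.
#' @export
inject_artifacts <- function(rec, n_spikes, spike_sd_mult = 10, seed = 1) {
  validate_recording(rec)
  n <- n_samples(rec)
  if (n_spikes >= n / 10) stop("too many spikes for series length",
                               call. = FALSE)
  if (n_spikes == 0) {
    return(list(rec = rec, truth = data.frame(channel = integer(),
                                              sample = integer())))
  }
  withr_seed(seed, {
    x <- rec$data
    truth <- list()
    for (s in seq_len(n_spikes)) {
      ch <- sample.int(nrow(x), 1)
      w <- sample(2:5, 1)
      pos <- sample.int(n - w - 20, 1) + 10
      amp <- spike_sd_mult * stats::sd(x[ch, ])
      bump <- amp * sin(pi * seq_len(w) / (w + 1))
      idx <- pos:(pos + w - 1)
      x[ch, idx] <- x[ch, idx] + bump
      truth[[s]] <- data.frame(channel = ch, sample = idx)
    }
    rec$data <- x
    list(rec = rec, truth = do.call(rbind, truth))
  })
}

#' Generate a two-group, two-state synthetic cohort
#'
#' Emulates a study design with an exercise-trained group and a control
#' group, each recorded in a resting and a movement state.  Coherence
#' effects are injected per region pair and frequency interval: the
#' affected pair's channels share a band phase whose jitter is set so the
#' expected cross-region phase-locking equals
#' `baseline + group_effect (trained group) + state_effect (movement)`,
#' plus a small per-subject jitter.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param group_effect,state_effect Named numeric vectors of coherence
#'   offsets; names are `"REGIONA-REGIONB|INTERVAL"`, e.g.
#'   `c("LPFC-RPFC|IV" = 0.3)`.
#' @param baseline Baseline coherence target for every region pair named in
#'   either effect.
#' @param subject_sd SD of the per-subject jitter on the coherence target.
#' @param duration,fs,noise_sd Passed to [gen_banded_recording()].
#' @param states Which session states to generate (default both).
#' @param seed Integer seed.
#' @return List of `fnirs_recording`s (2 groups x 2 states x n_per_group)
#'   with `group` in `{"control", "trained"}` and `state` in
#'   `{"resting", "movement"}`; attribute `targets` records each subject's
#'   realized coherence targets.
#' @export
gen_cohort <- function(n_per_group = 12,
                       group_effect = c("LPFC-RPFC|IV" = 0.3),
                       state_effect = numeric(),
                       baseline = 0.35, subject_sd = 0.04,
                       duration = 900, fs = 10, noise_sd = 0.1,
                       states = c("resting", "movement"), seed = 1) {
  stopifnot(n_per_group >= 2)
  montage <- default_montage()
  cells <- union(names(group_effect), names(state_effect))
  parse_cell <- function(s) {
    main <- strsplit(s, "|", fixed = TRUE)[[1]]
    regs <- strsplit(main[1], "-", fixed = TRUE)[[1]]
    list(region_i = regs[1], region_j = regs[2], interval = main[2])
  }
  recs <- list()
  targets <- list()
  k <- 0
  for (group in c("control", "trained")) {
    for (state in states) {
      for (subj in seq_len(n_per_group)) {
        k <- k + 1
        sseed <- (seed * 100003 + k * 7919) %% .Machine$integer.max
        coh <- list()
        tg <- list()
        withr_seed(sseed + 1, jit <- stats::rnorm(length(cells), 0,
                                                  subject_sd))
        for (ci in seq_along(cells)) {
          cell <- parse_cell(cells[ci])
          eff <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
          rho <- baseline +
            (if (group == "trained") eff(group_effect, cells[ci]) else 0) +
            (if (state == "movement") eff(state_effect, cells[ci]) else 0) +
            jit[ci]
          rho <- min(max(rho, 0.02), 0.98)
          chi <- match(region_channels(montage, cell$region_i),
                       montage$channels)
          chj <- match(region_channels(montage, cell$region_j),
                       montage$channels)
          for (a in chi) for (b in chj) {
            coh[[length(coh) + 1]] <- list(i = a, j = b, rho = rho,
                                           interval = cell$interval)
          }
          tg[[cells[ci]]] <- rho
        }
        rec <- gen_banded_recording(coherence = coh, duration = duration,
                                    fs = fs, noise_sd = noise_sd,
                                    seed = sseed, montage = montage)
        rec$group <- group
        rec$state <- state
        rec$subject_id <- sprintf("%s%02d", toupper(substr(group, 1, 1)),
                                  subj)
        attr(rec, "targets") <- tg
        recs[[k]] <- rec
      }
    }
  }
  recs
}
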