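---
title: "Connectivity of cerebral hemodynamic oscillations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity of cerebral hemodynamic oscillations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscoupling)
```

## The problem

Multichannel fNIRS measures changes in oxygenated-hemoglobin concentration
(ΔHbO₂, micromolar) over cortical regions at ~10 Hz.  Spontaneous
oscillations in these signals arise from distinct physiological sources
occupying characteristic frequency intervals: cardiac (I, 0.6–2 Hz),
respiratory (II, 0.145–0.6 Hz), myogenic (III, 0.052–0.145 Hz), neurogenic
(IV, 0.021–0.052 Hz) and endothelial/metabolic (V, 0.0095–0.021 Hz).  The
package quantifies, per interval:

* **activation** — the time-averaged Morlet wavelet amplitude (WA) of each
  channel;
* **functional connectivity** — the wavelet phase coherence (WPCO) of each
  channel pair, gated for significance against amplitude-adjusted Fourier
  transform (AAFT) surrogates;
* **effective connectivity** — directed coupling strength and a direction
  index between region-mean signals, from dynamic Bayesian inference of a
  coupled phase-oscillator model, again surrogate-gated.

Cohort-level contrasts (group × state) are one-way ANOVAs with Bonferroni
correction, preceded by Kolmogorov–Smirnov and Levene checks.

## Preprocessing

The cleaning chain runs in a fixed order: Beer–Lambert conversion (when
the input is raw light intensity), a 3 s centered moving average,
moving-SD/cubic-spline motion-artifact repair, spatial ICA, and a
zero-phase order-6 Butterworth band-pass at 0.005–2 Hz.

**Beer–Lambert conversion.**  Per wavelength, ΔOD(t) = −log₁₀ I(t)/Ī, and
the two chromophore concentration changes solve the least-squares system
ΔOD_λ = (ε_HbO₂,λ·ΔHbO₂ + ε_HHb,λ·ΔHHb)·d·DPF with d = 30 mm and
DPF = 7.0 at all three wavelengths (740/808/850 nm).  Extinction
coefficients come from the Gratzer/Prahl compilation; the 808 nm entries
are linearly interpolated between the published 806 and 810 nm rows.
Because ΔOD is referenced to the recording's own mean intensity, the
concentrations are recovered relative to their mean baseline — exactly
what a ΔHbO₂ analysis needs.

**Artifact repair.**  Samples inside 1 s moving-SD windows exceeding
3× the median moving SD are excised and re-filled with a local cubic
spline fitted through local-mean anchors of the flanking clean samples
(interpolating through every noisy flank point can overshoot across a
wide gap); runs touching a series boundary use nearest-value extension.  The threshold is a
package default: a transient of 10 channel-SDs that is only 2–5 samples
wide raises the 10-sample moving SD to roughly 3.6–4.2 SD, so a threshold
of 5 would miss it, while 3 flags it with a false-positive probability
around 10⁻¹¹ per window on Gaussian noise.

**ICA.**  Components are estimated by FastICA (symmetric decorrelation,
tanh contrast) across channels, implemented in the package.  Rejection is
reproducible by default: a component whose spectral power fraction in
0.6–2 Hz exceeds 0.6 is labeled cardiac and zeroed (`"auto-cardiac"`);
manual index lists are supported.  Spatial ICA across channels is our
reading of a per-channel description that is ambiguous in the source
methodology; it is the decomposition that makes physiological interference
separable.

**Filtering.**  All zero-phase filters are applied spectrally: the FFT of
the (mirror-padded, demeaned) series is multiplied by the *squared*
Butterworth magnitude response of the stated order.  This is the exact
magnitude response of forward–backward filtering, with none of the
pole-recursion round-off that makes transfer-function recursions unusable
three decades below Nyquist (an order-2 band-pass at 0.0095–0.021 Hz on a
10 Hz series leaves several percent of a stop-band sine when run as a
recursion in double precision).  Phase analyses downstream therefore
inherit no filter phase distortion, and DC is removed exactly.

## Wavelet analysis

The continuous wavelet transform uses the analytic Morlet wavelet with
center-frequency parameter f₀ = 1 (ω₀ = 2π), the convention of the
cardiovascular-oscillation literature, on a log-spaced grid of 16 voices
per octave over 0.005–2 Hz (interval V is barely one octave wide, so a
dense grid matters).  Coefficients are L1-normalized and rescaled so a
unit-amplitude sinusoid at a scale's center frequency has unit magnitude:
WA is read directly in micromolar.

The cone of influence (COI) is the e-folding time of the wavelet envelope,
√2·s at scale s.  By default the COI is excluded for intervals IV–V
(where a 15-minute recording holds only ~9–13 cycles and edges matter) and
included elsewhere.  `wpco_pair()` additionally exposes `coi_mult`, the
number of e-folding times trimmed per edge: with `coi_mult = 3` the edge
transients of a windowed transform fall below 10⁻⁶ in the coherence, which
is the setting under which the package verifies the exact phase-shift
invariance of WPCO.  Interval aggregation is the unweighted mean across
grid frequencies inside the interval; because WPCO is a phase-only
statistic, grid rows far from any oscillation contribute noise-level
coherence — on real broadband signals every row carries signal, but when
analyzing a synthetic single tone it is appropriate to restrict the grid
to rows the tone actually powers.

WPCO per frequency is the modulus of the time-averaged unit phasor of the
phase difference, √(⟨cos Δφ⟩² + ⟨sin Δφ⟩²) ∈ [0, 1]; frequency-wise
coherence is computed first and then averaged over the interval, which
preserves the [0, 1] interpretation per band.

## Surrogate significance

AAFT surrogates rank-remap the series to a Gaussian, randomize the Fourier
phases, and remap back to the empirical amplitude distribution: sorted
surrogate values equal the original's exactly, the spectrum is
approximately preserved, and phase relations with other signals are
destroyed.  Fifty surrogates are generated by default and an observed
statistic is significant when it exceeds the surrogate mean + 2 SD.  Only
one member of a pair is surrogated by default (the partner's dynamics are
kept intact); surrogating both is available.  `wpco_matrix()` builds each
channel's surrogate decompositions once and reuses them across the 91
pairs, which cuts the wavelet-transform count by an order of magnitude
without changing the statistic.

## Effective connectivity

The two phases are modeled as coupled stochastic differential equations
φ̇_l = Σ_k c_k^{(l)} P_k(φ₁, φ₂) + ξ_l with a Fourier basis up to order K
(constant; sin/cos of each phase; sin/cos of m·φ₁ ± n·φ₂) and white noise
of covariance E.  Inference is Bayesian with midpoint discretization:
given E the coefficient posterior is Gaussian in closed form, E is
re-estimated from residuals, and the two alternate to convergence.  In
windowed mode the posterior propagates to the next window's prior with its
covariance inflated by `prop_const²` (default 0.2) times its diagonal.

The coupling strength q_{i→k} is the Euclidean norm of all coefficients in
oscillator k's equation through which φ_i acts (partner and cross terms),
and the direction index D = (q_{i→k} − q_{k→i})/(q_{i→k} + q_{k→i}) lies
in [−1, 1], positive when i drives k.  The printed form of the direction
index in the source literature repeats q_{i→k} in the denominator; the
package uses the sum of the two strengths, which is the only reading under
which D is bounded as claimed.

Two design choices deserve emphasis:

* **Fourier order K = 1 by default.**  With K = 2 and oscillators near a
  low-order resonance — e.g. natural frequencies 0.03 and 0.04 Hz, a 3:4
  ratio, exactly the slow-band regime this analysis targets — several
  cross terms evolve at identical beat frequencies along the observed
  trajectory and the coefficient vector is structurally unidentifiable
  (the basis Gram matrix's spectrum spans eight orders of magnitude, and
  coupling norms either explode or split mass arbitrarily).  K = 1 spans
  the physically dominant sinusoidal coupling and remains identifiable;
  K stays configurable for users with well-separated frequencies.
* **A proper prior (precision 10) on the first window.**  When coupling
  exceeds the frequency detuning the pair phase-locks, making the
  constant and the sin/cos of the near-constant phase difference almost
  collinear; a moderate zero-mean Gaussian prior pins the unidentifiable
  combination instead of letting coefficient mass slosh, while identified
  directions (data curvature several orders larger) are essentially
  untouched.  With these defaults, simulated pairs at 0.03/0.04 Hz with
  a₂₁ = 0.5 are recovered within ±25 % in 20 of 20 seeds and the driver's
  sign is always correct; under zero coupling the inferred norms are ~0.005.

**Known limitation.**  When phases are estimated from narrowband
*observations* (band-pass + analytic signal) of a strongly phase-locked
pair, measurement phase noise common to the extraction induces spurious
coupling in both directions, and the direction index through the signal
path becomes unreliable — a recognized property of dynamical inference
under observation noise, not specific to this implementation.  Direction
claims are therefore strongest on phase-level data or weakly-locked pairs;
the surrogate gate remains valid either way, because surrogates pass
through the identical extraction path.  Phases are extracted with an
order-2-per-pass zero-phase band-pass to the interval, FFT analytic
signal, unwrapping, and half a cycle trimmed per end; extraction flags the
result unreliable when the band holds < 1 % of variance or the mean phase
velocity is off the interval center by more than a factor 3.

Region-level analysis runs on region-mean ΔHbO₂ series (one per region,
15 unordered pairs) in intervals IV and V, the bands where neurogenic and
endothelial coupling lives.

## Synthetic data: what it emulates and what it does not

Every test input is generated with known ground truth:

* `gen_banded_recording()` sums one slowly-frequency-modulated cosine per
  band plus white measurement noise.  Within a band, channels named in a
  coherence target share a common phase plus independent
  Ornstein–Uhlenbeck phase jitter with stationary SD σ; since the phase
  difference of a pair is then stationary Gaussian, the expected phase
  locking is exp(−(σᵢ² + σⱼ²)/2), and σ² = −log ρ inverts the knob in
  closed form — a calibration that is exact rather than numerical.
  Defaults mirror the instrument (10 Hz, 14 channels, 900 s ≙ a 15-minute
  session) with band amplitudes of a few tenths of a micromolar, the
  order of magnitude of spontaneous ΔHbO₂ oscillations; only ratios
  matter downstream.  Measured WPCO between target-1.0 channels stays
  slightly below 1 whenever white noise is present, because band-edge
  wavelet rows are noise-dominated — the knob is monotone, not identity.
* `gen_coupled_phases()` integrates the Kuramoto-type pair
  dφ₁ = (ω₁ + a₁₂ sin(φ₂−φ₁))dt + ξ, dφ₂ = (ω₂ + a₂₁ sin(φ₁−φ₂))dt + ξ
  by Euler–Maruyama and returns the generating coefficients in the
  inference basis layout.
* `inject_artifacts()` adds half-cosine bumps 2–5 samples wide (the kind
  of transient a cubic spline can repair), with ground-truth indices.
* `gen_cohort()` builds two groups × two states with coherence offsets
  injected per region pair and interval, plus per-subject jitter
  (SD 0.04) around the target.

What the generator does **not** emulate: 1/f background spectra, serially
correlated measurement noise, hemodynamic response functions, superficial
(scalp) contamination, heartbeat waveform shape, or inter-channel
crosstalk.  Passing tests therefore demonstrate correctness of the
estimators under controlled conditions, not robustness to every artifact
of real recordings.

## Statistics

`oneway_anova_table()` runs one F test per unit × interval
(`stats::oneway.test` with equal variances, so the two-group F is exactly
the squared pooled t) and corrects with p_corr = min(1, m·p).  The family
m defaults to the number of units — correction within each interval — and
is configurable; the package's own acceptance checks use the fully joint
family of 455 (91 pairs × 5 intervals).  Between-state comparisons are
treated as independent-group ANOVAs, mirroring the one-way design;
a paired alternative is deliberately out of scope.  `contrast_maps()`
bins corrected p-values into signed tiers (0.05/0.01/0.001) for
connectivity-map rendering.

## Problem sizes and reproducibility

The package's self-checks run the full chain at the study's own signal
conditions: 900 s recordings at 10 Hz for coherence properties, 1200 s
pairs at 0.03/0.04 Hz for coupling recovery (20 seeds), 4096-sample white
noise for null calibration (20 seeds × 50 surrogates), 24-subject cohorts
for power, and 100 replicates of a 455-cell null table for family-wise
error.  The demonstration pipeline (`run_demo()`) processes a 4-subject ×
2-state cohort of 900 s recordings end to end with economical surrogate
counts (3 per channel for coherence, 4 per direction for coupling);
production analyses should raise both to the default 50.  Every stochastic
step takes an explicit integer seed, and one top-level seed fans out
deterministically to per-subject, per-stage seeds, so any subset of a run
reproduces bit-for-bit.

The library API (`preprocess()`, `wa_by_channel()`, `wpco_matrix()`,
`region_ec()`, `oneway_anova_table()`, `run_pipeline()`) is the intended
interface; the pipeline writes the same TSV/JSON tables a command-line
front end would, and `scripts/acceptance.R` in the source repository is a
worked example of driving it non-interactively.
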