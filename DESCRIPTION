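Package: nirscoupling
Title: Functional and Effective Connectivity of fNIRS Hemodynamic Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of spontaneous cerebral oxygenation oscillations
    recorded with multichannel functional near-infrared spectroscopy
    (fNIRS).  Converts raw light intensities to hemoglobin concentration
    changes via the modified Beer-Lambert law, cleans the signals (moving
    average, moving-SD/cubic-spline motion-artifact repair, ICA, zero-phase
    band-pass), decomposes them with a Morlet continuous wavelet transform
    into five physiological frequency intervals (cardiac, respiratory,
    myogenic, neurogenic, endothelial), and quantifies band-wise wavelet
    amplitude, wavelet phase coherence with amplitude-adjusted Fourier
    transform (AAFT) surrogate significance, and directed phase coupling
    (strength and direction) between cortical regions by dynamic Bayesian
    inference of coupled phase oscillators.  Includes a synthetic-data
    generator with controllable coherence and coupling ground truth, and
    cohort-level ANOVA statistics with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils, car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
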