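Package: spikerot
Title: Spike-Train and Kinematics Analysis for Head-Fixed Passive Rotation
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-neuron recordings acquired while a
    head-fixed animal is passively rotated on a platform. Converts LED
    tracking into head-direction kinematics (angle, angular velocity and
    acceleration, linear speed, movement mask, rotation-inversion counts),
    and computes per-cell statistics with permutation significance tests:
    head-direction tuning curves and the Rayleigh-vector HD index with a
    whole-train time-shift shuffle, split-half tuning stability,
    autocorrelogram-based theta rhythmicity with a per-spike shuffle,
    angular-speed modulation scores, waveform features (peak-to-trough,
    half-width, negativity), bursting index, and fast-spiking interneuron
    classification. Includes a synthetic-session generator (inhomogeneous
    Poisson spike trains with von Mises directional tuning, sinusoidal theta
    modulation and linear speed modulation on simulated rotation
    trajectories) so every stage can be exercised without recordings, plus
    group-level Mann-Whitney and Fisher exact comparisons for layer
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
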