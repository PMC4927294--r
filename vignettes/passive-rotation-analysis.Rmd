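---
title: "Analysing head-direction tuning under passive rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing head-direction tuning under passive rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikerot)
```

## The preparation and the statistical problem

`spikerot` analyses single-neuron recordings made while a head-fixed animal
is passively rotated on a platform. A single LED on the rotating apparatus
is tracked at 25 Hz; because the head is fixed to the platform, the LED's
polar angle about the rotation centre *is* the head direction (up to a fixed
offset that only rotates tuning curves). The scientific questions are
per-cell: does the firing rate depend on head direction (HD cells), is
spiking rhythmic in the theta band (4–12 Hz), and does the rate follow
angular speed? Each question is answered with a statistic plus a
permutation (shuffle) null computed from the cell's own spike train, so no
parametric assumption about firing statistics is needed.

## From tracking to kinematics

Raw LED coordinates are boxcar-smoothed with a centred 600 ms rectangular
window (truncated at the edges so every series stays on the 40 ms frame
grid). The rotation centre is estimated by an algebraic (Kåsa)
least-squares circle fit — closed-form and deterministic — and the head
angle is `atan2` about that centre, unwrapped by mapping successive frame
differences into $(-\pi, \pi]$. Angular velocity and acceleration are
forward finite differences on the unwrapped angle,
$\omega_i = \Delta\theta_i / \Delta t$, $\alpha_i = \Delta\omega_i / \Delta t$,
with the last value repeated to keep all series frame-aligned. Linear LED
speed (cm/s) from frame-to-frame displacement defines the movement mask: a
frame is "moving" when speed exceeds 1 cm/s, and **only spikes in moving
frames** enter the HD, theta and speed analyses. Masking is applied after
smoothing; the session manifest records this order.

Direction *inversions* are counted as sign changes of consecutive
frame-to-frame angle differences. Two guards matter: raw differences with
magnitude above $\pi$ are wrap artifacts of the $0/2\pi$ seam and are
re-mapped onto the short arc before sign-counting (a genuine inter-frame
rotation above $\pi$ rad in 40 ms would require ~80 rad/s, two orders of
magnitude above the ~1 rad/s of manual rotation, so the re-mapping loses
nothing physical); and differences below a dead-band of $10^{-4}$ rad are
treated as rest and do not toggle the sign state, otherwise numeric chatter
during rest would register as inversions.

When classifying accelerations versus decelerations, frames with
$|\alpha| < 10^{-9}$ rad/s² are counted as neither: at constant platform
speed the finite-difference $\alpha$ carries floating-point residue whose
sign is meaningless.

## Head-direction tuning

The tuning curve uses 36 bins of 10°. Each spike inherits the head angle of
its containing video frame; occupancy is the summed frame time per bin, and
the rate is spikes divided by occupancy. A session is only analysable for
HD when every bin is visited during movement — violations raise an explicit
error listing the empty bins rather than yielding silent `NaN`s.

The HD index is the mean resultant length (Rayleigh vector) of the binned
curve,

$$R = \frac{\left| \sum_i r_i e^{\mathrm{i}\theta_i} \right|}{\sum_i r_i},$$

read as the rate-weighted average over all bins: 0 for a flat curve, 1 when
all rate mass is in one bin, exactly 0.5 for a raised cosine
$r_i = 1 + \cos(\theta_i - \theta_0)$ on the symmetric bin grid. A
spike-wise alternative (resultant over individual spike angles) was
rejected because the statistic is defined over the binned,
occupancy-normalised curve.

Significance comes from a whole-train time-shift shuffle: each of 1000
permutations adds one uniform random offset to *all* spike times with
circular wraparound over the session and recomputes the index against the
unshifted kinematics. This preserves the full inter-spike structure while
destroying the spike–trajectory alignment. The offset is kept at least 20 s
from either session edge (clamped to a quarter of short sessions) so that
no permutation is a near-identity; the exact value is configurable and has
little effect in practice. The p-value uses the add-one correction
$p = (1 + \#\{R_\mathrm{null} \ge R_\mathrm{obs}\}) / (1 + n_\mathrm{perm})$
so it can never be zero; a cell is an **HD cell** when its observed index
exceeds the 95th percentile of its own null, and a **strong HD cell** when
additionally the index exceeds 0.8 and $p < 0.01$. The one-sided
exceedance fraction and the percentile-rank reading of the criterion
coincide at the 95th percentile, so only the former is implemented.

Split-half stability is the Pearson (linear, not circular) correlation
between tuning curves of the two half-recordings, reported only when every
bin is sampled in both halves — otherwise an explicit reason code
(`bin_coverage`, `zero_variance`) is returned. Tuning curves are never
smoothed before the index, stability or peak rate: the peak rate is the
maximum raw bin rate.

## Theta rhythmicity

The spike-train autocorrelogram uses 10 ms bins out to ±0.5 s; the 1 s
total window is the minimum making "average power within 1 Hz of the peak"
well defined on the spectral grid (1 Hz native resolution). The
autocorrelogram is mean-subtracted before the discrete Fourier transform —
without this, the DC term leaks into the low edge of the 1–50 Hz
denominator and dominates it; this DC-handling choice is the main source of
cross-implementation variation for this statistic and is therefore
configurable and tested. The series is zero-padded fourfold (0.25 Hz grid)
for peak localisation; the padding does not materially change the 1 Hz
averaging windows. The theta index is the mean power within 1 Hz of the
4–12 Hz peak divided by the mean power over 1–50 Hz. Cells with 20 or fewer
spikes are excluded with a reason code, and indices below 5 carry a
descriptive "weak rhythmicity" flag.

The theta null differs from the HD null: each permutation shifts **each
spike independently** by its own uniform offset with session wraparound
(no minimum offset), which preserves the spike count but destroys all
inter-spike-interval structure. Significance again at the null 95th
percentile.

## Speed modulation

The instantaneous rate is the spike count per 40 ms frame divided by
0.040 s, aligned 1:1 with the kinematics frames, with no smoothing (an
optional Gaussian smoother exists but is off by default). The speed score
is the Pearson correlation between that rate and the *unsigned* angular
speed $|\omega|$ over movement frames — rotation is bidirectional, so the
sign of $\omega$ is a nuisance; the signed-$\omega$ correlation is reported
alongside as a secondary value. No filtering of extreme speeds is applied.
The null is the same rigid whole-train shift as for HD. Rest-versus-
rotation firing rates are spike counts over summed durations within each
class of the movement mask.

## Waveform features and cell-type classification

Waveform features come from peak-aligned snippets sampled at 20 kHz.
Baseline is the mean of the first quarter of the snippet. Peak-to-trough
time runs from the positive peak to the subsequent minimum; half-width is
the width of the positive peak at half its baseline-subtracted amplitude
with linear interpolation between samples; negativity is the trough
amplitude as a fraction of peak amplitude. Peak-to-trough (the fast-spiking
criterion) and half-width (the layer-comparison measure) are deliberately
kept as distinct measures. The bursting index is the fraction of spikes
whose *preceding* inter-spike interval is below 6 ms — the
preceding-interval convention avoids double-counting a pair through both of
its members; the first spike contributes only to the denominator.

A cell is classified fast-spiking when the spike is narrow **and** the rate
high. The source studies display these thresholds only graphically, so they
are configuration values with defaults of 0.4 ms peak-to-trough and 5 Hz
mean rate, and every classification echoes the thresholds actually used.

## Group statistics

Between-layer contrasts use the two-sided Mann-Whitney rank-sum test
(exact for small untied samples, normal approximation with tie correction
otherwise — the `stats::wilcox.test` switch) for continuous statistics and
the two-sided Fisher exact test for the proportion of HD cells. No
multiple-comparison correction is applied, and the report metadata says so.
Bootstrap confidence intervals on medians are available but not part of the
standard report.

## The synthetic-session generator

Because no recordings ship with the package, every stage is exercised on
generated sessions whose defaults encode the study conditions: 300 s
sessions at 25 Hz, 6 direction inversions (observed mean 6.6 ± 4.7),
plateau angular speed 1.1 rad/s (observed 1.1 ± 0.4), ramp acceleration
1.3 rad/s² (observed 1.3 ± 0.8), and 20% rest. Rotation epochs follow
trapezoidal speed profiles with seeded duration jitter; rest is inserted as
whole blocks (not interleaved jitter) so the movement mask is unambiguous
in tests. The platform geometry is never stated in the source work and only
matters for converting angular to linear speed at the 1 cm/s cutoff; the
LED lever arm defaults to 10 cm and is configurable.

Spike trains are inhomogeneous Poisson, generated by thinning against the
documented upper bound
$\lambda_{\max} = r_0\, e^{\kappa}/I_0(\kappa) \,(1 + d)\, \max_t s(t)$ of
the intensity

$$\lambda(t) = r_0 \,
\frac{e^{\kappa \cos(\theta(t) - \theta_p)}}{I_0(\kappa)} \,
\bigl(1 + d \cos 2\pi f t\bigr)\,
\max\!\bigl(0,\, 1 + g\,|\omega(t)|/r_0\bigr),$$

i.e. von Mises directional tuning (normalised so the direction-averaged
rate stays $r_0$), sinusoidal theta modulation of depth $d$, and a linear
gain $g$ on angular speed floored at zero. A 2 ms absolute refractory
period is enforced by deletion. The model is an emulation target for the
firing classes in the recorded population — sharp HD cells, theta cells,
speed-modulated fast-spiking interneurons — not a biophysical claim.
Waveforms are biphasic raised-cosine templates with closed-form geometry
(half-width exactly half the positive-lobe duration; peak-to-trough exactly
the mean of the two lobe durations), the fast-spiking template narrower
(0.25 ms peak-to-trough) than the principal template (0.8 ms).

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: tracking noise and LED dropouts, spike-sorting
contamination, slow drift of excitability, bursting beyond what the
refractory-thinned Poisson model produces, and head movements against the
restraint. The generator's role is to give every statistic a ground truth,
not to imitate raw recordings.

## Numerical choices and degenerate inputs

Seeds are explicit everywhere (`session_spec`, `cell_spec`, every shuffle),
and identical configuration plus seeds replays to byte-identical report
JSON. Degenerate inputs fail loudly with reason codes rather than silent
`NA`s: collinear tracking (circle fit), unvisited direction bins, silent
cells, too few spikes for the theta analysis, zero-variance series for the
speed score, empty epoch classes, monophasic waveforms. The per-cell
pipeline catches these per analysis, so one failed statistic never voids a
cell's remaining report fields.

Validation problem sizes were chosen to make the checks sharp but quick:
type-I calibration uses 200 untuned cells on a 300 s session with 500
permutations for the HD null and 200 for the theta and speed nulls (the
expected exceedance rate of the percentile criterion at $n$ permutations is
$(n(1-q)+1)/(n+1)$, i.e. 5.2% and 5.5% — inside the binomial band tested);
parameter recovery uses 100 cells with $\kappa = 2$ and roughly a thousand
movement spikes each; rhythmicity recovery uses 600 s trains at 10 Hz with
depth 0.8. These sizes are stated here so the reported rates can be read
against their sampling error.

## Known limitations

Head fixation precludes any assessment of place, grid or border firing;
nothing here generalises to 2-D foraging data. The theta index depends on
the DC-handling convention (documented above) and is comparable across
implementations only when that convention matches. The percentile-based
shuffle criterion has a small, quantifiable excess over the nominal 5% at
finite permutation counts (see above); at 1000 permutations the excess is
below half a percentage point. The Mann-Whitney confidence intervals
sometimes quoted alongside such tests are not part of the standard report;
medians and p-values are.
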