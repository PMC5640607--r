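---
title: "Methods: decoding and perceiving heading across saccades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding and perceiving heading across saccades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periheading)
```

## The problem and the model

Neurons in the dorsal visual stream (areas MST and VIP) signal heading — the
direction of self-motion — from optic flow, and they do so even while the
eyes track the flow with optokinetic-like movements: slow tracking phases
interrupted by fast resetting saccades. `periheading` implements a
population read-out of heading from such recordings and the statistics
needed to characterize its perisaccadic failure mode, where decoded and
perceived headings transiently converge toward straight ahead.

The read-out rests on a deliberately simple tuning model. Over the central
±30° of azimuth, a neuron's rate is approximated as linear in heading,
`y = a·x + b`. With only three to five sampled headings there is no support
for sigmoid or bell-shaped tuning (no saturation, no flanks), so the linear
form is the appropriate statistical model, and it has the virtue of an exact
inverse: a rate observed in a 20 ms bin converts to a heading estimate
`x̂ = (y − b)/a`. Neurons enter the decoder only if a rank-based test
(Kruskal–Wallis on 1000 ms slice rates across headings, chi-square
approximation, 2 df for three headings) flags them as heading-tuned at
α = 0.05, and the population estimate per bin is the median of the
per-neuron estimates — robust to the long tails that division by small
slopes produces. Estimates are deliberately not clipped to the stimulus
range, so centrifugal biases remain observable.

Compression is the normalized SD: per time bin, the SD of the decoded (or
perceived) heading across stimulus headings, divided by its mean over two
flanking 100 ms windows (−200 to −100 ms and 200 to 300 ms relative to
saccade onset) that are far enough from the saccade to be unaffected. A
value of 1 means baseline separation; the argmin is the time of maximum
compression. For behavioral curves the flanks are all times at least 100 ms
from onset, because reports are sampled quasi-continuously rather than
binned.

## Event extraction

Saccades are detected by the standard speed criterion: 2-D eye speed
(Euclidean norm of the centred finite-difference velocity) at or above
80 °/s, with onset at the first sample above criterion and offset at the
first below. Whether the original criterion was 1-D or 2-D is not
documented for such datasets; 2-D is the default here (`two_dim = FALSE`
gives the horizontal-only variant). Runs shorter than 6 ms (three samples
at 500 Hz) are discarded as noise — the criterion itself is silent on
duration, and single-sample spikes are overwhelmingly measurement noise.

A saccade anchors an analysis snippet spanning −200 to +450 ms around its
onset. The snippet is eligible only if no other saccade onset falls inside
that window — note that this rule is asymmetric: a preceding saccade 300 ms
earlier does not disqualify a snippet, but a following saccade 300 ms later
does — and only if eye position stays within the central 20°-wide window
(±10° on both axes; the phrase "central 20°" is ambiguous between a width
and a half-width, so the limit is configurable via `central_limit`).
Spikes are then binned in half-open 20 ms bins. The grid has 33 bins with
left edges −200, −180, …, 440 ms (a bin's timestamp is its left edge);
this is the unique 20 ms lattice that contains a `[0, 20)` bin aligned to
saccade onset and covers the full window, at the cost of the last bin
extending 10 ms beyond +450 ms.

## The synthetic generators

The generators produce data with the statistical structure the analyses
assume; they define the package's study conditions and are first-class,
tested code.

**Eye traces** alternate constant-velocity slow phases (default 10 °/s)
with minimum-jerk saccades whose peak speed is set explicitly (default
300 °/s), so detector tests have a controllable threshold crossing.
Intersaccadic intervals are exponential (mean 1000 ms) with a refractory
floor and a cap at the time the slow phase drifts about 1.2 amplitudes,
which keeps gaze inside the central screen region the way optokinetic
resetting does; realized amplitudes therefore track the accumulated drift
around the default 10° mean. Because a smooth waveform has no instantaneous
speed step, the generator reports as ground-truth onset the time its
analytic speed crosses the 80 °/s criterion (the field's operational
definition of onset) alongside the kinematic launch time; detector accuracy
is assessed against the former.

**Spiking populations** are linearly tuned with the subpopulation split
38 leftward (a < 0) / 33 rightward (a > 0). Slope magnitudes are log-normal
with median 0.1 (spikes/s)/°, intercepts log-normal with median
12 spikes/s — both anchored on a typical MST fit of
`y = 0.108·x + 11.77` — and rates are clamped at zero before spikes are
drawn (Poisson by default, with optional additive Gaussian rate noise whose
correlation time is one 20 ms bin). The intercept-to-slope ratio matters:
it sets the size of the decode shift `(1 − g)·b/a` that a gain `g`
produces, and the default ratio (~120 °) places the model in the regime
where perisaccadic gain drives decoded headings toward, but not
pathologically past, straight ahead.

**Gain kernels** are multiplicative rate modulations as a function of time
from saccade onset, normalized so their mean over the flanks (more than
100 ms before or after onset) is exactly 1. The default model kernels are
Gaussian: congruent suppression dipping at 80 ms, incongruent enhancement
peaking 40 ms later at 120 ms, both with 40 ms SD and depth 0.25, and a
global kernel defined as their average. The 0.25 depth is chosen to match
the scale of empirical normalized modulation profiles, whose 40–160 ms
modulation indices sit near 0.8 (congruent) and 1.2 (incongruent); with
much deeper kernels the decode shift exceeds the stimulus eccentricity,
decoded headings cross the centre, and the compression minimum degenerates
into a pair of crossing artifacts instead of a single minimum at the time
of maximal modulation.

**Behavioral trials** draw stimulus onsets uniformly over ±200 ms around
saccade onset (matching the ~2.5 ms sampling that latency-corrected designs
achieve) and generate reports as
`gaze + (1 − bias)·(1 − c(t))·(heading − gaze) + noise`, where `c(t)` is a
Gaussian-in-time compression profile (default peak 0.8 at −5 ms, SD 50 ms —
perceived compression peaks just before the saccade), `gaze` is the
eye-in-head offset α (a head offset does not move it), and `bias` is a
static shrink toward gaze present in fixation trials too. The bias is
implemented as a unitless fraction rather than a degree offset, since an
additive constant cannot pull percepts toward the gaze centre for both
heading signs. Report noise defaults to 2° SD, the order of a 1°-tick ruler
response.

What the generators do **not** emulate: flow-field rendering and frame
timing, vergence and torsion, main-sequence kinematics, microsaccades and
blinks, drift in tuning over a session, and correlated noise across
neurons. Passing tests therefore demonstrate that the analysis chain is
correct and internally consistent under the assumed structure, not that the
assumed structure exhausts real data.

## The virtual-neuron model

`run_suppression_model()` repeats the simulated experiment (default 50
times): draw a fresh 71-neuron population, simulate the five headings
(−30°, −15°, 0°, 15°, 30°), apply the gain kernels, clamp rates at zero,
decode each neuron with its own generating tuning, take the population
median per bin, average the decoded time courses across repetitions, and
compute the compression curve of the averaged courses.

The kernels are applied as pointwise multiplicative gain aligned to saccade
onset, not as a sliding convolution: a near-1 kernel convolved along time
would smear rather than produce the localized dip the modulation profiles
show, so "modulating with the response profile" is read as gain. In
selective mode the gain is graded by congruence
`c = sign(a)·h/h_max` — the full congruent kernel at `c = 1`, the full
incongruent kernel at `c = −1`, a linear blend between, and the average of
the two for the straight-ahead stimulus, which prefers neither
subpopulation. The graded blend extends the half-depth treatment of 0°
naturally to ±15° and avoids a binary-assignment artifact in which
intermediate headings receive the full decode shift without the
compensating eccentricity.

## Numerical choices

* **Ties and degenerate inputs.** All-tied rank tests return H = 0, p = 1
  (the chi-square approximation is 0/0 there). Identical rates across
  headings fit slope 0 and are flagged non-decodable; slopes below
  1e-6 (spikes/s)/° are excluded from decoding to avoid division blow-up.
  Flat compression curves (depth below 1e-9, or below `min_depth` = 0.05
  for behavioral curves) report `NA` for the time of maximum compression
  rather than an arbitrary argmin.
* **Multiple comparisons.** Per-bin separation tests are
  Benjamini–Hochberg-adjusted across the 33 bins; "FDR" without further
  qualification is read as BH.
* **Bootstrap.** Percentile intervals from resampling neurons (not
  snippets) with replacement, 1000 resamples, 95% level. BCa would need
  jackknife acceleration for a gain that is negligible at n = 71; the
  percentile choice is documented since reference implementations default
  to BCa.
* **Sign tests.** One-sided binomial tests against 1.0 with ties at
  exactly 1 dropped; the congruent condition is tested for suppression
  (below 1), the incongruent for enhancement (above 1).
* **Cross-correlation.** Curves are block-averaged onto the neural 20 ms
  grid; the reported τ maximizes the Pearson correlation over lags within
  ±200 ms, with positive τ meaning the neural curve lags the behavioral
  one. The sign convention matters because a latency can be quoted with
  either sign depending on which curve is shifted.
* **Running means.** The two-bin running mean used for display assigns
  pairwise averages to midpoint timestamps; statistics always use raw
  bins. The five-trial behavioral running mean truncates at series edges
  (mean of available samples).

## Problem sizes

The test suite and the reproduction script run at the study's native scale
where that is cheap — 71 neurons, five headings, 50 model repetitions,
33 bins, ~200 trials per heading behaviorally — and scale down only the
purely statistical simulations (50-replicate recovery checks, 200-replicate
coverage checks, 1000-replicate type-I-error checks with 10 slices per
group), sizes at which binomial error bands around the nominal rates are a
few percentage points wide.

## Known limitations

The decoder assumes the tuning fitted in the late post-saccadic window
(300–450 ms) is the correct forward model at all times, which is exactly
the assumption whose perisaccadic failure the compression statistic
measures — the package quantifies the failure, it does not fit
time-resolved tuning. The rank test treats 1000 ms slices as exchangeable
replicates and ignores slow nonstationarities. The reference-frame
classifier distinguishes only the centres its two conditions can separate
(gaze versus everything that stays at 0°); body- and screen-centred frames
are indistinguishable from head-centred when only the head is turned.
Kernels are extracted or supplied, never fitted by optimization.
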