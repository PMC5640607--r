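# periheading

Saccadic eye movements transiently distort the brain's representation of
heading — the direction of self-motion read out from optic flow by neurons
in macaque areas MST and VIP. Around the time of a saccade, headings decoded
from such populations converge toward straight ahead ("perisaccadic
compression of heading"), and human observers misperceive briefly flashed
self-motion stimuli the same way. `periheading` implements the complete
analysis chain for studying this phenomenon, from raw eye traces and spike
times to decoded-heading time courses, compression statistics, saccadic
suppression models, and the matching psychophysics — together with synthetic
generators so that every stage can be exercised and tested without recorded
data.

The package is written for computational neuroscientists working on
population decoding, perisaccadic perception, or saccadic suppression. All
user-facing functions take a data frame first and return tibbles, so stages
chain with the pipe; result objects have `tidy()`, `glance()` and
`autoplot()` methods.

## The model at the core

Each neuron's heading tuning is approximated linearly,

    y(t) = a * x(t) + b

with `y` the firing rate (spikes/s), `x` the heading (deg, rightward
positive), `a` the tuning slope and `b` the intercept. Decoding inverts the
fitted line per neuron and 20 ms bin,

    x̂(t) = (y(t) - b) / a

and the population estimate is the median of the per-neuron estimates.
Compression is quantified as the standard deviation across the decoded (or
perceived) heading time courses, normalized by its mean in two flanking
windows (200–100 ms before and 200–300 ms after saccade onset); the time of
maximum compression is the argmin of that curve. Perisaccadic response
modulation is summarized by the modulation index — the ratio of the mean
rate 40–160 ms after saccade onset to the rate 300–450 ms after — and by
multiplicative gain kernels obtained by normalizing condition-averaged rate
time courses to a flank mean of 1. A virtual population of 71 linearly tuned
neurons, modulated by these kernels either globally (all neurons alike) or
selectively (suppression of congruently stimulated neurons, enhancement of
the others), shows that only selective suppression reproduces the
compression.

## Worked example

Contrast global and selective saccadic suppression in the virtual-neuron
model:

```r
library(periheading)

m_sel <- run_suppression_model("selective", seed = 7)
m_glo <- run_suppression_model("global",    seed = 7)
compare_modes(m_sel, m_glo)
#> # A tibble: 2 × 4
#>   mode      min_normalized_sd t_max_compression_ms n_repetitions
#>   <chr>                 <dbl>                <dbl>         <dbl>
#> 1 selective             0.213                  100            50
#> 2 global                0.899                   60            50
```

Under selective suppression the normalized SD of the five decoded headings
collapses to 0.21 of its flank level, with maximum compression 100 ms after
saccade onset; under global suppression the curve barely moves (minimum
0.90). `autoplot(m_sel$compression)` draws the compression curve,
`autoplot(m_sel$decoded)` the decoded headings.

The full synthetic pipeline — eye traces, spikes, saccade detection, tuning
fits, decoding, modulation indices, the model, and the behavioral analyses —
runs from one seed:

```r
res <- run_pipeline(seed = 1, trial_duration_s = 30, n_repetitions = 10,
                    behavioral_args = list(trials_per_heading = 100))
res
#> periheading pipeline run (seed 1)
#>   neurons: 71  tuned: 70
#>   neural compression min: 0.224 at 60 ms
#>   behavioral compression min at -7.5 ms
#>   cross-correlation latency: 100 ms

res$sign_tests
#> # A tibble: 2 × 6
#>   condition       n median ci_low ci_high      p_sign
#>   <chr>       <int>  <dbl>  <dbl>   <dbl>       <dbl>
#> 1 congruent      70  0.835  0.774   0.897 0.000000555
#> 2 incongruent    68  1.13   1.10    1.22  0.0000337
```

70 of the 71 synthetic neurons test as significantly heading-tuned; their
modulation indices show suppression in the congruent condition (median
0.84 < 1) and enhancement in the incongruent condition (median 1.13 > 1),
both significant by a one-sided sign test. The behavioral compression of the
simulated heading reports peaks just before saccade onset (−7.5 ms), and the
cross-correlation between the neural and behavioral compression curves
recovers the simulated neural processing latency.

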