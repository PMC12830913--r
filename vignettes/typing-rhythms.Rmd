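---
title: "Inferring diurnal rhythms from typing dynamics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring diurnal rhythms from typing dynamics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(typerhythm)
```

## The problem

Smartphone keyboards record when a person types, how fast they type, and
how the phone is held while they do. Because typing happens throughout the
waking day and stops during sleep, these traces carry a diurnal rhythm —
but an indirect and heavily censored one: an hour without typing may mean
sleep, or merely a phone left in a pocket. `typerhythm` implements a
framework that separates those two kinds of absence by assuming most
people keep a *stable 24-hour rhythm*: hours are imputed from their
temporal neighbours and from the same hour on adjacent days, so an
isolated quiet hour inside an active day is filled in as active, while a
consistent nightly block stays quiet.

## Data model

Sessions are binned by the UTC hour of their start time into day-by-24
matrices of four modalities: median alphanumeric inter-key delay (pooled
across the hour's sessions; delays above 5 s are treated as pauses, not
typing), total key presses, and the fractions of sessions typed upright
and while moving. An hour with no sessions is missing in *all* modalities:
the premise of the framework is that absent data may mean sleep, so
absence is left for the decomposition to impute rather than recorded as an
observed zero. Matrices are built on UTC days deliberately — travel then
appears as a phase shift of the rhythm instead of being hidden by local
clock changes — and the local UTC offset is kept as per-day metadata for
the transition analysis. Each modality is z-scored over its observed cells
(population denominator) and the inter-key delay is negated, so that
larger always means more or faster activity.

## The graph-regularised SVD

The four matrices are vectorised (day-major) and stacked into one
4 × 24·D matrix `X` sharing a single time factor. The temporal graph
connects consecutive hours within a day, the last hour of a day to the
first hour of the next, and each hour to the same hour on adjacent
days — a spiral with crosslinks. Days absent from the grid contribute no
edges, so a gap in the record splits the graph and stops information
flowing across it; days that are present but fully unobserved keep their
nodes and are imputed. Edges are unweighted by default (a single
connection type), with hour- and day-weights exposed for experimentation.

Per component, on the current residual `R`, the fit minimises

$$F(u, v) \;=\; \sum_{(m,t)\,\text{observed}} (R_{mt} - u_m v_t)^2
\;+\; \lambda\, v^\top L v, \qquad \lVert u\rVert_2 = 1 .$$

The norm constraint matters: without it the penalty could be dodged by
shrinking `v` and growing `u`. Internally the solver minimises the
scale-invariant form $\sum_{obs}(R-uv^\top)^2 + \lambda\lVert u\rVert^2
v^\top L v$, whose value along the ray $(cu, v/c)$ is constant and equals
$F$ at $\lVert u\rVert=1$; both coordinate updates then stay closed-form
(a sparse symmetric solve for `v`, masked least squares for `u`) and each
is an exact minimiser, so the objective is non-increasing by
construction. Further components are fitted by deflating the observed
residual entries; downstream analyses use only component 1.

Numerical choices:

* **Initialisation** — `v` from the per-bin mean of observed standardised
  values (zeros where never observed), `u` from the masked projection;
  fully deterministic.
* **Convergence** — relative objective change below `tol` (default 1e-8)
  or 500 iterations; objectives at rounding-noise level (exactly low-rank
  input) count as converged. Non-convergence returns the fit with a
  warning rather than an error.
* **Sign** — each component is flipped so the key-count loading is
  non-negative: higher scores mean more typing.
* **Degeneracy** — with `lambda = 0` a time bin observed in no modality
  makes the v-solve singular; the error message says to use
  `lambda > 0` or drop the bin. With `lambda > 0` the solve can only fail
  when an entire graph component is unobserved.

**Choosing λ.** λ trades smoothness against fidelity and in the source
framework is tuned by hand. The automatic default (`select_lambda()`)
hides 20 % of the observed time bins, fits over a log-spaced grid, and
takes the *smallest* λ whose held-out imputation RMSE is within 1 % of the
minimum — the profile is typically flat over orders of magnitude, so the
tolerance keeps the choice from being decided by fourth-decimal noise, and
undersmoothing is the conservative direction for the downstream sleep
edges. Manual override is a single argument.

## Sleep extraction

The component-1 score histogram of a rhythmic user is bimodal: a night
mode and a wake mode. Cells strictly below a threshold are classified as
sleep and counted per day; ties are wakeful, and no contiguity is
required. The threshold default is the `valley` method — the KDE antimode
between the two largest density modes (bumps under 5 % of the main mode's
height are ignored), the automatic analogue of placing a dashed line in
the histogram gap by eye — with Otsu's between-class-variance criterion as
the fallback when the density looks unimodal, and a `manual` value always
available. Days with fewer than 4 observed hours are dropped by default:
extreme estimates concentrate on days with little data.

Two limitations are inherent rather than incidental. First, the imputed
night block is interpolated from the *observed* values flanking it, so the
method needs activity to decline toward the sleep window; hours of quiet
wakefulness adjacent to sleep are indistinguishable from sleep itself and
bias the count upward by roughly their number. Second, a threshold on a
histogram cannot split two populations whose scores coincide — the method
therefore tends to overestimate sleep slightly, and simulated median
absolute errors of about 1 h are the realistic floor, not a tuning
shortfall.

## Phase extraction and travel analysis

Each day's score row is reinterpreted in polar coordinates: hour `h` maps
to the bin-centre angle `2π(h+0.5)/24` (an hourly aggregate represents the
whole hour; the half-hour offset avoids a systematic early bias), and the
score gives the vector length. Negative scores are clipped to zero by
default — a vector length cannot be negative — with `shift-min` and
`softplus` mappings exposed. The weighted circular mean's angle is the
day's phase (time of peak activity) and its normalised resultant length
measures phase coherence; a zero resultant flags the phase as undefined
rather than raising an error. Because a ~16-hour activity arc has a small
resultant, single-day phases carry roughly ±1–1.5 h of noise; analyses
should average across days or transitions.

A time-zone transition is a day whose UTC offset differs from the previous
day's and persists for at least 7 days (configurable); short-lived changes
are discarded, which also resolves overlapping candidates, and a minimum
magnitude filter (e.g. ≥ 2 h) is available. For each transition the
unweighted circular mean phase of the 3 pre-transition days forms a
baseline, and days −3…+7 report their signed circular difference from it,
mapped to (−12, +12] hours so a 23 h → 1 h change reads +2 h. Pooled over
transitions, east- and westward groups are compared per offset day with
Welch's unequal-variance t-test (`stats::t.test`), starred at
0.05/0.01/0.001. Viewed from UTC, westward travel increases the phase and
eastward travel decreases it; the simulations reproduce both the sign and
the first-post-day significance of that pattern.

## What the synthetic data emulate — and what they do not

The generator produces the statistical structure the framework assumes,
with defaults chosen once as realistic for a single adult user:

* a sleep window centred on a 03:30 chronotype midsleep, duration
  8 ± 0.5 h (well within the mode of adult sleep);
* plateau-like waking phone use with a mild (amplitude 0.2) sinusoidal
  midday peak, session counts 1 + NegBin(mean 3 − 1) per active hour
  (overdispersed, as real usage counts are), boundary hours thinned by
  their awake fraction (typing continues until lights out, but only
  during the awake part of the hour);
* brief nocturnal awakenings with a single short, slow session at
  0.1/sleep-hour — the sparse within-night observations that anchor the
  imputed night block at genuinely low activity;
* lognormal inter-key delays whose median follows a sinusoidal
  performance curve (slowest around 03:00 local, amplitude 15 %) with a
  per-session random effect (sd 0.25 log) so hourly medians are noisy
  around the curve, as heterogeneous real sessions make them;
* upright/movement flags with distinct rates near the sleep window
  (in-bed use is flat and stationary);
* 20 % wake-hour missingness, 2 % whole missing days, and offset
  schedules with direction-specific re-entrainment (eastward slower by
  default, a free parameter).

Ground truth records exact per-UTC-day sleep hours (midpoint rule per
hour) and the wake-midpoint phase. Wearable and self-report emulators add
Gaussian noise clipped to [0, 24] (naps excluded by default) and
nearest-hour rounding top-coded at 10, respectively.

Passing tests on these data show that the pipeline recovers rhythms *when
the stable-rhythm assumption holds*. They do not show robustness to what
the generator omits: irregular or fragmented sleep, shift-work schedules,
weekday/weekend structure, autocorrelated missingness (e.g. vacations
without the phone), typing-style drift, or populations whose phone use
does not decline toward sleep. On such data the smoothing assumption
itself is violated and the regularisation would need re-tuning, as the
framework's own authors note for clinical populations.

## Problem sizes and determinism

The test-suite and acceptance experiments use 8–90-day single-user
scenarios, a 4 × 240 matrix for the SVD-limit check, a 2 × 8 masked toy
against a BFGS oracle, 20-day matrices for the imputation comparison, and
a 252-day schedule with ten ±6 h transitions per direction — sizes at
which every experiment completes in seconds while leaving the phenomena
(imputation, thresholding, re-entrainment) clearly visible. All
randomness flows from explicit seeds; `simulate_user()` is bit-for-bit
reproducible and a pipeline rerun with the same config and seed writes
byte-identical artefacts.

## Known limitations

* Only component 1 is used downstream; higher components are fitted by
  deflation and exposed but unanalysed.
* Sleep is reported as hours per UTC day, not as onset/offset clock
  times, and no nap/bedtime disambiguation is attempted.
* The east/west comparison pools transition-day observations as
  independent; no mixed model is fitted (a model-ready export,
  `export_model_table()`, is provided instead).
* Group-level joint decompositions across users are out of scope.
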