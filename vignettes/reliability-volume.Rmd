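---
title: "Reliability Volume: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability Volume: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvskill)
```

## The model

Reliability Volume (RV) treats a training repetition as a success when the
whole instrument path stays inside a tolerance tube around the expert's
standard path. With a standard path $S = \{s_1, \dots, s_N\}$ and $M$
repetitions $T_m = \{t_{m1}, \dots, t_{mN}\}$ sharing the index length
$N$, the pointwise deviation is $d_{mn} = \lVert t_{mn} - s_n \rVert$.
For a tolerance radius $d_j$, the working-space volume is the cylinder
$V_j = \pi d_j^2 h$ coaxial with the standard path, and the empirical
reliability is the fraction of repetitions whose *maximum* deviation stays
within $d_j$:

$$R_j = \frac{1}{M} \sum_{m=1}^{M}
  \mathbf{1}\!\left[\max_n d_{mn} \le d_j\right].$$

The RV metric is the ordered pair $(R_j, V_j)$ swept over a descending
ladder of radii. Two monitoring views derive from it: the smallest volume
reaching a target reliability (precision at constant success probability)
and the reliability at a fixed volume (consistency at constant
tolerance), both evaluated on cumulative prefixes of the training series.

### The success criterion

The conformity test is deliberately worst-case per repetition: a single
excursion exits the tube, so the path fails at that radius. The state
function $Z = d_{mn} - d_j$ partitions the deviation space; a repetition
conforms only when $Z \le 0$ at every index. An average-based reading of
the criterion would reproduce the conventional working volume's known
insensitivity to transient lapses — exactly what RV is designed to see.
This is also why the per-path-maxima ladder is the default: reliability
changes only when the radius crosses some path's maximum, so the $M$
distinct maxima carry every attainable reliability value. The full
deviation multiset (`ladder = "full"`) is available for fidelity to the
ladder's original description; it adds rungs, never information (rungs
below every maximum only ever add $R = 0$).

### The tube length h

Two conventions coexist for $h$: the arc length of the standard path (the
definition attached to the volume formula itself) and the fixed 2 cm
height of the physical workspace the task is performed in. Both are
supported through `h_mode`; `"arclength"` is the default because it makes
$V$ scale with the task's geometry, and `fixed_h = 2` reproduces the
workspace convention. Which convention produced any given published
volume is not always recoverable, since the back-computed radius depends
on the choice; traces and curves therefore always record the $h$ they
used.

## Preparation: index alignment

Deviations pair points strictly by index — no elastic (DTW-style)
alignment, which would be a different metric. Recordings of different
frame counts are brought to a common $N$ by arc-length resampling of the
piecewise-linear path, endpoints preserved exactly. `repetition_set()`
resamples a path *only when its count differs from the target*, so
already-aligned ensembles keep exact pointwise correspondence.

One caveat documented rather than hidden: uniform arc-position resampling
places new vertices on the original polyline, so it cuts corners. For
densely sampled smooth recordings the arc-length error is negligible
(halving a 10,000-point circle changes its length by less than one part
in $10^6$), but resampling a noise-dominated jagged polyline shortens it
materially. The resampler is a preparation step for recordings sampled
well above the motion's spatial scale, not a smoother.

## Monitoring and the stopping rule

Session snapshots are cumulative prefixes (repetitions $1..m$), so a
reliability at checkpoint $m$ has denominator $m$ — matching how
snapshot tables at 10/25/50 repetitions are conventionally reported, and
making every reliability an exact multiple of $1/m$. Checkpoints default
to (10, 25, 50) and are fully configurable.

The stopping rule scans consecutive checkpoint pairs in order and
triggers at the first absolute reliability change $|\Delta R| \ge 0.05$
at a fixed volume, reading skill from the checkpoint immediately
preceding the change. The rule is two-sided by design: an improvement is
also a departure from steady state, and the two-sided first-trigger
reading is the only one consistent with both published worked decisions
(one triggered by an improvement, one by a plain increase after a flat
pair). Gradual drifts that never produce a single step of 0.05 are a
known blind spot of the threshold form and out of scope here.

## The synthetic generator

No motion-capture recordings ship with the package, so validation rests
on a generator with known statistical structure. The default standard
path is a two-loop helix (radius 1 cm, 0.3 cm pitch per loop, $N = 200$,
winding $4\pi$) — the two-full-loop geometry of a knot-tying exercise at
roughly hand scale, without claiming biomechanical fidelity. Repetitions
add i.i.d. isotropic Gaussian noise of per-axis scale $\sigma_m$ to every
point. Three schedules emulate training dynamics:

* **flat** — constant $\sigma$ (steady state; default 0.1 cm, about the
  marker-scale variability a steady trainee shows at centimetre-scale
  geometry);
* **learning** — $\sigma$ decaying geometrically to half its starting
  value across the series;
* **fatigue** — flat $\sigma$ with a ×3 spike over 5 consecutive
  repetitions, placed just past mid-series by default so it falls between
  the later checkpoints.

Under this model each pointwise deviation is $\sigma_m$ times a
chi-distributed variable with 3 degrees of freedom, independent across
indices, giving the closed-form containment law

$$R(d) = F_{\chi_3}(d/\sigma)^N$$

implemented in `analytic_reliability()` (via the chi-squared distribution
on the squared variable) and used as an independent oracle against the
empirical estimator. Inverting the chi(3) mean
$\mathbb{E}[d] = 2\sigma\sqrt{2/\pi}$ gives the moment estimator
`estimate_sigma()`, closing a parameter-recovery loop that checks
generator and metric against each other.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real recordings: temporal autocorrelation of hand
tremor, heteroscedasticity along the path (knot-tying is harder in some
segments), systematic bias (a trainee consistently offset from the
standard), marker dropout, and any velocity or duration structure. The
isotropic model is a test harness, not a claim about trainees.

## Numerical choices and degenerate inputs

* Duplicate deviation values collapse to one ladder rung; reliability at
  a duplicated value is computed once.
* `volume_at_reliability()` uses the weak inequality $R \ge$ target and
  returns the smallest qualifying rung. With $M$ repetitions the
  attainable values are $k/M$, so a 0.95 target at $M < 20$ effectively
  demands that every repetition conform.
* The conventional working volume centres each repetition's sphere on the
  path's own centroid (the natural reading of a "hand-centered point")
  and averages sphere volumes arithmetically across repetitions; a
  degenerate all-coincident path contributes volume 0 with a warning.
* Zero-length paths (all points coincident) cannot be resampled and raise
  a degenerate-path error; coordinates must be finite.
* Frame indices need not start at 0; ordering is by frame value with ties
  kept in file order. Units are centimetres throughout (volumes in cm³);
  unit conversion is the caller's responsibility.
* All simulation randomness flows through one seed carried by the noise
  profile.

## Validation problem sizes

The test suite exercises the estimator at sizes chosen to make the
statistics sharp while keeping the suite quick to run: the brute-force
state-function oracle on 200 random instances ($M \le 10$, $N \le 20$);
the chi(3)$^N$ closed-form limit at $\sigma = 1$ cm, $N = 50$, $M = 2000$
repetitions, checked at ten radii spanning analytic success probabilities
0.05–0.95 within three binomial standard errors; noise-scale recovery at
$M \times N = 10^4$ within 5%; and the learning/fatigue dynamics over 100
seeded runs each (learning must shrink the $R = 0.95$ volume between the
first and last checkpoint; a calibrated mid-series fatigue spike must
trip the stopping rule).

## Known limitations

Index-based correspondence assumes repetitions traverse the task at
broadly comparable pacing; strongly time-warped executions inflate
deviations that elastic alignment would forgive — by design, but worth
knowing. The metric carries no temporal information (duration, velocity,
smoothness). The stopping rule reacts to step changes only. And with
small $M$, reliability is coarse ($1/M$ granularity), so fixed-volume
traces at early checkpoints move in visibly discrete steps.
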