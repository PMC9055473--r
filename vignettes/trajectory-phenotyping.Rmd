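---
title: "Phenotyping weight-loss trajectories with DTW k-means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping weight-loss trajectories with DTW k-means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajclust)
```

## The problem and the model

A 16-week mobile weight-management program produces, for every user, an
irregular sequence of self-logged weights together with streams of
app-use events: meal logs, messages exchanged with a coach, daily step
counts. End-of-program percent weight change collapses this record to one
number and hides its dynamics — a user who lost 6%, regained, and lost
again is indistinguishable from one who lost 6% steadily. `trajclust`
phenotypes the *shape* of the weight course: it standardizes each series
to a fixed-length, scale-free trajectory, clusters trajectories with
k-means under dynamic time warping (DTW), and then asks which app-use
behaviours separate the resulting phenotypes, cross-sectionally and week
by week.

The method makes three substantive assumptions. First, shape rather than
level is the unit of analysis: a 150 kg and a 90 kg user who both lose 8%
along the same course belong together, which is why every series is
z-normalized before clustering. Second, modest temporal misalignment is
noise, not signal — users hit their nadir a week or two apart — which is
why distances are DTW rather than Euclidean. Third, a small number of
latent archetypes usefully summarizes the population; the number is
chosen from the inertia curve, not assumed.

## Eligibility cascade

Users enter the analysis only if their record can support an outcome.
The cascade applies, in order: at least one weight log; height within
[125, 230] cm (an implausible-entry screen); adult age (≥ 18 years — the
criterion says "adult" without a number, and 18 is the US convention);
initial BMI ≥ 25 kg/m², the overweight criterion; a final weight; no
physiologically inconsistent jumps (BMI change ≥ 3.5 kg/m² between
consecutive logs within 30 days, or ≥ 7.0 within 60 days — months are
read as fixed 30-day blocks so the rule is exactly testable); and minimal
self-monitoring (≥ 1 meal log in every program week, a configurable
stage). The first failing stage is the user's exclusion reason, so
reasons are mutually exclusive and the flow table conserves counts at
every stage.

Two windows need conventions the source material leaves open:

* **Weeks**: week *w* covers day indices [7(*w*−1), 7*w*−1], so the
  16-week program spans days 0–111. The *initial* weight is the earliest
  log in [−14, +7] days — records up to two weeks before coaching count
  as "before coaching", and the window is configurable because no lower
  bound is published. The *final* weight is the last log of week 16,
  falling back to week 17 (days 112–118) only when week 16 is empty.
* **Target-weight screening** (excluding users whose target exceeds
  their initial weight) activates only when a `target_weight_kg` column
  is present, since target weight is not part of the core log schema.

## Standardization

Each user's series is reduced to 16 dimensionless points in three steps.

1. **Regularization.** Duplicate same-day logs are averaged (the
   alternative first/last-taken conventions are unstated anywhere and
   averaging is symmetric). The series is then evaluated at 30 equally
   spaced time points spanning its observed range, by linear
   interpolation of the piecewise-linear interpolant. For sparse series
   this is interpolation; for dense ones it is equal-interval resampling;
   the two branches are deliberately the same operator, which keeps short
   and long records comparable.
2. **Smoothing.** A valid-mode centered moving average with window 15
   maps 30 points to 30 − 15 + 1 = 16. The pre-smoothing grid length of
   30 is the single most consequential inferred parameter in the
   pipeline: it is the only value for which the window-15 moving average
   lands exactly on a 16-point trajectory, and it is exposed as
   `grid_len` with default 30. Exponential smoothing is intentionally
   absent: it weights the recent past, which suits forecasting rather
   than the symmetric denoising wanted here.
3. **z-normalization.** Subtract the mean, divide by the *population*
   SD (the convention of the time-series-clustering literature). A
   numerically constant series (SD < 1e−12) becomes all zeros and is
   flagged degenerate rather than producing NaNs.

The chain is affine-equivariant by construction: for any a > 0,
preprocessing a·x + b yields the same trajectory as x (the tests assert
agreement within 1e−9), so unit systems and absolute weight cancel.

## DTW, DBA, and k-means

`dtw_distance()` is the textbook dynamic program: local cost (x−y)²,
steps (1,0)/(0,1)/(1,1), matched endpoints, no warping window (none is
used in the source analysis; a band can be added for speed). The
*squared* DTW cost — the sum of squared differences along the optimal
path — is the quantity the k-means objective minimizes, and inertia is
Σ dtw² by default; because it is not recoverable whether the published
"total sum of distances" squared its distances, both Σ dtw² (`inertia`)
and Σ dtw (`inertia_root`) are reported everywhere. The implementation is
Rcpp, with an exhaustive warping-path enumeration in the test suite as an
independent oracle (exact agreement over all series pairs of length ≤ 4
on a {0, 0.5, 1} alphabet).

Centroids are DTW barycenters (DBA): every member series is aligned to
the current barycenter along its optimal path and each barycenter
coordinate is replaced by the mean of the values aligned to it, iterated
to a 1e−8 coordinate tolerance or 10 refinement passes per k-means
update. DBA is a local refinement — tests check it against a brute-force
candidate grid as a lower bound, not for global optimality.

The Lloyd loop assigns by squared DTW (ties to the lowest cluster index,
for determinism), repairs an empty cluster by reseeding it from the point
farthest from its current centroid, and stops when assignments stabilize.
Seeding is k-means++ adapted to DTW distances, with 5 restarts by
default; the best restart by inertia wins; everything is deterministic
given `seed`. Inertia is recorded each iteration and is non-increasing
(asserted in tests). After fitting, clusters are relabeled by descending
size so "cluster 1" is always the largest, matching how such cohorts are
narrated.

### Choosing k

`elbow_scan()` fits k = 2…10 and suggests the knee of the inertia curve.
The knee statistic is deliberately *not* the largest second difference of
normalized inertia: on five-archetype synthetic data the
stable-or-increase archetype is diametrically opposed to the three
decreasing shapes, so the k = 2 → 3 inertia drop dwarfs everything after
it and the second difference always points at the first big drop, not at
the true structure. Instead the suggestion is a "kneedle"-style rule on
the log of the unsquared inertia curve: the k at the largest vertical
distance below the chord joining the curve's endpoints. The log scale
responds to relative improvements, so structureless data — whose inertia
decays roughly geometrically, i.e. log-linearly — has no knee anywhere
and is flagged low-confidence (maximum chord depth below 0.25, a level
single-cluster data stays well under while five-archetype data sits near
0.46). The full curve is always returned so the choice can be overridden
visually, which is how the original cluster count was chosen.

## Outcomes and statistics

Percent change is 100·(final − initial)/initial, classed into six
intervals: gain > 2%, stable (−2, 2], and losses of (2, 5], (5, 10],
(10, 15], > 15%. The published prose ranges overlap at their endpoints,
so a fixed convention is required: every boundary belongs to the
larger-loss side (−5% exactly is a 5–10% loss; +2% exactly is stable).
A sweep test verifies the six classes partition the line with no gaps.

Adherence rates use the full 16-week program as denominator (a
program-level rate, not a rate over active weeks). Cross-sectional
comparisons route each continuous variable through a Kolmogorov–Smirnov
normality screen — with parameters estimated from the sample, the
variant's small-sample bias accepted because the screen only routes the
choice of test — into one-way ANOVA (normal) or Kruskal–Wallis
(otherwise). The published description assigns both tests to "normally
distributed variables", an evident slip; the implementation uses ANOVA
for normal and Kruskal–Wallis for the rest, with η² always computed from
the ANOVA sum-of-squares decomposition so effect sizes stay comparable.
Categorical outcomes use Pearson chi-square without continuity
correction, with Cramér's V (or signed Φ on 2×2 tables). Weekly
comparisons use pooled-variance t tests — pooled to match the pooled-SD
Cohen's *d* — across configurable cluster pairs, and ANOVA with η²
across the converging cluster triple.

Significance is the dual rule used in large-cohort mHealth work: p < .05
*and* an effect above the small threshold for its type (η² ≈ 0.01,
Cramér's V ≈ 0.01, |d| ≈ 0.20). The V ≈ 0.01 small threshold is
unconventional but retained verbatim as the published analysis's own
guard; all thresholds are configurable. No multiple-testing correction is
applied, again following the source analysis; the effect-size floor is
its substitute.

## The synthetic generator

No generative model of the real trajectories is published, so the
generator's curves are parametric stand-ins calibrated qualitatively to
the published cluster prototypes: sharp = exponential decay to −10% at
week 16; moderate = fast decay to −4% by week 8, then plateau; yo-yo =
the moderate curve to its week-8 nadir, then linear rebound to −1%;
stable/increase = +2% linear; "other" = a sum of two sinusoids that never
converges. Weights are logged at per-archetype weekly Poisson counts with
day-level jitter (so series lengths are heterogeneous, as the pipeline
expects), with Gaussian measurement noise of 0.5 kg by default —
day-to-day scale and hydration variability. Demographics echo the
published cohort marginals (92% female; age ~ N(43.9, 10.9) truncated at
18; height ~ N(166.4, 7.4) cm; BMI ~ N(33.6, 5.9) truncated at 26 so the
simulated cohort stays in the program's target range) purely as
defaults.

Meal-log rates are full 16-week curves, identical across archetypes in
week 1, peaking in weeks 2–4, then decaying at archetype-dependent speed
so that the moderate-vs-yo-yo gap is zero in week 1, largest at week 4,
and shrinking thereafter — the qualitative weekly-divergence structure
the statistics module is designed to detect. Every user logs a weight on
day 0 and at least once in the final week, so final-weight availability
is governed solely by `inject_violations()`, which flags Bernoulli draws
of users for out-of-range heights, missing weight logs, missing
final-week logs, or an inserted +4.5 BMI-unit jump (margin above the 3.5
threshold so measurement noise cannot mask it) and returns a manifest
that the eligibility tests reconcile exactly.

What the generator does *not* emulate: behavioural feedback (adherence
responding to weight change), seasonal or weekday patterns, device
switching, unit-entry errors, or any coaching-content effects. Passing
tests therefore demonstrate that the pipeline recovers structure of this
idealized kind — not that real cohorts contain it.

## Benchmarks and problem sizes

The standing recovery benchmark (`trajectory_benchmark()`) generates 500
users with *equal* archetype shares at 0.1 kg noise, seed 7. Equal shares
are a deliberate departure from the heavily skewed published membership:
at n = 500 the skewed shares would leave the smallest archetype with
fewer than ten members, making recovery a test of luck rather than of
the algorithm. On this benchmark the elbow scan suggests k = 5 and the
k = 5 fit recovers the ground-truth labels with ARI ≥ 0.9 (both asserted
in the acceptance tests; observed values across seeds are ARI 0.92–0.97).

Test and acceptance problem sizes — 500-user benchmarks, 600-user
two-archetype cohorts for the weekly-effect structure, 1,000-rep null
simulations at n = 50 per group, 5,000 per group for Cohen's *d*
recovery — are chosen so the statistical assertions have comfortable
margins while a full run of suite plus acceptance script completes in a
few minutes on one CPU.

## Numerical choices and degenerate inputs

* DBA tolerance 1e−8 (max coordinate change), k-means assignment ties to
  the lowest index, restart count 5 — all deterministic given `seed`.
* A constant weight series z-normalizes to zeros with a `degenerate`
  flag instead of dividing by zero.
* Zero pooled SD (Cohen's *d*) and zero total SS (η²) return `NaN` with
  a warning rather than fabricating a value.
* A weekly comparison cell with fewer than two observations in any group
  is emitted as `NA` and flagged, not fatal.
* Chi-square tables with a zero margin are rejected as domain errors.
* `regularize()` requires at least two distinct observation days; users
  that sparse should have been excluded upstream.

## Limitations

The clustering is hard-assignment k-means: users near phenotype
boundaries get no membership uncertainty. DBA finds local optima;
restarts mitigate but do not eliminate this. The KS screen with
estimated parameters is anti-conservative at small n, which matters
little here because it only routes between two tests whose conclusions
coincide on these data. The published headline cohort means are not
reproducible from a synthetic cohort and are not claimed; the
printed-table quantities (association strength, derived counts, shares)
are recomputed exactly from the shipped fixture instead. Finally, 16
points per trajectory is coarse: sub-weekly dynamics are smoothed away
by design.
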