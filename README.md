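# trajclust

Phenotyping 16-week weight-loss trajectories from mobile
weight-management lifelogs.

Mobile weight-loss programs judge success by a single number — percent
weight change at the end of the program — which cannot distinguish a user
who lost steadily from one who lost, rebounded, and ended at the same
weight. `trajclust` instead clusters the *shape* of each user's weight
course and relates cluster membership to app-use behaviour. It is aimed at
mHealth and obesity researchers who have per-user event streams (weight
logs, meal logs, coach messages, step counts) and want trajectory
phenotypes plus the adherence signals that separate them.

## What it computes

Each user *i* contributes an irregular weight series
*l<sub>i</sub>* ∈ ℝ<sup>T<sub>i</sub></sup>. The pipeline:

1. **Eligibility cascade** — mirror of a study-flow diagram: ≥1 weight
   log; height within [125, 230] cm; adult age; initial BMI ≥ 25 kg/m²
   (initial weight = first log in the window [−14, +7] days around
   enrollment); final weight available in program week 16 (days 105–111,
   falling back to days 112–118); no BMI jump ≥ 3.5 kg/m² within 30 days
   or ≥ 7.0 within 60 days between consecutive logs; ≥ 1 meal log per week.
2. **Standardization** — duplicate days averaged; linear interpolation /
   equal-interval resampling onto a 30-point grid; centered moving average
   with window 15 (30 − 15 + 1 = 16 points); z-normalization to mean 0,
   population SD 1, so only shape matters.
3. **Clustering** — k-means under dynamic time warping (local cost
   (x−y)², steps {(1,0),(0,1),(1,1)}, no window), DBA (DTW barycenter
   averaging) centroids, k-means++ seeding, best of `n_init` restarts;
   the number of clusters is chosen by an elbow scan over k = 2…10 with a
   log-scale knee rule.
4. **Outcomes** — percent weight change classed into
   {gain > 2%, stable, 2–5%, 5–10%, 10–15%, > 15% loss}.
5. **Statistics** — KS-routed ANOVA / Kruskal–Wallis with η², chi-square
   with Cramér's V (or signed Φ for 2×2), pooled-SD Cohen's *d*;
   significance requires both p < .05 and an effect above the small
   threshold for its type. Week-by-week effect-size curves trace when
   adherence between clusters diverges.

A synthetic-lifelog generator (`generate_cohort()`) emulates five latent
trajectory archetypes — sharp decrease, moderate decrease, yo-yo rebound
after a week-8 nadir, stable/increase, and a non-converging remainder —
with cluster-dependent adherence that peaks in weeks 2–4 and then
diverges, plus injectable protocol violations to exercise every exclusion
rule. It makes the whole pipeline testable without any proprietary data.

## Worked example

```r
library(trajclust)

cfg <- synth_config(n_users = 300,
  archetype_weights = setNames(rep(0.2, 5), trajectory_archetypes),
  seed = 2024)
cohort <- generate_cohort(cfg)

elig <- apply_eligibility(cohort)
X <- preprocess_cohort(elig$included)   # 300 x 16 z-normalized matrix
fit <- kmeans_dtw(X, 5, seed = 2024)
print(fit)
#> DTW k-means: k = 5, n = 300, inertia = 67.1290 (converged, 9 iter)
#> cluster sizes: 73, 69, 56, 56, 46
adjusted_rand_index(fit$cluster, elig$included$archetype)
#> [1] 0.7561838
```

Clusters recover the five generating archetypes (ARI 0.76 at a realistic
0.5 kg log-to-log noise; 0.96 at the low-noise benchmark settings).
Comparing app use across the fitted clusters:

```r
usage <- summarize_usage(elig$included)
outcomes <- weight_outcomes(elig$records)
compare_clusters_cross_sectional(usage, outcomes, augment(fit))
#> # A tibble: 6 x 6
#>   variable               test_name  p_value effect_type effect_value significant
#> 1 meal_records_per_week  kruskal_… 8.08e-49 eta_squared       0.774  TRUE
#> 2 weight_records_per_we… anova     3.81e-30 eta_squared       0.385  TRUE
#> 3 messages_sent_per_week anova     2.32e- 4 eta_squared       0.0706 TRUE
#> 4 messages_received_per… anova     2.92e- 6 eta_squared       0.0997 TRUE
#> 5 steps_per_day          anova     2.75e-20 eta_squared       0.282  TRUE
#> 6 weight_change_class    chi_squa… 9.38e-95 cramers_v         0.641  TRUE
```

Meal-record adherence carries the largest effect (η² = 0.77 here, where
the generator imposes distinct per-archetype meal rates), and cluster
membership is strongly associated with the weight-change class.
`weekly_effect_trajectory()` produces the per-week Cohen's *d* curves, and
`autoplot()` methods draw centroids, elbow curves, and effect
trajectories.

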