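---
title: "Segmenting high-cost high-need claims populations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting high-cost high-need claims populations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcnseg)
library(dplyr)
```

## The problem

High-cost high-need (HCHN) patients are usually defined by a threshold —
here, adults in the top 5% of annual spending — and such thresholds lump
clinically very different people together: a woman with a complicated
pregnancy, a patient cycling through the emergency department for
behavioral health crises, and a multimorbid patient with frequent
admissions all clear the same spending bar. Care-management programs built
for the aggregate tend to fit none of them. hcnseg implements a
segmentation pipeline that disaggregates a threshold-defined claims
population into clinically distinct subgroups and quantifies how
trustworthy each subgroup is.

The pipeline has six stages, each exposed as an ordinary function over
data frames:

1. **Cohort selection** — `select_eligible()`: adults at or above a
   spending quantile, tie-inclusive.
2. **Condition grouping** — `group_conditions()`: ICD-9-CM codes to
   condition categories through a prefix crosswalk (longest prefix wins),
   one binary flag per category per patient.
3. **Feature assembly** — `polar_encode()`: demographics plus condition
   flags into a numeric matrix; utilization and spend are *never*
   clustering inputs, so downstream utilization comparisons between
   clusters are unbiased by construction.
4. **Partitioning** — `fit_kmeans()` and `select_k()`: Lloyd's k-means
   with restarts; the number of clusters chosen by a jump criterion on
   the partial F curve over k = 2..20.
5. **Stability** — `run_stability()`: bootstrap refits, kappa-maximizing
   label matching, per-cluster Rand agreement and Jaccard overlap.
6. **Profiling** — `profile_clusters()`, `rank_deviations()`,
   `suggest_label()`: per-cluster descriptive tables, standardized
   deviations from the cohort mean, and rule-based label suggestions.

`run_pipeline()` orchestrates all of it from one configuration with one
master seed.

## Mixed data on the unit circle

k-means needs a Euclidean space, but most claims features are categorical.
Each categorical variable with $L$ ordered levels is mapped to a point on
the unit circle: level $\ell$ (1-based) gets the angle
$\theta = 2\pi(\ell - 1)/L$ and contributes the coordinate pair
$(\cos\theta, \sin\theta)$. All levels are then equidistant from the
origin, every pair lies exactly on the unit circle, and one variable can
contribute at most a squared distance of 4 between two patients — no
single categorical variable can dominate. Binary indicators use the
quarter-circle convention $0 \mapsto (1, 0)$, $1 \mapsto (0, 1)$, so a
disagreement costs a distance of $\sqrt 2$. Continuous age is z-scored so
its variance matches the bounded categorical coordinates.

Two aspects of this encoding are genuine configuration choices rather
than mathematical necessities, and both are exposed in
`encoding_scheme()`: the *level ordering* of each categorical variable
(which determines the angles, and therefore which levels sit adjacent on
the circle) and the *scaling of continuous variables* (z-scoring is the
default because unscaled years would overwhelm unit-circle coordinates).
With more than four levels, adjacent levels are closer than opposite
ones, so the ordering carries weak metric information; for the
eligibility-program and race/ethnicity vocabularies used here the
orderings are fixed package-wide constants, making runs comparable.

## Choosing the number of clusters

For each transition $k \to k+1$ the package computes the partial F
statistic

$$F_k = \frac{(\mathrm{SSE}_k - \mathrm{SSE}_{k+1})/p}
             {\mathrm{SSE}_{k+1}/(n - (k+1)p)},$$

the mean-square improvement from one extra cluster over the residual
mean-square, with $p$ coordinates per centroid. While transitions still
split real structure, $F_k$ stays high; once they only split noise it
collapses. The selected k is the one whose incoming transition shows the
largest *proportional* (log-scale) drop to the next transition — the
elbow of the curve.

Three details of this rule matter and were deliberate design choices:

- **Proportional, not absolute, drops.** The statistic's magnitude
  shrinks mechanically with k, so the largest absolute drop is almost
  always at the first transition, which would bias the rule toward tiny
  k. The log-scale drop is scale-free: on the bundled six-cluster fixture
  the curve falls from about 9.7 to 2.9 at the 5→6 transition, and that
  3.3-fold collapse dominates regardless of where the curve started.
- **Monotone envelope and the F = 1 floor.** Deep in the noise tail the
  partial F values are small and wobbly, and ratios of near-zero values
  explode. The curve is therefore clamped to its non-increasing envelope
  (the statistic is a monotonically decreasing one; local bumps are
  noise) and floored at $F = 1$, the no-improvement baseline of a
  mean-square ratio. Sub-baseline fluctuation can then never fake a jump.
- **The k = 1 anchor.** The transition $1 \to 2$ is computed internally
  so that the first grid point (k = 2) has a preceding transition and can
  itself be selected — otherwise two clean clusters could never be the
  answer.

SSE monotonicity across the grid is guaranteed, not hoped for: each k is
warm-started from the previous best solution augmented with one centroid
at the farthest observation, in addition to the random restarts.

A Sugar–James-style transformed-distortion criterion
(`criterion = "distortion_jump"`) is available as an alternative reading
of the information-theoretic jump idea; both are interpretations, since
an automatic rule is required for software where a published analysis
could read an elbow off a plot.

## The k-means engine

`fit_kmeans()` implements Lloyd's algorithm directly: random-partition
initialization (every observation assigned to a random cluster — the
textbook description), alternating assignment and centroid recomputation,
convergence on stable assignments or a relative SSE change below
`tol = 1e-6`, `max_iter = 300`. The per-iteration SSE trace is kept on
the fitted object and is non-increasing by construction; the test suite
asserts it on every fit. Clusters left empty after a reassignment are
repaired by reseeding the empty centroid at the observation farthest from
its current centroid. Ten restarts (seeded `seed + restart - 1`) are the
default; k-means++ initialization is available by configuration. The
implementation is hand-written rather than delegated because the
per-iteration trace, the described initialization, and the explicit
empty-cluster policy are all part of the contract; `stats::kmeans` with
the Lloyd algorithm serves as an independent cross-check in the tests.

## Cluster stability

Because partitional clustering forces every observation into a cluster,
a cluster is only meaningful if resampled data reproduce it. For each of
`n_replicates = 500` (configurable) bootstrap replicates the cohort is
resampled with replacement, k-means is refit at the same k, and replicate
cluster numbers — which are arbitrary — are matched to the original
numbering by the one-to-one permutation maximizing total Cohen's kappa
between per-cluster membership indicators, found by exact optimal
assignment (Hungarian algorithm) on the k×k kappa matrix rather than
greedily. Degenerate kappa tables (both indicators constant) are defined
as 1 when identical and 0 otherwise, avoiding 0/0.

Two per-cluster indices are then computed over the comparison population
(by default the unique patients in the bootstrap sample, each
contributing one membership comparison; `comparison = "full"` instead
assigns out-of-sample patients to the nearest replicate centroid):

- **Rand-style observed agreement**: the percentage of patients on which
  the two partitions agree about membership in the cluster — in it in
  both, or out of it in both.
- **Jaccard overlap**: joint members as a percentage of patients placed
  in the cluster by either partition — stricter, since agreement "out of
  the cluster in both" no longer counts. Algebraically Jaccard ≤ Rand
  agreement for every cluster and replicate.

These are binary-membership, per-cluster indices; the pair-counting
global Rand index over whole partitions is a different statistic and is
deliberately not what is implemented.

## Profiling and labeling

Per-cluster profiles summarise demographics, condition prevalence, and —
precisely because it was excluded from clustering — utilization: mean and
SD of admissions, hospital days, ED visits, and their preventable
subsets. Preventable utilization is driven by a pluggable code-prefix
flag table per care setting, standing in for licensed
preventable-utilization classifications without reimplementing them.

"What makes this cluster itself?" is answered by the standardized
deviation $(\bar x_{c,f} - \bar x_f)/s_f$ of each feature's cluster mean
from the grand mean, scaled by the *patient-level* cohort SD, making
scores scale-free (age in years and prevalences in percent are
comparable, and the ranking is invariant to affine rescaling of any
continuous feature). Zero-variance features are excluded with a note.
Labels are suggested by an ordered, editable rule table over the top
deviations (e.g. pregnancy-complication prevalence above 90% and
positively deviating suggests "Pregnancy Complications"); the rule table
mechanizes what is in practice an investigator judgment, so rule-derived
labels are suggestions with provenance, and user-supplied labels always
win.

## The synthetic claims generator

No real claims ship with the package; every stage is exercised by
`generate_cohort()`, which plants known structure:

- cluster labels from mixing weights; condition flags independently per
  category given the cluster;
- demographics from per-cluster distributions over the eligibility and
  race/ethnicity vocabularies (including an explicit Missing level);
- utilization counts from per-cluster negative binomial distributions
  when the stated SD implies overdispersion (claims counts usually are
  overdispersed), Poisson otherwise; hospital days built over admissions;
- preventable counts as binomial thinnings of their parent counts, so
  `preventable ≤ parent` holds per record, exactly;
- annual spend as log-normal noise around a linear index of utilization —
  only the rank tail matters for the quantile eligibility rule, so the
  exact spend form is non-critical;
- optionally, a claims table exactly consistent with all of the above
  (one outpatient line per active condition, diagnosis codes drawn from a
  synthetic ICD-9-flavored pool, flagged codes on exactly the preventable
  encounters, paid amounts summing to annual spend to the cent), so that
  emit-then-ingest round-trips are exact.

A `separation` control moves cluster condition prevalences toward (0) or
away from (values above 1) the population mean *on the logit scale*, so
probabilities stay inside (0, 1) at any separation.

`fixture_cohort_spec()` is the bundled six-cluster specification used
throughout the documentation and tests. Its cluster structure — a
relatively healthy group, a 98%-prevalence pregnancy-complications group,
a behavioral-health group, a cardio-metabolic group, and two multimorbid
groups with lower and higher resource use, with per-cluster ages, gender
mix, eligibility programs, and utilization means matching the published
pattern for this population — makes the generator's output resemble the
descriptive tables such an analysis produces. Two parameters are stated
choices rather than inferred values, because the marginal spend
distribution and count overdispersion of the original data are not
public: the spend model coefficients, and the negative-binomial SDs where
a published SD was unavailable. `stability_demo_spec()` is a small
four-cluster design whose first two clusters are nearly deterministic and
disjoint while the last two share one cloud (near-complementary weak
profiles); it exists to demonstrate the stability gradient —
well-separated clusters reproduce under the bootstrap, merged clouds
split arbitrarily and do not.

What the generator does *not* emulate: longitudinal multi-year
trajectories and regression to the mean; correlation between condition
categories beyond what cluster membership induces; coding intensity
varying with utilization; and any proprietary persistence risk score
(synthetic eligibility is the spending-quantile rule only). Passing tests
on this generator therefore show that the machinery recovers planted
structure under realistic marginals — not that six clusters, or these six
clusters, exist in any particular real population.

## Numerical choices and degenerate inputs

- Eligibility ties: all patients tied with the boundary spend are
  included (deterministic, conservative); an all-equal spend vector is an
  error demanding an explicit tie policy rather than a silent guess.
- The age filter (≥ 21) is applied before the spending quantile, so the
  quantile is computed among adults.
- Unmapped diagnosis codes are counted and surfaced (attribute plus
  message, and the pipeline manifest), never fatal.
- `partial_f` returns `Inf` when the (k+1)-solution has zero error; a
  zero-residual grid selects the first k reaching SSE 0.
- Jaccard with both membership sets empty is defined as 100 (vacuous
  agreement) with a warning; inside the bootstrap loop the case is
  handled explicitly as "cluster absent from this sample on both sides".
- Replicate refit failures are skipped and counted in the report and
  manifest, never silently absorbed.
- All randomness flows from explicit seeds: the spec seed for the
  generator, `seed + restart` for k-means restarts, `seed + replicate`
  for bootstrap replicates, and fixed offsets from the pipeline master
  seed — identical configurations are byte-identical end to end.

## Problem sizes used in validation

The published analyses this design follows run at hundreds of thousands
of patients; the package's own validation runs at desk scale, which is
ample for the properties being checked: parameter recovery and k
selection on 20 independent cohorts of n = 3000 at high separation
(median adjusted Rand index ≥ 0.9, k = 6 recovered in 20/20 seeds in the
shipped acceptance run); the stability gradient on n = 800 with 50
bootstrap replicates; index/matching oracles on exhaustively enumerable
universes of up to 8 patients and brute-force permutation search up to
k = 5. The stability default of 500 replicates matches standard practice
and remains the `run_stability()` default; tests and the acceptance
script use fewer replicates only to keep runs short, and all counts are
recorded in outputs.

## Known limitations

- k-means with spherical geometry is the method being implemented, not
  an endorsement; heavily correlated condition flags violate its
  equal-variance heart, which is precisely why the stability module
  exists and why multimorbid clusters come out less stable.
- The polar encoding makes multi-level variables' adjacency ordering
  weakly informative (see above); results with more than four levels are
  ordering-dependent by design and the ordering is configuration.
- The automatic jump rule is one operationalization of "the improvement
  jumped the most"; a different monotone transform of the improvement
  statistic can select a different k on flat curves. The full curve is
  always returned and plotted (`autoplot()`), and a fixed k can be
  supplied to bypass selection.
- ICD-9-CM only, matching the era of the data design; no ICD-10
  crosswalk dialect is provided.
- The bundled crosswalk and preventable-flag tables are synthetic
  stand-ins shaped like the licensed originals (multi-level CCS, PQI,
  ED-visit classification); real analyses must supply the licensed
  tables through `read_crosswalk()` / `read_preventable_flags()`.
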