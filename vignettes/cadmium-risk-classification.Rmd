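---
title: "Cadmium risk assessment and data-driven risk classification for processed grain products"
author: "cdrisk authors"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrisk)
```

## The problem

Cadmium is a Group I human carcinogen that accumulates in the edible parts
of grain; for populations with grain-based diets, rice and wheat consumption
is a principal exposure route. National surveillance programmes assay
processed grain products (rice, wheat flour, "other") city by city, which
raises two analytical questions:

1. How contaminated and how risky is each (city, product) combination, in
   terms that combine worst-case contamination, chronic cancer risk and
   non-carcinogenic hazard?
2. How should those combinations be *graded* into ordinal risk levels
   without an analyst drawing the level boundaries by hand?

`cdrisk` answers the first with three standard indices and the second with
a k-means++ clustering whose number of clusters is chosen by a vote of
three cluster-validity indices.

## Preprocessing of laboratory records

Surveillance exports report each determination as a string. The parser
(`parse_detection_value()`) implements the standard conventions:

* non-detect tokens ("ND", "not detected", "未检出"; configurable,
  case-insensitive) are assigned a concentration of **0 mg/kg** and flagged
  censored. Values are deliberately *not* imputed at LOD/2 — the zero-coding
  convention is part of the index definitions downstream (in particular it
  pins the within-unit minimum at 0, which is what lets a provincial
  maximum be recovered from a published range);
* a leading `"<"` is deleted and the numeric value retained, uncensored;
* anything else must parse as a non-negative numeral, otherwise the row is
  rejected with its row number (strict mode) or skipped with a warning
  (lenient mode).

Descriptive summaries use range (max − min), arithmetic mean, **sample**
(n − 1) standard deviation and the coefficient of variation sd/mean. The
n − 1 convention is a documented choice — published tables of this kind
rarely state their convention, and rounded printed means/SDs cannot
discriminate the two — and is asserted against self-generated data in the
tests. The SD of a single value is defined as 0; a zero mean sets the CV to
an `NA` marker rather than dividing by zero. National "average" rows are
ambiguous between pooling all samples and averaging per-province rows, so
`overall_stats()` reports both, labelled `pooled` and `unit_mean`.

## The three risk indices

For unit–product group with concentrations `X` and limit `S` (defaults
rice 0.2, wheat flour 0.1, other 0.2 mg/kg):

* **Pollution index** `P = X / S`, and the **Nemerow integrated pollution
  index** `NIPI = sqrt((Pmax² + Pavg²)/2)`, which up-weights the worst
  sample; it always lies in `[Pmax/√2, Pmax]`.
* **Estimated daily intake** `EDIq = FC · Xq / W` at a concentration
  quantile `Xq`, with FC the per-province daily consumption of the product
  (kg/d) and W body mass (60 kg default).
* **Target cancer risk** `TCR = EF·ED·CSF·EDI50 / ATC` at the median
  concentration, and **target hazard quotient**
  `THQ = EF·ED·EDI95 / (ATC·RfD)` at the 95th percentile. Defaults
  EF = 365 d/y, ED = 70 y and ATC = EF·ED make the leading factor exactly 1,
  so TCR reduces to `CSF·EDI50` and THQ to `EDI95/RfD`; the full formulas
  are kept so non-default exposure constants work, and all constants are
  configurable.

Quantiles are computed by linear interpolation between order statistics
(`stats::quantile`, type 7 — the common default), over **all** values
including censored zeros.

Two unit conventions deserve a note:

* **RfD.** The reference dose for cadmium is entered as 0.001 mg/(kg·d)
  (i.e. 1 µg/kg/d, the JECFA-derived convention). Source documents
  occasionally print the same number with µg units, which would shift THQ
  by ×1000; the mg/(kg·d) reading is the one consistent with published THQ
  magnitudes of order 0.1–5, and is the package default (`rfd` is
  overridable).
* **CSF.** There is no authoritative oral slope factor for cadmium, and
  `exposure_params()` therefore has **no default** — supplying one silently
  would fabricate cancer-risk numbers. All examples pass `csf` explicitly.

## Clustering and selection of the number of risk levels

The clustering observation is the (unit, product) vector (NIPI, TCR, THQ).
The three indices live on wildly different scales (TCR ~ 10⁻³, THQ ~ 1), so
columns are **z-scored** (n − 1 SD) before clustering; constant columns are
set to 0 and flagged. Centroids are reported in both spaces.

`kmeans_fit()` is a from-scratch implementation:

* **k-means++ seeding** — first centroid uniform, each next centroid drawn
  with probability proportional to the squared minimum distance to those
  already chosen (already-chosen points have probability 0 unless all
  distances are 0);
* **Lloyd iterations** with Euclidean distances, stopping when the maximum
  centroid displacement falls below `tol = 1e-8` or after 300 iterations;
* **10 restarts** by default, the smallest within-cluster SSE winning;
* **empty-cluster repair** by re-seeding the empty centroid with the point
  farthest from its current centroid; if every point coincides with a
  centroid (all-identical data) repair stops, leaving a duplicate centroid
  and SSE 0 rather than failing;
* assignment ties go to the lowest cluster index, making results
  bit-reproducible for a given (data, seed, config).

Each candidate K in `k_range` (default 2–8) is fitted and scored by:

* **silhouette coefficient** (mean of `(b−a)/max(a,b)`; singleton clusters
  contribute 0 — a common convention, chosen because a singleton offers no
  within-cluster distance to estimate `a`); larger is better;
* **Dunn index** — minimum single-linkage inter-cluster distance over the
  maximum cluster diameter; larger is better (the canonical definition; an
  all-singleton partition with zero diameter returns `Inf`);
* **Davies–Bouldin index** — mean over clusters of the worst
  `(s_i + s_j)/d(c_i, c_j)` ratio, in the standard 1979 form; smaller is
  better; coincident centroids with nonzero scatter give `Inf`.

**Voting.** With C candidates, each index ranks them and awards C points to
its best candidate down to 1 for its worst; within-index ties share the
mean of the points they span, so every index distributes exactly
C(C+1)/2 points. Awarding "max-K" points to the best — as vote schemes of
this kind are sometimes stated — over-allocates when the candidate range
starts at 2; anchoring the scale at the number of candidates preserves the
ordinal intent while keeping the totals conserved. Ties in total points
break toward the smaller K (parsimony).

**Risk levels.** Clusters are ordered by the mean of their standardized
centroid coordinates — an equal-weight NIPI+TCR+THQ severity score, the
least-assumptive choice given that no weighting of the three indices is
canonical — and numbered 1…K ascending. Score ties break by the
unstandardized THQ centroid, then by stable cluster id, so the mapping is
deterministic and invariant to cluster relabelling. `tabulate_levels()`
counts combinations per level and, above the high-risk threshold
(level ≥ 4 by default, configurable), the composition by product and by
province. Percentages are **truncated** at the second decimal, the
convention under which published shares such as 16/22 → 72.72 and
5/22 → 22.72 arise. Shares are computed over (city, product) combinations,
the unit in which high-risk tables are published, not over samples.

Risk levels are *relative*: they order the studied combinations against
each other and say nothing about absolute safety.

## The synthetic-data generator

The raw national dataset is access-restricted, so the generator stands in
for it in all tests. It emulates:

* a province → city → product hierarchy (defaults: 20 provinces × 9 cities,
  matching the scale of a national campaign covering ~187 cities in 20
  provinces; 50 samples per city × product cell — surveillance reports do
  not state per-cell counts, so this is a configurable, realistic default);
* a latent risk tier per city; concentrations are log-normal with the
  tier's median and a common geometric SD (default 3, giving the CVs of
  order 1–4 seen in real summaries); default tier medians 0.002–0.18 mg/kg;
* left-censoring *reported, not truncated*: draws below the detection limit
  (default 0.002 mg/kg) keep their row as the non-detect token, and detects
  below a reporting threshold (2×LOD) are written as `"<value"` with
  probability 0.05;
* per-province RNG substreams derived from one global seed, so one
  province's block can be regenerated without the others and output is
  byte-identical under a fixed configuration;
* a consumption table with optional per-province log-normal jitter around
  national base intakes (defaults rice 0.24, wheat flour 0.14, other
  0.05 kg/d — plausible per-capita staple intakes standing in for a total
  diet study table).

What it does **not** emulate: spatial autocorrelation between neighbouring
provinces, temporal structure across sampling years, product-specific tier
differences within a city, inter-laboratory LOD variation, or duplicate /
outlier records. Tests passing on synthetic data therefore demonstrate the
pipeline's statistical and algorithmic correctness, not the real data's
compliance with the log-normal-tier model.

## Verification strategy and problem sizes

* The validity indices are checked to 1e-12 against brute-force
  pairwise-distance oracles on dozens of random fixtures (N ≤ 30), and the
  k-means objective against exhaustive enumeration of all 2-partitions for
  N ≤ 8.
* The k-means++ seeding law is checked empirically against the exact D²
  distribution on the three-point line `{0, 1, 3}` (second-pick
  probabilities 1/10 vs 9/10) over 10⁵ draws.
* Parameter recovery: 5 latent tiers with medians 0.05–0.45 mg/kg (step
  0.1) and geometric SD 1.06 — adjacent medians separated by more than four
  geometric SDs — across 200 cities (40 per tier) with 30 samples per cell,
  10 seeds. The vote is required to select K = 5 in at least 9/10 runs with
  adjusted Rand ≥ 0.95 against the latent tiers, and the recovered level
  order must match the tier order. The recovery harness clusters the rice
  features only: tiers are assigned per city, and the wheat-flour limit
  (0.1 vs 0.2 mg/kg) doubles NIPI at equal concentration, so mixing
  products would deliberately confound the tier structure.
* The worked provincial NIPI examples that are fully determined by
  published inputs (range, mean, limit; minimum pinned at 0 by non-detect
  zero-coding) are reproduced to 5e-5, and the published 22-row high-risk
  table tabulates to its printed composition shares.

These sizes keep the full suite comfortably fast on a single CPU while
leaving each check statistically meaningful.

## Known limitations

* Non-detects contribute 0 rather than a left-censored likelihood; indices
  in heavily censored cells are biased low by construction (this is the
  surveillance convention, not an oversight).
* Euclidean k-means assumes roughly spherical clusters in z-space; strongly
  log-spaced index distributions may be better served by a log transform
  before `feature_matrix()`, which the API permits but does not default to.
* The vote compares only the three indices above; alternative selection
  criteria (gap statistic, hierarchical methods) are out of scope.
* Risk levels are ordinal and relative; cross-dataset comparability of
  levels is not guaranteed because the z-scoring is per-dataset.
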