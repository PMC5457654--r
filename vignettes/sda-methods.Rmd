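---
title: "Signal detection analysis of injury severity: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection analysis of injury severity: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pedsda)
```

## The problem and the model

An EMS injury registry records, for each transported pedestrian, who they
are (age, sex), when they were hit (4-hour time bin, season), where
(road-width class, national-road and densely-inhabited-district flags,
residence-area aging rate and proportion of low-income households), how far
from home (network distance along the road graph), and whether the injury
was severe (hospital admission) or minor (discharged after evaluation).
The scientific question is which *combinations* of these ten variables
delimit subgroups with distinctly different severe-injury percentages.

Signal detection analysis answers it by recursive binary partitioning.
Every candidate split of a subgroup is reduced to a 2×2 table against the
outcome, with cells `a, b, c, d` (split-positive severe/minor,
split-negative severe/minor), total `n`, prevalence `P = (a+c)/n`, and
split level `Q = (a+b)/n`, and scored by the weighted kappa family

$$\kappa(r) \;=\; \frac{(ad-bc)/n^2}{\,r\,P(1-Q) + (1-r)(1-P)\,Q\,},
\qquad r \in [0,1].$$

Algebraically, $\kappa(0.5)$ is Cohen's kappa, $\kappa(1) = (SE-Q)/(1-Q)$
the quality index of sensitivity, and $\kappa(0) = (SP-(1-Q))/Q$ the
quality index of specificity; the weight `r` prices false positives
against false negatives. The sign of $\kappa(r)$ is the sign of $ad-bc$,
and a degenerate margin returns 0 by convention. These identities are
property-tested against independent closed forms.

At each node `best_split()` evaluates every candidate of every variable,
keeps the maximum-κ candidate that survives three gates, and `grow_sda()`
recurses into both children with **all** variables still available (a
variable may be re-used deeper in either branch). The three gates are the
stopping rules:

1. **size** — both prospective children must have at least `min_subgroup`
   subjects (default 10). Applying the rule to *prospective* children means
   a finished tree can never violate it post hoc.
2. **significance** — Pearson chi-square on the 2×2 table, 1 df, no
   continuity correction, must reach `p < alpha` (default 0.05).
3. **CI sign** — the lower limit of the `ci_level` (default 95%) confidence
   interval of κ must be above zero.

The model's assumptions are minimal but real: the outcome is binary and
recorded without error; records are independent; rules are axis-parallel
single-variable thresholds or category memberships (no oblique or multiway
splits); and missing values are handled by making a variable ineligible at
any node where it has missing entries (no surrogate splits).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r` | 0.5 | kappa weight; 0.5 = Cohen's kappa, symmetric costs |
| `alpha` | 0.05 | chi-square gate per selected split |
| `ci_level` | 0.95 | coverage of the kappa interval (rule 3) |
| `min_subgroup` | 10 subjects | smallest admissible subgroup |
| `max_depth` | unlimited | optional depth cap |
| `n_boot`, `boot_seed` | 1000, fixed | bootstrap settings when `r != 0.5` |

`r = 0.5` is the default because the severity outcome carries no stated
asymmetry in misclassification costs and Cohen's kappa admits an exact
large-sample variance. At `r = 0.5` the confidence interval is the
symmetric normal interval with the Fleiss–Cohen–Everitt asymptotic
standard error; for any other `r` no comparably standard variance exists,
so a seeded nonparametric bootstrap (multinomial resampling of the `n`
subjects over the four cells, percentile interval, at least 1000
resamples) is used instead. Intervals are clipped to $[-1, 1]$. The fixed
bootstrap seed keeps `grow_sda()` deterministic and invariant to record
order.

## Numerical and procedural choices

**Candidate grids.** Continuous variables contribute the midpoints between
consecutive sorted distinct values — the exhaustive, data-adaptive grid
that makes a brute-force oracle exact. Ordinal variables (the four
road-width classes) contribute their class boundaries, binary variables
their single split, and nominal variables (season, time bin) one
one-vs-rest candidate per level.

**Orientation.** A threshold partition can be labelled with either side
positive, and κ flips sign with the labelling. A risk factor whose
*upper* range is dangerous (e.g. "network distance above 133 m") would have
negative κ in the `<=` orientation and could never pass the CI gate, so
both orientations are evaluated and the severe-enriched side becomes the
positive branch. For binary variables this means the single partition is
oriented; for nominal variables the one-vs-rest candidates are taken as
given (complement sets are not added).

**Tie-breaks.** Exact κ ties are resolved by smaller p-value, then by the
position of the variable in the `variables` argument, then by smaller cut
value — making the fit deterministic and row-order invariant (tested by
shuffling).

**Degenerate inputs.** Zero-margin tables score κ = 0 and chi-square 0
with p = 1; an outcome with a single level present yields no split; a
constant variable yields no candidates; unknown variables raise domain
errors.

**Multiplicity.** No correction is applied across the thousands of
candidate cuts examined per node: the significance gate is the printed
per-split `p < 0.05`. This is a deliberate fidelity choice with a known
cost, quantified below.

**Rounding.** All printed percentages round half *up* to one decimal
(`round_half_up()`), matching the convention of published epidemiological
tables; pooled percentages are reconstructed from implied integer counts
(`round(n·prop/100)`), which is also how `reconcile_subgroups()` audits
published subgroup tables against stratum totals.

## Distances

Euclidean distance is the planar formula on projected coordinates.
Network distance is the minimum total edge length between the residence
and injury nodes (Dijkstra via igraph; negative or zero edge lengths are
rejected at network construction, as are edges shorter than the chord
between their endpoints — a road is at least as long as a straight line).
Points are snapped to the *nearest node*, with lexicographic tie-breaks,
rather than to an interior edge point; this approximates GIS
network-analyst behaviour and keeps the exhaustive shortest-path oracle
simple. Synthetic networks can be densified where snapping resolution
matters. Disconnected origin–destination pairs return an `Inf` marker —
never an exception — and the pipeline counts and excludes them. Edge
weights are geometric lengths only; travel time and one-way restrictions
are out of scope.

## What the generator emulates — and what it does not

`sim_config()` describes a mid-sized suburban EMS catchment with two adult
strata (defaults 229 older, 316 working-age). Covariates are drawn
independently per stratum: aging rate N(19.64, 5.17) / N(17.80, 4.93) and
low-SES proportion N(40.80, 6.50) / N(41.51, 7.53), truncated to [0, 100];
sex, road-width class, national-road, district, time-bin and season
frequencies from the published one-decimal percentages (used instead of
the published raw counts, which are internally inconsistent in the
working-age column). The road network is a jittered 30×30 grid with 100 m
spacing — large enough that the median target distance is reachable from
every residence, fine enough that short trips (one block, ~100 m) exist.
Residence nodes are uniform; the injury node is the one whose network
distance best matches a lognormal draw moment-matched to mean (SD)
1128 (1837) m / 1939 (2487) m — lognormal because the SDs exceed the
means, ruling out symmetric models. Severity is Bernoulli with the
probability of the planted tree's leaf: for the older stratum
0.563 / 0.455 / 0.270 / 0.176 across the SES–road-width–aging-rate leaves,
for the working-age stratum 0.197 / 0.082 / 0 across the
distance–aging-rate leaves.

Real registries differ in ways the generator deliberately omits:
covariates are correlated (SES and aging rate cluster spatially), the
street network is not a lattice, distances have a large point mass of
very short trips, and severity depends on unmeasured factors (vehicle
speed, health status). Passing tests on synthetic data therefore
demonstrate that the *algorithm* recovers structure it was promised, not
that the substantive findings generalise.

## What the simulations show, and honestly do not

Three behaviours are measured by the test suite and `scripts/acceptance.R`
(problem sizes: 50 replicates at n = 2000 per stratum for recovery and
null experiments; 20 default-size registries for the stopping-rule audit;
1000 random tables for the kappa equivalences).

**Structural correctness.** Every grown tree, on every audited registry,
satisfies all three stopping rules exactly: no leaf below 10, every
internal split with p < 0.05 and a positive κ-CI lower bound, and leaves
partitioning the stratum. Shortest paths agree with exhaustive simple-path
enumeration; κ(0.5) agrees with Cohen's kappa to machine precision.

**Cut-point recovery.** On single-split data (n = 400, rates 0.55 / 0.20)
the planted variable is found in every replicate, and the induced
partition agrees with the generating one for at least 95% of records in
over 90% of replicates. The cut *value*, however, wanders by a few
observations around the generating boundary — standard change-point
behaviour: the estimator's error lives on the count scale, so no value-
scale gap in the generated data can pin the cut into a fixed interval at
this sample size. Recovery is therefore scored by partition agreement,
not by cut membership in an interval.

**Selection optimism (null model).** With a constant severe probability
and no planted effect, the grown trees are *not* single leaves: with
roughly 2000 candidate cuts per continuous variable and a per-split
p < 0.05 gate, the maximally selected chi-square essentially always
exceeds its nominal critical value, and the null single-leaf rate is 0%
in 50 replicates. This is the documented price of the no-correction
design choice: subgroups from a single SDA fit are hypothesis-generating,
and their p-values are optimistic. Users who need family-wise control
should tighten `alpha` or validate subgroups on held-out data.

**Planted-root identifiability.** The older stratum's planted root
(low-SES proportion at 35.21%) is recovered in 100% of replicates. The
working-age planted root (network distance at 132.84 m) is *not*
recoverable under this generator: the moment-matched lognormal places only
about 1.5% of records below 132.84 m, so the distance split's attainable
κ (~0.005) is an order of magnitude below the aging-rate split's (~0.14),
and maximum-κ selection correctly prefers the latter. The planted tree is
faithful to the published rules, and the distance distribution is faithful
to the published moments — but the two are jointly incompatible: the source
data evidently carried a much larger short-trip mass (about 10% below
133 m) than any two-moment lognormal fit allows. This is reported as a
measured 0% working-age root recovery rather than papered over, and it is
a useful caution: subgroup rules sitting in a thin tail of an exposure
distribution are not identifiable by agreement-maximising partitioning.

## Known limitations

- Binary severity only; no survival, ordinal or continuous outcomes.
- Two-way splits without pruning or cost-complexity cross-validation.
- No surrogate splits; variables with missing values simply become
  ineligible at affected nodes.
- Node snapping (not edge snapping) for distances; plain length weights.
- Percentages and pooled proportions reproduce one-decimal printed-table
  arithmetic, which can differ from full-precision arithmetic by up to
  0.05 points.
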