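---
title: "Stage-structured social networks from co-detection data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-structured social networks from co-detection data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foraynet)
```

## The problem

In cooperatively breeding birds such as the Florida scrub-jay, adults fall
into distinct life-history stages — breeders (territory owners that have
bred), dominants (territory owners that have not yet bred), and helpers
(non-territorial non-breeders) — and the stages are expected to behave
differently: helpers make repeated off-territory forays in search of breeding
openings, dominants foray when unpaired, and breeders stay home. `foraynet`
implements the full analysis chain that turns playback-survey co-detection
records into stage-level inference: group-by-individual (GBI) matrices →
simple-ratio-index association networks → per-individual network position
metrics → spatially filtered linear models → permutation-referenced stage
contrasts. A stage-structured survey simulator with known ground truth makes
every step testable without field data.

## Data model

The raw record is a binary GBI matrix: one row per observed aggregation, one
column per individual. Each aggregation carries metadata — its sampling point
(survey records) or none (opportunistic records of aggregations containing
birds from non-adjacent territories), a date, and its kind. Individuals carry
sex, stage, territory, an optional egg-laying flag, and a survival flag;
territories carry two covariates, the distance from the territory boundary to
the nearest sampling point (m) and the number of immediately adjacent
territories.

Individuals detected fewer than 3 times are removed before network
construction (`filter_min_detections()`). Aggregations emptied by that
removal are dropped: they carry no dyadic information, and because the SRI
denominator counts only aggregations containing at least one dyad member,
dropping them provably leaves every SRI value unchanged (asserted as a test).

## Association index and node metrics

For a dyad (A, B) with joint count $x$ and union count $D$ (aggregations
containing either), the simple ratio index is $\mathrm{SRI} = x/D$, which
corrects association strength for unequal detection. The per-dyad denominator
$D$ doubles as the dyad's sample size: `robustness_summary()` reports the
percentage of dyads with $D$ below a threshold (default 20, the conventional
minimum) plus the mean and standard error of $D$ over all $\binom{n}{2}$
dyads. By default the summary covers the full filtered network, with an
argument to restrict to the analysed subset, since either convention is
defensible.

Four per-individual responses are computed:

* **binary degree** — the number of nonzero-SRI partners. Binary rather than
  weighted degree is used because opportunistic records are restricted to
  non-neighbour aggregations, which biases *weights* (not the existence) of
  within-group edges downward.
* **betweenness** — shortest-path betweenness with edge lengths $1/\mathrm{SRI}$,
  fractional credit among tied geodesics (Brandes accounting), and by default
  normalised by $(n-1)(n-2)/2$. Normalisation is a deliberate choice: it makes
  values comparable across years with different network sizes, and on
  ~170-node networks it is the only scale consistent with reported
  stage differences in the third decimal place. A flag disables it.
* **local clustering** — the fraction of a node's neighbour pairs (binary
  adjacency, SRI > 0) that are themselves connected. Degree ≤ 1 leaves the
  quantity undefined; it is stored as missing and propagates as complete-case
  deletion into the models, which is why the clustering model loses residual
  degrees of freedom relative to the other metrics. Treating it as 0 instead
  would conflate "no opportunity to cluster" with "no clustering".
* **unique points** — the number of distinct survey points at which the
  individual was detected. Opportunistic aggregations have no point and are
  excluded by default (a flag counts each as its own pseudo-point).

Edges exist wherever SRI > 0; no minimum-weight pruning is applied.

## Spatial inclusion

Territories with no sampling point within 100 m of their boundary ("within"
read boundary-inclusively, ≤ 100) or with ≤ 1 adjacent territory are excluded
from the statistical analyses, as are individuals that did not survive the
sampling period. Exclusion reasons are tallied under the declared precedence
survival → distance → adjacency so the tallies partition the excluded set;
the precedence is a package convention, not an inference from the original
tallies. Geometry is deliberately simple planar arithmetic (point–segment
distances, boundary-contact counts with a tolerance; corner-only contact
counts as adjacent by default, matching polygon-neighbour tools) — covariates
may equally be supplied directly as a CSV, making the geometry utilities
optional. A point inside a territory returns its distance to the nearest
edge, because the criterion concerns proximity of sampling coverage to the
boundary.

## Models and stage contrasts

Each metric is modelled by ordinary least squares on distance to nearest
point, number of adjacent territories, stage, sex, and stage×sex, with
sequential (type-I) sums of squares in that fixed order — the default
behaviour of `anova()` on an `lm` fit, and the convention the reported SS
tables follow. The per-term effect size is
$\eta^2 = SS_{\mathrm{term}} / SS_{\mathrm{residual}}$ — note the
*residual* (not total) SS in the denominator; `eta_squared()` and
`f_statistic()` expose the pure arithmetic so printed SS tables can be
checked for internal consistency.

Pairwise stage differences use the Tukey HSD construction on raw group means
(the behaviour of `TukeyHSD()` applied to one term of a multi-term fit):
difference of means, with family-wise 95% half-width
$q_{0.95,k,\nu}\sqrt{\tfrac{MSE}{2}(\tfrac1{n_a}+\tfrac1{n_b})}$, where $MSE$
and $\nu$ come from the full model. The female-vs-male helper contrast is
computed inside the stage×sex cell-mean family ($k$ = number of non-empty
cells, typically 6), which is what the same command does for an interaction
term; the original family choice is not stated, so this convention is ours.
A covariate-adjusted alternative is deliberately not the default.

Variance homogeneity across stages uses the Brown–Forsythe statistic: the
one-way ANOVA F on absolute deviations from group medians.

## Data-stream permutation reference

Observed differences and Brown–Forsythe statistics are referenced against
location-restricted data-stream permutations: checkerboard swaps of the GBI
matrix restricted to aggregations at the same sampling point, which conserve
every individual's total and per-point detection counts. Opportunistic
aggregations have no point and are frozen (singleton classes). The proposal
picks a class, two aggregations in it, then one individual from each side of
their symmetric difference — a guaranteed checkerboard via a symmetric
kernel, so the stationary distribution is the same uniform distribution over
margin-preserving matrices that naive rejection sampling targets, at a much
higher acceptance rate.

The chain is serial: by default one accepted swap between successive
recorded samples (the convention of the standard implementation of this
test), 1000 samples, with one-tailed p-values computed with the add-one
convention $p = (1 + \#\{\text{as-or-more extreme}\})/(1 + B)$ in the
direction given by the a-priori prediction table (`default_predictions()`).
Thinning (`swaps_per_sample`) and burn-in are configurable and deviate from
that convention when used.

Two properties of this null deserve emphasis, both demonstrated in the test
suite:

* **It is not centred at zero.** Each individual's detection effort — and
  with the location restriction, *where* it was detected — is conserved, so
  group differences driven by detection asymmetries survive permutation. The
  null mean tracks the observed difference closely; a large raw difference
  can carry a large permutation p. The test asks whether associations are
  more structured than chance *given* who was detected where and how often.
* **Unique points is exactly invariant** under location-restricted swaps
  (per-point column sums never change), so its permutation null is
  degenerate. Its comparisons therefore carry parametric Tukey p-values
  only, and the null columns are absent — which also explains why a
  location-controlled permutation analysis cannot report randomized values
  for that metric.

The "±95% confidence level" attached to the null mean is $1.96\,s/\sqrt{B}$,
a CI for the mean of the (highly autocorrelated) null sequence — the only
scale consistent with half-widths orders of magnitude tighter than the null
spread.

## The synthetic study design

`synthetic_config()` fixes the simulated field design; defaults were chosen
once, from the study system's description, and are not tuned:

| parameter | default | rationale |
|---|---|---|
| grid | 8×8 territories of 300 m (9 ha) | population of ~60–75 territories averaging 9 ha |
| occupancy | breeder pair, or lone dominant w.p. 0.15 | dominants are a small minority of territory holders |
| helpers | truncated Poisson(0.7), max 7, on breeder territories | 0–7 helpers, population mean under 1 |
| foray probability / round | breeder 0; dominant 0.25; helper F 0.5, M 0.4 | breeders do not foray; helpers foray most; dominants intermediate |
| foray kernel | truncated geometric, q = 0.5, ≤ 3 steps | forays and dispersal are short-range (1–2 territories) |
| detection | radius 200 m, certain response | playback answered only by nearby birds; no detection function reported |
| effort | 2 rounds/week × 12 weeks | twice-weekly sampling, February–April |
| points | boundary intersections jittered ≤ 50 m, ≥ 200 m apart | points stratified on boundary intersections, ≥ 200 m spacing |
| opportunistic | groups of co-located forayers from non-adjacent territories, recorded w.p. 0.5 | opportunistic records restricted to non-adjacent-territory aggregations |

Each round every individual is at home or forays to a kernel-drawn
territory; its location is uniform within the occupied territory; every
point-visit's responders within the detection radius form one survey
aggregation. The 50 m point jitter keeps every territory within 100 m of a
point (so the default layout passes the spatial filter in full) while giving
the distance covariate genuine variation — with points exactly on
intersections the covariate is constant and the model rank-deficient.

At these defaults a simulated year yields ~150–190 networked individuals and
~1100–1300 aggregations, matching the scale of a real field season. What the
generator does *not* emulate: within-season boundary drift, nest-cycle time
dynamics, dominance interactions, mortality (survival flags are settable,
not simulated), aggregation hotspots, and any real detection function.
Passing tests therefore show the pipeline's correctness and the design's
internal consistency, not that field data would meet the same effect sizes.

### What the tests establish

* **Ordering recovery.** With the planted foray ordering (breeder <
  dominant < helper), mean degree and mean unique points recover the
  ordering breeders < dominants < helpers in ≥ 90% of 20 replicate seeds
  (observed: 20/20).
* **Null calibration.** With all stages given identical foray rates, the
  one-tailed permutation p for the breeder-vs-helper degree difference is
  approximately uniform over 200 replicate seeds (Kolmogorov–Smirnov test at
  α = 0.01). The calibration experiment uses 100 recorded samples thinned by
  25 swaps: with single-swap thinning the chain barely moves between
  samples and the rank of the chain's own starting state is not a
  meaningful p-value. This thinning choice is part of the calibration
  design, documented here because it deviates from the single-swap default.

## Numerical choices and degenerate inputs

* SRI with a zero denominator (possible only before filtering) is defined
  as 0.
* Betweenness on networks with fewer than 3 nodes is all-zero; clustering
  for degree ≤ 1 is missing, never 0.
* Swap proposals are bounded (10^5 attempts) and stall with an error rather
  than looping forever on unswappable matrices.
* Brown–Forsythe with a zero-spread group is legal (its deviations are 0);
  an all-groups-constant response yields F = 0/0 and is surfaced as such
  rather than masked.
* Chains, simulations and pipelines are bit-reproducible given a seed; the
  seed is recorded in every null distribution and results bundle.
* Problem sizes in the shipped experiments (5×5 grids for calibration, 20
  seeds for recovery, 100–1000 permutations) were chosen so the full suite
  runs in minutes on one core; all are arguments, not constants.

## Known limitations

* The permutation and parametric analyses share complete-case handling but
  the permuted statistic is the raw mean difference, not a refitted model
  contrast; covariate-adjusted permutation contrasts are out of scope.
* No half-weight or twice-weight association indices; no eigenvector
  centrality or community structure; no mixed models across years; no
  multiple-testing correction beyond Tukey's family-wise intervals.
* The geometry utilities assume projected planar coordinates in metres and
  simple (non-self-intersecting) territory rings; there is no GIS-format
  ingestion.
* Year-to-year comparisons are by re-running the pipeline per year; the
  package does not model years jointly.
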