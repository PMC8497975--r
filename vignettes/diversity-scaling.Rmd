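---
title: "Diversity-area scaling of multi-site microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-area scaling of multi-site microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darscale)
```

## The model

The species-area relationship (SAR) of classical biogeography, `S = cA^z`,
links species richness to sampled area. For host-associated microbiomes the
"area" `A` is naturally the number of accumulated microbiome samples — either
one sample per individual at a fixed body site (the *inter-individual*
design) or one sample per body site along the digestive tract (the
*intra-tract* design). The diversity-area relationship (DAR) generalizes the
SAR by replacing richness with the Hill number of order `q`,

\[
{}^qD = \Big(\sum_{i=1}^{S} p_i^q\Big)^{1/(1-q)}, \qquad
{}^1D = \exp\Big(-\sum_i p_i \ln p_i\Big),
\]

so one scaling analysis covers richness (`q = 0`), the exponential of Shannon
entropy (`q = 1`), the inverse Simpson concentration (`q = 2`) and any other
order. Two accrual models are fitted to each diversity-accrual curve:

* **PL** (power law): `D = c A^z`, fitted as `ln D = ln c + z ln A`;
* **PLEC** (power law with exponential cutoff): `D = c A^z e^{dA}`, fitted
  as `ln D = ln c + z ln A + dA`.

Both are estimated by ordinary least squares on the log-linear forms, never
by nonlinear optimization, so the estimates are closed-form and exactly
reproducible. Four derived parameters make up the profiles reported per
diversity order:

* the scaling parameter `z` (rate of diversity increase with accumulated
  samples);
* the pairwise diversity overlap `g = 2 - 2^z`, with `g = 0` at `z = 1` (no
  overlap) and `g = 1` at `z = 0` (total overlap);
* the maximal accrual diversity (MAD) `D_max = c(-z/d)^z e^{-z}`, the PLEC
  curve's maximum, attained at `A_max = -z/d` and defined only when `d < 0`
  and `z > 0`;
* `RIP = 100\,c/D_{max}`, the percent ratio of individual-level diversity
  (the PL `c`, the expected diversity of the first accumulated sample) to
  population-level potential diversity.

## Resampling designs

Because the PL intercept `c` depends on which sample is accumulated first,
both designs randomize the accumulation order and average over resamples:

* **Inter-individual** (`interIndividualProfiles()`): for one body site, each
  resample draws a uniformly random permutation of the site's samples (one
  per subject), builds the accrual curve at every `q`, and fits both models.
  The study design uses 100 resamples; the argument is configurable.
* **Intra-tract** (`intraIndividualProfiles()`): each replicate draws one
  sample per site and accumulates the sites in a fixed anatomical order
  running from the oral cavity towards the intestinal tract (default
  `dtSiteOrder()`; the principle fixes the direction, not an exact sequence,
  so the order is an argument). The study design uses 1000 replicates.

**Success accounting.** A resample counts as successful when the PL
regression is estimable (at least 3 points and non-constant `ln D`) with
regression-F `p < 0.05`, and the PLEC fit simultaneously passes its F-test
with `d < 0` and `z > 0`, so that `D_max` and RIP exist. All reported means
and standard errors are over this common successful set, which keeps every
column of a `DARProfileSet` recomputable from its per-resample log
(`resampleLog()`); `N_success` counts the set's size. An accrual curve with
zero variance in `ln D` — identical communities, for instance phylum-level
curves when every site holds the same phyla — is flagged failed with `z = 0`
and undefined `R`/`p`, and is counted, not dropped. Note that `g` and RIP
are averaged per resample (`mean(2 - 2^{z_r})`), not evaluated at the mean
parameters; by Jensen's inequality the two differ whenever `z` varies.

## Randomization tests

`randomizationTest()` compares a DAR parameter (`z` or `D_max`) between two
sample groups at one diversity order. The group statistic is the mean fitted
parameter over `innerReps` random accumulation orders (successful fits
only). The null distribution pools both groups and re-splits the samples at
random into pseudo-groups of the original sizes, recomputing the statistic
pair per permutation; the test is two-sided through the absolute difference,
and the p-value uses the add-one correction
`p = (1 + \#\{null \ge obs\})/(n_{valid} + 1)`, which cannot be zero.
Permutations whose statistic is degenerate (no successful fit in a
pseudo-group) are dropped; when they exceed half of the permutations the
test is reported *inconclusive* rather than as a 0/1 call. The two groups
are internally put in a canonical order before any random draw, so swapping
the arguments changes nothing, including the RNG stream.

`pairwiseMatrix()` applies the test to all unordered site pairs (45 for ten
sites) and assembles the coded significance matrix: one 0/1 digit per
diversity order, the `q = 0` digit separated by a comma (`"0,000"`),
inconclusive tests coded `x`, plus per-site percentages of significant
comparisons. No multiplicity correction is applied across pairs, matching
how such matrices are conventionally reported; a user wanting FDR control
can apply `p.adjust` to the stored p-value array.

The exact permutation scheme behind published DAR site comparisons is not
recoverable from the descriptions available; the pool-and-resplit scheme
implemented here is the standard two-sample permutation test applied to a
resampling-averaged statistic, and is documented as this package's design
choice. `innerReps` (default 10) trades Monte-Carlo noise in the statistic
for cost; the same value is used for observed and null statistics, which
keeps the test exchangeable and its size nominal.

## The synthetic cohort generator

Real multi-site 16S cohorts of the kind this analysis targets (on the order
of 2000 samples: ten digestive-tract sites in ~240 adults, binned at phylum
to genus) cannot ship with a package, so `generateCohort()` produces seeded
cohorts with the statistical structure the analysis assumes:

* a nested 5-level taxonomy (`generateTaxonomy()`), default
  14/28/55/110/400 phylum-to-genus;
* per-site genus pools of `poolSize` (default 300) sharing a `poolOverlap`
  core across sites, so site differentiation is tunable;
* core-satellite occupancy: each pool taxon is present in an individual with
  probability `pi ~ Beta(a, b)`;
* abundance-occupancy coupling: the per-taxon mean log-abundance is a
  monotone (Beta-CDF) transform of its occupancy with an exactly
  `N(0, lognormalSigma^2)` marginal, so common taxa are also abundant —
  the feature that makes higher-order diversity saturate quickly and the
  fitted `z` fall steeply from `q = 0` to `q >= 1`, as observed in real
  digestive-tract data;
* within-sample lognormal noise (unit log-SD) and multinomial read counts at
  `readDepth` (default 10^4).

The generator stores the realized occupancies and site pools in
`metadata()$generator`, so closed-form expectations can be checked against
its output: the expected pooled richness over `n` individuals is
`E[S(n)] = \sum_t [1 - (1 - \pi_t)^n]`, with Beta-averaged form
`P\,[1 - B(a, b+n)/B(a, b)]`. `calibrateOccupancy()` inverts that closed
form — bisection on `b` (the slope is monotone in `b`: rarer taxa accrue
longer) over a small grid of `a` — to hit a target log-log slope without any
simulation. This makes end-to-end parameter recovery testable: a cohort
calibrated to slope 0.30 and analysed with `interIndividualProfiles()`
returns `mean_z(q = 0)` within ±0.05 of the target.

What the generator does *not* emulate: real taxon identities, compositional
covariance between taxa, sequencing error, or longitudinal revisits. Passing
tests therefore demonstrate that the estimators recover the structure the
model assumes, not that any particular biological dataset follows that
model.

## Numerical choices and degenerate inputs

* Natural logarithms throughout; `q = 1` uses the exact Shannon limit, never
  a numerical limit.
* Abundances are normalized inside `hillNumber()` over positive entries, so
  counts and relative abundances are interchangeable and zeros never enter
  the sums; all-zero communities and negative entries are errors.
* No rarefaction or coverage correction is applied before diversity
  computation; curves are built from raw pooled relative abundances.
* A curve is degenerate when `max(ln D) - min(ln D) < 10^{-12}`; the PLEC
  design matrix must additionally have full rank (QR rank 3).
* The fit core uses closed-form/QR least squares rather than `lm()` because
  the permutation machinery calls it millions of times; the test suite
  verifies it against `lm()` and hand-written normal equations to `1e-10`.
* Default diversity orders are `q = 0..3`, the range over which the profiles
  are conventionally reported; any non-negative grid can be supplied.
* Subjects with multiple samples at one site contribute their first sample
  by id sort (`dedupeSubjects = TRUE`), so each area unit is one individual.

## Problem sizes used by the shipped tests

The test suite runs the designs at desk scale, chosen so each check
exercises the full pipeline while the whole suite stays interactive:
parameter recovery uses 60 subjects at one site with 30 resamples; the
type-I-error study uses 500 tests of 8-vs-8 samples with 200 permutations
and 3 inner resamples; the power study uses 20 tests of 30-vs-30 samples
with 3-fold different pool sizes (the `D_max` contrast this detects reliably
needs curves long enough to pin down the cutoff `d`, which is why these
groups are larger). The study-scale defaults (100 and 1000 resamples, 1000
permutations) remain the function defaults.

## Known limitations

* `D_max = c(-z/d)^z e^{-z}` is an extrapolation; when the fitted `d` is
  close to zero, `A_max = -z/d` and hence `D_max` become unstable. Short
  accrual curves (around ten points) produce heavy-tailed `D_max` estimates,
  which depresses the power of the `D_max` permutation test at small group
  sizes; this is a property of the statistic, not of the implementation.
* The PL intercept `c` overestimates the first-sample diversity whenever the
  accrual curve saturates within the fitted range (the log-log curve is
  concave and the fitted line lies above it at `A = 1`), so RIP values
  carry that bias; they remain comparable across groups fitted the same way.
* The intra-tract design treats sites as exchangeable within a site only
  through uniform sampling; repeat visits and within-subject correlation
  across sites are not modelled.
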