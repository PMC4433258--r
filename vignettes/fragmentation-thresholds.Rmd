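---
title: "Methods: habitat amount, fragmentation per se, and extinction thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat amount, fragmentation per se, and extinction thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragthresh)
```

## The question and the two landscape variables

Habitat loss and habitat fragmentation are different processes: one removes
habitat, the other breaks what remains into pieces. Theory predicts that
fragmentation *per se* should move a species' extinction threshold — the
habitat amount below which it cannot persist — toward higher habitat
amounts. Testing that on gridded occurrence data requires separating the
two axes per analysis unit. `fragthresh` does this with two percentages per
grid cell:

* **PFC**, the share of the cell's valid (non-nodata) pixels classified as
  forest — the habitat-amount axis;
* **rLPS**, the share of the cell's *forest* contained in its single
  largest connected patch — the fragmentation axis. For a fixed PFC, high
  rLPS means the forest sits in one block (weak fragmentation); low rLPS
  forces the remaining forest into many, necessarily small, patches.

rLPS is a ratio to forest area, not to cell area, so it is undefined where
PFC = 0 and may legitimately be smaller than PFC. `compute_rlps()` returns
`NA` for forest-free cells and never coerces it to 0 or 100; what to do
with such cells is a modelling decision, made explicitly downstream
(`species_dataset(zero_forest_policy=)`, default `"drop"` with a recorded
count — imputing an rLPS for a cell without forest would fabricate
fragmentation information).

Patch connectivity defaults to 8-neighbour (queen) adjacency, the common
choice for coarse categorical land-cover products, and is exposed as a
flag. Patches are clipped at cell boundaries: the metrics are per-cell
state descriptors, so a patch spanning two cells counts in each
separately; landscape-wide patch tracking would entangle neighbouring
analysis units.

## The occurrence model and its screen

Occurrence over a species' native-range cells is modelled as

$$p = \mathrm{logit}^{-1}(\beta_0 + \beta_1\,\mathrm{PFC} + \beta_2\,\mathrm{rLPS}),$$

fitted by IRLS (`stats::glm`, deviance tolerance $10^{-8}$, 100 iterations
max) with predictors untransformed, in percent units — so $\beta_1$ is the
change in log-odds per percentage point of cover. Quasi-separation is
flagged (`converged = FALSE` plus a warning), never silently accepted.

Species enter the threshold analysis only if the model is trustworthy:

* likelihood-ratio $\chi^2$ (df = 2) p-value < 0.05,
* rank-based (Mann–Whitney, ties = ½) AUC $\ge$ 0.7,
* McFadden's $\rho^2 = 1 - \ell_{full}/\ell_{null} \ge$ 0.2,
* prevalence strictly between 0.15 and 0.70 (both boundaries excluded), so
  that neither rarity nor ubiquity degrades the fit statistics.

The comparison operators are deliberately inclusive ($\ge$) for AUC and
$\rho^2$: the reference screening of the 16-species example table
(`understory_fit_stats()`) retains species sitting exactly at 0.20, which
fixes the operator choice. With exactly two predictors the VIF has the
closed form $1/(1-r^2)$; the package computes it that way rather than
through an auxiliary regression.

## Sensitivity scalars and the percentile bootstrap

Two log-ratio scalars summarize a fitted model at fixed endpoint scenarios
(`scenario_constants()`):

$$\Omega_{cover} = \ln\frac{p(5, 100)}{p(75, 100)}, \qquad
  \Omega_{fragm} = \ln\frac{p(20, 10)}{p(20, 100)},$$

contraction from high (75%) to low (5%) cover without fragmentation, and
fragmentation from none to the empirical maximum (rLPS 100 → 10) at a
constant, moderately low 20% cover. `percent_change()` maps a scalar to the
implied proportional change, $100(e^\Omega - 1)$; the worked conversions
−3 → −95%, −1 → −63%, −0.5 → −39% round at integer precision, while
$\Omega = +1$ is exactly +171.8%.

Confidence intervals are percentile-bootstrap only (no delta method): 1,000
resamples of whole (PFC, rLPS, occurrence) triads with replacement at the
cell level, each of the original sample size, model refit per resample, and
the 95% interval read at ranks $\lfloor 0.025B \rfloor$ and
$B - \lfloor 0.025B \rfloor + 1$ — positions 25 and 976 at $B = 1000$. No
stratification by outcome is applied by default (resampling is plain triad
resampling); replicates whose outcome collapses to a single class or whose
refit fails to converge are redrawn from the running RNG stream (up to 50
extra draws per slot) and then raise a hard error with diagnostics — a
silent drop would bias the interval, and the redraw policy keeps the
procedure total on prevalences near the screening bounds.

Group means (herbs vs ferns) pair replicate $b$ across species: group
replicate $b$ is the mean of every member species' $b$-th bootstrap scalar,
and the same rank rule applies. Pairing, rather than re-drawing species
sets, keeps the group statistic a deterministic function of the per-species
replicate caches; re-drawing would add a between-species resampling layer
the cell-level design does not define.

All bootstrap draws run on a locally seeded RNG and restore the caller's
RNG state, so results are bit-reproducible given `seed` without side
effects on the session.

## The maximum-fragmentation envelope

The joint PFC–rLPS cloud of real gridded landscapes is funnel-shaped:
near-unfragmented cells occur at every cover, while the *minimum* rLPS
attainable falls as cover contracts. The strongest-fragmentation scenario
is estimated from the lower edge of that cloud:

1. `select_lower_edge_cells()` — the pfc axis is split into 25 equal-width
   bins over the observed range; each bin contributes its
   $\lceil 100/25 \rceil$ lowest-rlps cells (ties by cell id); the set is
   trimmed to exactly 100 by dropping its highest-rlps members, or topped
   up with the globally lowest-rlps remainder when sparse bins under-fill.
   Binning forces the edge set to span the cover gradient instead of
   pooling at low cover where low rLPS is cheap. Exact duplicates of
   (pfc, rlps) collapse to one candidate, so replicated tables select the
   same edge. Where the true edge layer is thin within a bin the quota is
   filled by the best cells available there; only in the single-bin
   configuration does the rule reduce to "the 100 lowest rlps overall".
2. `fit_envelope()` — ordinary least-squares polynomial of rLPS on PFC,
   degree 4 (the lowest degree that tracks the sharp upturn of the edge at
   high cover without oscillating across it), requiring at least 5 distinct
   pfc values.
3. `max_fragmentation_rlps()` — the polynomial evaluated at the requested
   covers, clamped to [1, 100]: a forest-bearing cell cannot have rLPS 0,
   and 1% is a conservative floor; values are kept at full precision and
   rounded only for display.

The nine published evaluation covers (85 … 5%) with their envelope rLPS
values (90, 60, 40, 26, 20, 16, 14, 10, 5) ship frozen as
`published_scenario_grid()`, so the published scenario pairs can be used
directly without the original land-cover data; `scenario_grids()` builds
the same structure from any freshly fitted envelope. The zero-fragmentation
scenario sets rLPS = 100 at every cover.

## Extinction thresholds and the hypothesis test

A logistic model never reaches occurrence probability 0, so the threshold
is read at the 0.5 criterion — the cover at which presence and absence are
equally likely. `curve_with_ci()` evaluates the fitted model along a
scenario grid with a bootstrap band (same replicate cache as the
sensitivity analysis, so both analyses are coherent and the refits are paid
for once). `detect_threshold()` scans from the highest cover toward loss
and returns the first level whose 95% CI overlaps the criterion.

"Overlaps" defaults to `ci_low <= 0.5` (the band *reaches down to* the
criterion). The alternative containment rule
(`ci_low <= 0.5 <= ci_high`) is exposed but not default, because a steep
curve can jump from safely above 0.5 at one grid level to entirely below it
at the next; the reach rule still fires at that first level, the
containment rule never does. A curve lying entirely below the criterion
thresholds at the highest examined cover (the true threshold is at or above
the range); a curve whose band never reaches 0.5 has no threshold in the
range (`NA`), and for scenario comparison `NA` is ordered below every
examined cover.

`compare_scenarios()` classifies a species as `supports_hypothesis` when
its maximum-fragmentation threshold sits at strictly higher cover than its
zero-fragmentation threshold *and* the two scenario bands are disjoint at
one or more covers (the per-level disjointness is the package's
operationalization of "statistically different under the bootstrap");
the mirrored ordering gives `opposite_response`, anything else
`null_response`.

## What the synthetic data emulate — and what they do not

`generate_cell_table()` is the default fixture: cover is drawn from a
right-skewed Beta(1.1, 2.8) scaled to (0, 100] (mean ≈ 28%, matching a
forest-minority landscape), and rLPS uniformly between a lower envelope
$e(\mathrm{pfc})$ and 100. The envelope is the left half of a logistic,
anchored at a floor of 5% as cover vanishes and reaching 100 at full
cover, with one rate parameter (default 0.05 per % cover) — the simplest
two-parameter family with the observed funnel shape. The default table
size is 5,279 cells, the size of the motivating national 10-km grid.
Pixel counts are synthesized per cell (10,000 valid pixels, i.e. 100 m
pixels in a 10 km cell) so every row satisfies the metric invariants,
including rLPS $\ge 100/n_{forest}$.

`generate_raster()` exercises the raster path specifically: Gaussian noise,
optionally smoothed with a separable Gaussian kernel (the aggregation
scale, in pixels), thresholded at the rank matching the target cover.
Aggregation raises per-cell rLPS at fixed cover, which is the one property
the tests rely on. `generate_occurrences()` draws independent Bernoulli
occurrences from chosen coefficients; `simulate_community()` wires a
nine-species community (five herbs, four ferns) whose rLPS coefficients
span negative, zero and positive responses, with per-species sub-seeds
derived as `seed + 7919 * i`.

These generators validate the machinery, not the ecology: occurrences are
spatially independent given the two predictors (no autocorrelation, no
dispersal limitation, no detection error), the funnel is stationary across
the gradient, and coefficients are constant over space. A green test suite
therefore demonstrates that the estimators recover known truth under the
model's own assumptions — not that the model is adequate for any real
landscape.

## Simulation scales and numerical conventions

The test suite's calibration checks run at the scales used throughout the
package's own validation: parameter/Ω recovery, hypothesis-direction and
null-calibration properties at $n = 2000$ cells with $B = 200$ bootstrap
replicates over 50 seeded trials each, and oracle equivalence of the patch
labelling against an independent recursive flood fill on 200 random
rasters up to 64 × 64. Direction-property species use deliberately strong
fragmentation coefficients ($\beta_2 = \pm 0.04$ with cover slopes placing
the thresholds mid-grid): the property under test is the sign logic of the
classifier, and weak effects would measure bootstrap power instead. The
full pipeline at the default 5,279 cells and $B = 1000$ runs in a few
minutes on one core; bootstrap cost is linear in $B$ and in $n$.

Other conventions: the likelihood-ratio statistic is floored at 0 before
the $\chi^2$ tail probability (guarding the rare negative rounding
residue); percentile bands occasionally fail to bracket the point estimate
(a known property of percentile CIs) and produce a warning, not an error;
`percentile_ci()` refuses $B < 40$, where the lower rank would be 0; ties
in edge-cell selection break by cell id so every stage is deterministic;
and Esri ASCII grids are the supported text raster format, with nodata
pixels excluded from both numerator and denominator of PFC.

## Known limitations

* Thresholds are read on the nine-level scenario grid; no interpolation
  between levels is attempted, so thresholds are quantized to the grid.
* The per-level CI-disjointness rule is conservative relative to a joint
  test across levels and ignores the correlation between the two scenario
  curves (they share replicates).
* The envelope's 100-cell edge rule is one defensible operationalization
  of "the lower edge of the cloud"; quantile regression or hull-based
  estimators are deliberate non-goals here.
* No spatial autocorrelation correction is applied to the occurrence
  models; with strongly clustered records the bootstrap intervals will be
  optimistic.
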