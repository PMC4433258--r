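# fragthresh

Does habitat fragmentation *per se* — the breaking apart of habitat,
independent of how much habitat there is — push species toward extinction at
higher habitat amounts? `fragthresh` implements a grid-based workflow for
asking that question with presence/absence data on a regular cell
tessellation (the motivating case: forest understory herbs and ferns on a
10 × 10 km national grid, with forest mapped from a 100-m land-cover
raster). It is aimed at landscape ecologists and biogeographers who have a
categorical land-cover raster and per-cell occurrence records, and want the
full chain from landscape metrics to fragmentation extinction thresholds in
reproducible, tested R.

## The model

Each grid cell carries two forest descriptors:

* **PFC** — percentage forest cover, the habitat-amount variable;
* **rLPS** — relative largest patch size, the percentage of the cell's
  forest contained in its largest connected patch (queen adjacency by
  default). rLPS near 100 means all forest in one block; low rLPS means
  shattered forest. rLPS is undefined (not 0, not 100) in forest-free cells.

Occurrence of species *j* is modelled by logistic regression over its
native-range cells:

```
p = exp(b0 + b1*PFC + b2*rLPS) / (1 + exp(b0 + b1*PFC + b2*rLPS))
```

Models are screened for robustness (likelihood-ratio chi-squared p < 0.05,
AUC >= 0.7, McFadden's rho-squared >= 0.2, prevalence strictly between 15%
and 70%). Two scalar sensitivities summarize the fitted response, each a
natural-log ratio of predicted probabilities:

```
Omega_cover = ln[ p(PFC=5,  rLPS=100) / p(PFC=75, rLPS=100) ]   # forest loss, no fragmentation
Omega_fragm = ln[ p(PFC=20, rLPS=10)  / p(PFC=20, rLPS=100) ]   # fragmentation at fixed cover
```

`100*(exp(Omega)-1)` is the implied percent change in occurrence
(Omega = −3 is a 95% reduction, −1 a 63% reduction, −0.5 a 39% reduction).
95% confidence intervals come from a percentile bootstrap: 1,000 resamples
of (PFC, rLPS, occurrence) triads with replacement, model refit per
resample, CI read at ranks 25 and 976 of the sorted replicate values.

An empirical **maximum-fragmentation envelope** — a fourth-order polynomial
fitted to 100 cells on the lower edge of the PFC–rLPS cloud — defines, for
nine forest covers (85 … 5%), the strongest fragmentation observed at that
cover. The **extinction threshold** under a scenario is the first cover, in
the direction of forest loss, at which the occurrence probability's 95% CI
reaches 0.5 (presence and absence equally likely). A species *supports the
fragmentation threshold hypothesis* when its threshold under maximum
fragmentation sits at higher cover than under zero fragmentation (rLPS =
100), with the two scenario curves statistically separated at one or more
covers.

A synthetic-data module generates all inputs with known truth: neutral
binary forest rasters (smoothed-noise thresholding), funnel-shaped
PFC–rLPS cell tables, and Bernoulli occurrences from chosen coefficients.

## Worked example

```r
library(fragthresh)

sim  <- simulate_community(n_cells = 1500, seed = 5)   # synthetic study system
d    <- sim$species[["herb_negfrag"]]                  # true beta2 = +0.025
fit  <- fit_logistic(d)
gof_report(fit, d)
#> GOF: chi2 = 535.44 (p = 5.38e-117), rho2 = 0.262, AUC = 0.825, VIF = 1.031 -> PASS

reps <- bootstrap_fits(d, n_boot = 200, seed = 11)     # shared replicates
bootstrap_omega(d, "fragm", reps = reps)
#> Omega_fragm[herb_negfrag] = -1.751  (95% CI -2.075 .. -1.361) *  [B = 200]

grid <- published_scenario_grid()                      # (85,90), (75,60), ... (5,5)
compare_scenarios(
  curve_with_ci(d, grid, "max_frag",  reps = reps),
  curve_with_ci(d, grid, "zero_frag", reps = reps))
#> Extinction thresholds for herb_negfrag:
#>   max fragmentation: 45%  |  zero fragmentation: 15%
#>   divergent levels: 8  ->  supports_hypothesis
```

The fragmentation sensitivity is negative and significant (fragmenting the
forest at constant 20% cover cuts this species' occurrence by
`100*(1-exp(-1.75))` ≈ 83%), and its extinction threshold moves from 15% to
45% forest cover when fragmentation is maximal — the pattern the
fragmentation threshold hypothesis predicts, built into this virtual
species' positive rLPS coefficient.

Landscape metrics from a raster instead of a ready-made table:

```r
g   <- read_ascii_grid("forest.asc", forest_codes = c(23, 24, 25))
tab <- metrics_table(g, cell_size = 10000, connectivity = 8)
```

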