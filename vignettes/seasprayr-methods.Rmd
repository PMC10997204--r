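---
title: "Methods: PFAA enrichment in sea spray and global secondary fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PFAA enrichment in sea spray and global secondary fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `seasprayr`, the
parameters that matter, the design choices made where the method was
genuinely open, and the limits of what the synthetic-data tests can show.

## 1. Enrichment factors from chamber experiments

A sea-spray simulation chamber generates nascent SSA from continuously
renewed seawater; a 14-stage cascade impactor separates the aerosol into
size fractions (stages 1–6 and 7–8 pooled, giving 8 fractions over
0.015–15 µm aerodynamic diameter), and both compartments are analysed for
PFAAs and the sea-salt tracer Na⁺. The enrichment factor of homolog $i$ in
fraction $f$ is

$$\mathrm{EF}_{i,f} \;=\;
\frac{[\mathrm{PFAA}]_{\mathrm{SSA}}/[\mathrm{Na^+}]_{\mathrm{SSA}}}
     {[\mathrm{PFAA}]_{\mathrm{sw}}/[\mathrm{Na^+}]_{\mathrm{sw}}},$$

a dimensionless ratio invariant under any common rescaling of the
aerosol-side quantities (the sampled air volume cancels).

**Censoring.** Chamber-water values below the method detection limit are
substituted by the MDL and flagged; SSA values below their per-fraction
MDL are excluded from all regressions and per-experiment EFs (substituting
them would fabricate aerosol mass; excluding them only thins the sample).
A homolog enters EF estimation only if its water detection frequency
exceeds 30 % — strictly, so exactly 30 % fails. An experiment counts as a
detection if at least one of its triplicate water cartridges is
uncensored, and the experiment's water concentration is the mean of the
triplicate after substitution (the aggregation is not prescribed anywhere;
the mean of three nearly identical cartridges is the natural choice).

**Slope vs geometric mean.** Across experiments, the sodium-normalised
water ratio $x_e$ and SSA ratio $y_e$ satisfy $y_e = \mathrm{EF}\,x_e$
with no intercept. When the Pearson correlation between $x$ and $y$ is
significant (two-sided t-test on $r$ with $n-2$ df, $p < 0.05$ strictly),
the mean EF is the through-origin total least squares slope, the $s$
minimising

$$\sum_e \frac{(y_e - s\,x_e)^2}{1+s^2},$$

available in closed form as the appropriate root of
$s^2 S_{xy} + s\,(S_{xx}-S_{yy}) - S_{xy} = 0$. Otherwise the geometric
mean of the per-experiment EFs is used. The correlation is computed on the
raw ratios by default (`cor_on = "log"` switches to log scale; the choice
is exposed because either is defensible and the difference only matters
near the significance boundary).

**Uncertainty.** The slope CI is a seeded nonparametric percentile
bootstrap over experiments (2000 resamples by default) — the method
producing the published intervals is not specified beyond "95 % CI", and
resampling whole experiments respects the experiment as the sampling
unit. The geometric-mean CI is a t-interval on the natural-log scale,
back-transformed.

**A known property of the steep through-origin TLS.** With EFs of
$10^3$–$10^6$, the fitted line is nearly vertical in the $(x, y)$ plane,
and the orthogonal objective degenerates towards an inverse regression,
$\hat s \approx S_{yy}/S_{xy}$. Under multiplicative log-normal noise with
log-sd $\sigma$ this estimator has expectation
$\mathrm{EF}\,e^{1.5\sigma^2}$ — a +28 % bias at GSD 1.5 — whereas the
geometric-mean path is effectively unbiased with log-scale standard error
$\sigma/\sqrt{n}$. The package reproduces the published estimator rather
than repairing it; the consequence, quantified by the recovery simulation
in the acceptance script, is that slope-selected EFs recover the truth
within a factor 1.3 in roughly two-thirds of GSD-1.5 replicates, with
percentile-bootstrap coverage near 80 % rather than the nominal 95 %. At
the smaller residual scatter typical of supermicrometre fractions
($r > 0.9$, $\sigma \lesssim 0.2$) the bias shrinks to a few percent,
which is why slope and geometric-mean estimates agree well on
low-noise data. Users comparing the two methods on noisy submicrometre
fractions should expect the slope to run high.

**Size dependence.** Per homolog, `ef_vs_diameter_regression()` fits
ordinary least squares of $\log_{10} \mathrm{EF}$ on $\log_{10} d_p$
across supermicrometre fractions ($d_p > 1$ µm). The representative
diameter $d_p$ of a fraction is the geometric mean of its bounding
cutoffs, with the impactor inlet (15 µm) bounding the top fraction.

## 2. The SSA source function

The source function consists of three log-normal modes with number-median
diameters 0.095, 0.6 and 1.5 µm. Only the medians are inherited from the
parameterisation itself; the GSDs (2.10, 1.72, 1.60) follow the published
chamber-derived source function, and both are configuration parameters.
For mass integrals each mode is used as a log-normal *mass* distribution
with the same GSD and mass-median diameter
$d_m = d_n e^{3\ln^2\!\sigma_g}$ (Hatch–Choate), giving mass medians of
roughly 0.50, 1.45 and 2.91 µm. The default mode mass weights
(0.003, 0.045, 0.952) place ≈ 2.5 % of emitted salt mass below 1 µm,
matching the submicron sea-salt share this source function produces in
Earth-system-model output; they were fixed once, before any flux was
computed, and are likewise configurable.

A mode's per-fraction weights are closed-form log-normal CDF differences
over the fraction bounds (the outermost bounds extend to 0 and ∞), so no
quadrature error enters; the tests check them against numerical
integration. Mode-level EFs are the mass-weighted average of the fraction
EFs, with weights renormalised over the fractions that carry an EF; a
missing fraction holding more than 1 % of the mode's mass is an error
rather than a silent renormalisation. Scenario EFs take the per-fraction
CI bounds (low/high) rather than a CI of the aggregated mode EF — the
aggregation order is not prescribed; taking bounds first is conservative
(wider) and keeps the three scenarios exact transforms of the EF table.
Impactor aerodynamic diameters are treated as source-function dry
diameters (the sampling line dried the aerosol below 40 % RH); no shape
factor is applied.

## 3. The gridded world

The grid is a regular latitude–longitude raster (the Earth-system
resolution is 1.9° × 2.5°; the toy world uses 6° × 9°), with exact
spherical cell areas $R^2\,\Delta\lambda\,(\sin\varphi_t-\sin\varphi_b)$.
Province polygons, land polygons and coastline polylines are simple
vertex tables; all geometry predicates (point-in-polygon by the even-odd
rule, segment–rectangle intersection) are exact planar tests, adequate at
these scales because no shape crosses the dateline — grid adjacency and
dilation, in contrast, do wrap in longitude.

Assignment and fallback rules, in pipeline order, with the tie-breaks the
sources leave open resolved deterministically:

* **Rasterisation** — each ocean cell takes the province containing its
  centre; centres on boundaries are resolved by largest sampled overlap
  (an 8 × 8 point subgrid), then lexicographic id; ocean cells covered by
  no polygon take the nearest assigned province by breadth-first search
  and are reported.
* **Cell medians** — multiple measurements in one cell collapse to their
  median; censored field values are first replaced by the reporting
  study's MDL.
* **Merging** — provinces with data in fewer than 3 cells (but at least
  one) merge into the adjacent province (sharing a cell edge) with the
  most occupied cells, smallest-count-first so the fixed point is
  order-independent; a sparse province with no data-bearing neighbour is
  treated as data-free downstream, discarding its one or two cells rather
  than letting them masquerade as a distribution.
* **Quartiles** — mean/low/high scenario concentrations are the median,
  Q1 and Q3 of the occupied-cell values, with linear interpolation
  between order statistics (quantile type 7, R's default; no convention
  is prescribed).
* **Fallback** — data-free provinces copy the scenario triple of their
  best-populated adjacent *noncoastal* province; failing that, the
  Atlantic province whose latitude band overlaps theirs the most (ties
  lexicographic; a province with no overlapping Atlantic band takes the
  nearest band edge). Provenance (`measured`, `merged`,
  `neighbor_fallback`, `latitude_fallback`) is recorded throughout.
* **Cell classification** — cells intersecting land polygons are land;
  cells intersecting the coastline are coast (including ocean-side
  cells); inland = land ∖ coast.
* **Coastal extension** — for deposition, land cells within 2
  queen-dilation steps of a coastal-province cell take that province's
  concentrations (nearest source wins; equidistant ties go to the
  lexicographically smaller id); remaining land cells take the nearest
  noncoastal province. "Horizontally toward inland by two grid cells" is
  implemented as 8-neighbour dilation with n = 2 since the neighbourhood
  is not defined more precisely.

## 4. Fluxes, totals and scenarios

Monthly salt fields (kg m⁻² s⁻¹) are annualised with day weights on a
365-day calendar (no leap days, matching Earth-system-model calendars; the
seconds-per-year constant is configurable) and averaged over years. The
PFAA flux per cell, homolog and mode is

$$F_{\mathrm{PFAA}} = \mathrm{EF}_m \times (0.307\,F_{\mathrm{salt}})
  \times \frac{C}{10.8\ \mathrm{g\,L^{-1}}},$$

with no further constants: kg × pg/g = ng, so salt in kg m⁻² yr⁻¹ and
concentrations in pg L⁻¹ give ng m⁻² yr⁻¹ exactly. If only a total salt
field is supplied it is split across modes by the mode mass weights.
Global totals integrate over cell areas and convert ng → t with the fixed
factor 10⁻¹⁵. Deposition uses the same formula with wet/dry salt
deposition fields and the coastal-extension concentration raster;
concentrations are applied at the *deposition* location, so the origin of
deposited salt is untracked — this is why deposition totals can slightly
exceed emission totals, and the closed-world conservation test holds
exactly only under spatially uniform concentrations and EFs. PFOS is
carried as separate linear and branched homologs through EF estimation
and summed at the species level in the flux fields.

Scenarios co-vary jointly: low pairs CI-low EFs with Q1 concentrations,
high pairs CI-high with Q3. No cross-combinations and no Monte-Carlo
propagation are attempted — the three discrete scenarios are the
uncertainty statement.

## 5. What the synthetic data emulate — and what they do not

`gen_chamber_experiments()` draws per-experiment water concentrations
log-uniformly (default 50–2000 pg L⁻¹, spanning the contrast between
cleaner and more impacted waters), builds SSA concentrations as
EF × water ratio × SSA-Na⁺ × log-normal noise (default GSD 1.5), and
censors at configurable MDLs; the true EFs follow a power law
EF = a·d_p^b (defaults a = 3×10⁴, b = 1.2, matching the observed strong
log–log size dependence). `gen_grid_world()` builds a 30 × 40 world with
two continents and an island, twelve provinces (four coastal strips, open
bands, two basins), a mid-latitude-peaked salt emission profile scaled to
3×10¹² kg yr⁻¹, and deposition fields that close the global salt budget
exactly with a 60 % wet share. Several provinces are left without
measurements and one is kept at two data cells, so merging, neighbour
fallback and latitude fallback are all exercised by the default world.
Both generators are fully determined by their seed and emit truth records.

What passing tests on these fixtures demonstrate: correctness of the
estimators, rules and unit algebra, determinism, and conservation. What
they do not demonstrate: realism of absolute flux magnitudes (the toy
provinces and concentrations are order-of-magnitude placeholders, not
ocean data), real Longhurst geometry or bathymetry, surf-zone SSA
production, or atmospheric transport — deposition fields are consumed,
never modelled.

## 6. Problem sizes and numerical choices

The default test and acceptance workloads are sized to run in minutes on
one core: 19 experiments × 4 homologs × 8 fractions for the chamber
fixtures, 2000 bootstrap resamples per slope CI, 200 replicates for the
recovery study, 100 instances for the orthogonal-regression oracle, and a
30 × 40 grid for the world. All randomness flows from explicit integer
seeds; per-combination bootstrap seeds are derived arithmetically from the
master seed so that adding or removing a homolog does not shift another's
resamples. Ties anywhere (overlaps, equidistant cells, equal data counts)
resolve lexicographically, which is what makes two runs of the full
pipeline bit-identical.

## 7. Known limitations

* The raw-scale through-origin TLS slope is biased upward under strong
  multiplicative noise (Section 1); the package faithfully reproduces it.
* Percentile bootstrap CIs on 19 experiments undercover when the
  estimator is biased; the geometric-mean t-intervals do not share this
  problem.
* Geometry is planar and shapes must not cross ±180°; adequate for
  province-scale rectangles and the toy world, not for arbitrary global
  shapefiles.
* Gridded data are exchanged as plain long tables (`cell`, `value`), not
  NetCDF; adapters are the caller's responsibility.
* Deposition re-uses the concentration at the deposition location;
  source attribution of deposited PFAAs is out of scope by construction.
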