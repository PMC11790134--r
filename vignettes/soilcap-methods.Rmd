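---
title: "Methods behind soilcap: capacity indices, source apportionment and pollution-area mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind soilcap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcap)
```

## The problem

Stratified soil surveys of heavy metal(loid)s — here Pb, Cr, Mn, Cu, Zn,
Co, Ni and As measured in mg/kg at sites spread over residential,
commercial, educational, floodplain and agricultural land — are routinely
assessed with a battery of indices, apportioned to sources with receptor
models, and mapped with geostatistical interpolation. soilcap implements
that whole chain as composable functions around a `SoilSurvey` object (a
`SummarizedExperiment` with metals in rows, sites in columns, and site
coordinates and land use in `colData`).

## Pollution indices

For a measured concentration $C_i$, background $C_b$, screening value
$C_s$, standard limit $S_j$ and toxic-response factor $T_r$:

* contamination factor $CF = C_i / C_b$;
* ecological risk $ER = T_r \times CF$ (Hakanson);
* single-metal Nemerow index $NPI = C_i / S_j$;
* environmental pollution capacity: the existing capacity per hectare is
  $Q_i = 10^{-6} M (C_s - C_i)$, the total capacity
  $Q_{ib} = 10^{-6} M (C_s - C_b)$, and the capacity index
  $$\Pi = \frac{Q_i}{Q_{ib}} = \frac{C_s - C_i}{C_s - C_b},$$
  so $\Pi = 1$ on background soil, $\Pi = 0$ when the screening value is
  reached, and $\Pi < 0$ beyond it. $\Pi$ is independent of the soil mass
  per hectare $M$ (default $2.25 \times 10^6$ kg/ha), which only scales
  the capacity terms.

Integrated capacity per site first range-normalises each metal's $\Pi$
over the survey to $[0, 1]$ (a metal constant across all sites maps to
0.5 by convention) and then combines with the low-end-emphasising Nemerow
form $\sqrt{(\bar v^2 + \min(v)^2)/2}$. The low-end form is deliberate:
for a *residual capacity*, the worst condition is the smallest value, so
the minimum plays the role the maximum plays in the classical
contamination-oriented Nemerow index. A plain mean is available via
`soilcapConfig(integration = "mean")`.

Risk classes use lower-closed bins on $\Pi$: safe $\ge 0.7$,
precautionary $[0.4, 0.7)$, loaded $[0, 0.4)$, overloaded $< 0$. The only
threshold with external support is 0.7; the rest are configurable
defaults (`soilcapConfig(pi_bins = ...)`). A value exactly on a break
takes the better class. Under the default contamination rule $\Pi < 1$, a
site is flagged exactly when its concentration exceeds the background —
an algebraic equivalence the tests assert.

### Reference constants and their provenance

Backgrounds (FAO values: Pb 50, Cr 100, Mn 2000, Cu 100, Zn 300, Co 50,
Ni 100, As 20 mg/kg) and detection limits (Pb 0.25, Zn 0.21, Cr 0.16,
Mn 0.15, Ni 0.54, Co 0.12, Cu 0.05 mg/kg; As 0.3 µg/kg, converted to
0.0003 mg/kg at load time) are survey/instrument constants. Screening
values, standard limits and toxic-response factors are
jurisdiction-dependent and are the replication-sensitive unknowns of any
reanalysis: soilcap ships literature defaults — the agricultural-soil
screening standard where it exists and exceeds the background (As 30,
Pb 120, Cr 200 mg/kg), twice the background otherwise so the invariant
$C_s > C_b$ always holds (Mn 4000, Cu 200, Zn 600, Co 100, Ni 200), the
standard Hakanson $T_r$ set (Pb 5, Cr 2, Cu 5, Zn 1, Co 5, Ni 5, As 10,
Mn 1), and $S_j = C_s$. Every value is overridable through
`metalReferences(overrides = ...)` or a reference CSV, and results that
depend on them should be read as conditional on the chosen table.

## Land-use statistics

Descriptives use the unbiased (n−1) standard deviation and
$CV\% = 100\,s/\bar x$. Normality is tested with the Lilliefors-corrected
Kolmogorov–Smirnov test (`nortest::lillie.test`), since the reference
moments are estimated from the sample; the Box–Cox $\lambda$ is estimated
by profile maximum likelihood (`MASS::boxcox`, grid $[-3, 3]$ at 0.01)
and the transformation is applied only when normality is rejected at
0.05. One-way ANOVA uses the classical F test; a Brown–Forsythe Levene
pre-test (`car::leveneTest`) decides the post-hoc family — Tukey HSD
under homogeneous variances, Games–Howell (Welch t referred to the
studentized range) otherwise. Whether ANOVA runs on raw or Box–Cox
values is a flag (`transform`), raw being the default. Pairwise Pearson
correlations carry two-tailed t-test p-values; zero-variance metals are
reported as missing rather than propagating NaN.

## Geostatistics

The empirical semivariogram bins pairs up to half the maximum pair
distance (12 bins) and a parametric exponential (default) or spherical
model is fitted by weighted least squares with Cressie weights
$N_h/\gamma_{model}(h)^2$, from a small grid of starting values. For the
exponential model the `range` parameter is the e-folding distance of the
correlation, matching the synthetic field generator. A constant field
yields a degenerate zero-sill model; near-collinear geometry warns but
proceeds. Range estimation from a single realisation is inherently noisy
— on simulated 200-site fields roughly one realisation in six misses the
true range by more than 50% under any weighting we examined — so the
recovery tests judge the median over several independent fields.

Ordinary kriging solves the usual BLUP system with a unit-sum weight
constraint, using the covariance $C(h) = (\text{nugget} + \text{psill}) -
\gamma(h)$; duplicate site locations are averaged with a warning, and a
pure-nugget model collapses predictions to the global mean. IDW uses
weights $\propto d^{-2}$ by default and returns a site's exact value when
a cell centre coincides with it.

The ensemble predictor propagates variogram-estimation error in the
spirit of empirical Bayesian kriging: fit a model to the data, simulate
`K` new value sets at the data locations from it, refit a model to each,
weight each member by the Gaussian likelihood of the *observed* data
under its covariance (with the mean profiled out by GLS), and average the
member ordinary-kriging surfaces by those normalised weights. With
`K = 1` this is exactly ordinary kriging under the fitted model. Two
deliberate departures from the proprietary implementation this mimics:
no data subsetting (pointless at n = 30) and a single parametric family
per call; both keep the ensemble interpretable and testable.

Pollution-area detection compares the *site fraction* (percent of sites
violating the contamination rule) with the *area fraction* (percent of
study-polygon grid cells violating it) on the combined surface — the
unweighted cellwise mean of the kriging and IDW surfaces, the simplest
faithful reading of "combined interpolation"; either surface alone is a
switch away. The study polygon is the convex hull of the sites buffered
by the median nearest-neighbour distance (the true basin boundary of any
given survey being unknowable from coordinates alone), and the default
grid puts 100 cells along the longer bounding-box axis. Site fractions
are grid-free by construction; on smooth fields the area fraction moves
by well under 2 percentage points between 50- and 100-cell grids.

## Self-organizing map and cluster count

The SOM is a rectangular-topology batch SOM on z-scored concentrations:
codebook vectors are initialised from seeded draws of the data, and each
epoch reassigns best-matching units (BMUs) and replaces every codebook
vector by the neighbourhood-weighted mean of the samples, with a Gaussian
neighbourhood whose radius shrinks linearly from $\max(rows, cols)/2$ to
1. The default map is the aspect-balanced $\approx 5\sqrt n$-unit grid
(6×5 for n = 30). Training is deterministic given the seed.

Cluster count is chosen by k-means on the codebook followed by the
Davies–Bouldin index (mean over clusters of the worst pairwise
$(\sigma_i + \sigma_j)/d_{ij}$), minimised over k = 2..10 — the index is
undefined at k = 1. Two guards matter on small maps and are part of the
package's design: (i) only BMU-occupied units are clustered, because the
interpolating units a small map places between data regions carry no
samples yet would dominate the validity index (unoccupied units are
assigned to the nearest centroid afterwards); (ii) partitions containing
empty or singleton clusters are skipped as degenerate, because a
singleton's zero dispersion drives the DBI toward zero as k approaches
the number of units. With both guards, three well-separated planted
clusters are recovered as k = 3 across essentially all training seeds we
probed; without them the index frequently selected k ≥ 9.

Component planes are the per-metal slices of the codebook; the Pearson
correlation between two planes over units summarises the association the
maps show visually, and block-correlated inputs reproduce the expected
sign structure.

## PMF receptor model

The receptor model factorizes the sites × metals matrix $X \approx GF$
with $G \ge 0$ (n × p contributions) and $F \ge 0$ (p × m profiles),
minimising the uncertainty-weighted objective
$$Q = \sum_{ij} \left(\frac{x_{ij} - (GF)_{ij}}{u_{ij}}\right)^2 .$$

Uncertainties follow the two-branch EPA convention: below the detection
limit, $u = \tfrac{5}{6}\,MDL$ and the value is replaced by $MDL/2$;
above it, $u = \sqrt{(\sigma_j x)^2 + (0.5\,MDL)^2}$ — the square root is
essential on dimensional grounds (without it u would carry mg²/kg²). The
error fraction $\sigma_j$ defaults to 0.10 for every metal and is the
single most result-sensitive unknown; it is a column of the reference
table precisely so it can be overridden.

Optimisation uses weighted multiplicative updates (weights $1/u^2$),
which preserve nonnegativity and never increase Q — a property asserted
per iteration in the tests. Each fit restarts from `n_runs = 20` seeded
uniform initialisations and keeps the lowest Q; iteration stops when the
relative Q decrease falls below $10^{-6}$ or at 5000 iterations. The
factorization's scale ambiguity is fixed after fitting by rescaling so
each column of G averages 1, leaving $GF$ unchanged and making row k of
F the factor's mean apportioned concentration (so mass shares coincide
with row sums of F). Factor-count diagnostics over p ∈ {3, 4, 5} report
Q, Q over its expected value $nm - p(n + m)$, the share of scaled
residuals outside $[-3, 3]$ and per-metal $R^2$; on planted rank-3 data
the Q curve drops sharply to p = 3 and flattens. Mass-based factor
contributions are the default; the mean-normalised-contribution
convention is reported alongside. No robust reweighting of outlying
residuals and no rotational (Fpeak-style) or bootstrap error analysis
is included.

## The synthetic survey generator

The generator exists so that every stage runs and is testable without
restricted survey data; its defaults *are* the study conditions. Thirty
sites in five land-use strata (5/7/6/7/5) occupy rectangular blocks of a
2 km × 2 km study area with an arbitrary local origin. Per metal and
stratum, concentrations are lognormal with the two moments matched
exactly to the stratum's (mean, sd) — calibrated to the published
per-stratum descriptive statistics of the river-port survey this package
targets — via $\sigma^2_{\log} = \log(1 + s^2/m^2)$,
$\mu_{\log} = \log m - \sigma^2_{\log}/2$. Lognormality reflects the
right-skew the assessment workflow itself assumes (it reaches for Box–Cox).
The lognormal latent is a 50/50 variance mixture of a unit-variance
Gaussian random field (exponential correlation, range = extent/4,
simulated exactly by Cholesky) and independent noise, so variograms are
non-degenerate while stratum moments stay exact; values are clamped at
half the detection limit. Where the published per-stratum tables
disagree internally (one stratum's Cr mean appears with two values), the
descriptive-statistics table is used throughout.

What the generator does **not** emulate: the real basin geometry, the
published inter-metal correlation structure (metals are generated
independently given the field), temporal structure, and censoring
patterns. Passing tests therefore demonstrate correctness of the
*methods* under controlled conditions, not agreement with any particular
field dataset.

The planted receptor datasets (`generatePMFDataset`) draw gamma
contributions (shape 1.2 — near-constant contributions would leave the
split of the mean concentration across factors unidentifiable) and
block-structured profiles, with factor mass shares set exactly to the
requested split and Gaussian noise of sd `noise_level` × |value|,
truncated at zero.

## Problem sizes and numerical choices

The shipped tests exercise: 30-site surveys for the full pipeline;
200-site fields for variogram recovery (5 independent realisations,
judged in the median); planted 3-factor, 30 × 8 receptor problems at 5%
noise with 20 multistart runs; 30-sample, 3-cluster SOM problems on 6×5
maps; 50- vs 100-cell grids for area-fraction stability; and 8-fold
held-out comparisons of the ensemble predictor (K = 15) against ordinary
kriging. Ties and degenerate cases are resolved explicitly: lower-closed
risk bins, the 0.5 range-normalisation convention for constant-Pi
metals, duplicate-site averaging before kriging, IDW exactness at
coincident cells, skipped degenerate k-means partitions, and a warning
(not an error) for non-converged best PMF runs.

## Known limitations

Exact replication of any published survey requires that survey's
screening/standard/toxicity constants and per-sample data; with the
shipped defaults the index *machinery* is exact but the index *values*
are conditional. The ensemble predictor is a documented equivalent of,
not a clone of, proprietary empirical Bayesian kriging. The SOM is
rectangular-topology only. PMF uncertainty handling has no robust mode
enabled by default and no bootstrap/displacement error estimates.
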