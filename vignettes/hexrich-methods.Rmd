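---
title: "Methods: richness gradients on equal-area hexagonal grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: richness gradients on equal-area hexagonal grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hexrich analyses latitudinal and bathymetric gradients of marine species
richness from occurrence records. This vignette is the package's account of
the statistical machinery: the measures, the spatial discretisation, the
models, the synthetic-data generator used to validate the pipeline, and the
numerical and design choices a maintainer would want spelled out.

## The three richness measures

For a set of cleaned occurrence records the package computes, per spatial
unit:

* **alpha diversity** — the number of distinct species observed in the unit
  (a hexagonal grid cell). Raw alpha confounds richness with sampling
  effort: more records find more species.
* **gamma diversity** — the number of distinct species in a region
  (a 5° latitudinal band or 100-m depth interval).
* **ES50, rarefied richness** — the expected number of species in a random
  draw of 50 sampling units. A *sample* is a unique combination of event
  date and location (coordinates rounded to 4 decimal places, about 11 m;
  configurable). Given `N` samples of which species *i* occurs in `n_i`,
  the closed-form expectation for `m` drawn samples is

  $$E[S_m] = S_{obs} - \sum_i \binom{N - n_i}{m} \Big/ \binom{N}{m},$$

  evaluated in log-gamma space so large-`N` binomials never overflow;
  ratios that underflow clamp to zero. The same formula applied to record
  counts instead of incidences gives the individual-based (records-mode)
  variant; both modes are exposed because the two conventions coexist in
  the literature and in data-portal practice. In samples mode a unit can
  hold several species, so the statistic is bounded by `S_obs` and by the
  summed richness of the 50 richest samples, not by 50; records mode is
  bounded by 50. Cells with fewer than `m` units report a missing value
  rather than a rarefied-to-fewer estimate, keeping the statistic
  comparable across cells.

  The standard error is a seeded bootstrap (default `B = 200`): sampling
  units are resampled with replacement, incidences recomputed, and the
  standard deviation of the recomputed expectations reported.

## Spatial discretisation

Cells are hexagons of equal spherical area (default 50,000 km²) laid out as
a pointy-top axial tessellation in the plane of a Lambert azimuthal
equal-area projection centred on the study box (default 0–90° N,
100–180° E; spherical Earth, R = 6371 km). Because the projection is
exactly equal-area on the sphere, every hexagon has exactly the target
spherical area, and point-in-cell assignment is exact axial ("cube")
rounding — no gaps, no overlaps, and deterministic resolution of boundary
points (the cell with the nearest centre in the hexagonal metric). Cells
are not clipped to coastlines; a cell's clipped in-box area is measured by
a midpoint subgrid on the equal-area plane (64×64 for boundary cells),
which reassembles the closed-form spherical area of the box to well within
1%. An icosahedral discrete global grid would serve equally; the axial
construction was chosen for implementability and sits behind the same
interface.

Latitudinal bands are half-open 5° intervals `[5k, 5k+5)` with the top
band closed at 90°; depth intervals are half-open 100-m intervals closed
at 11,000 m. Band ocean areas are sums of exact spherical zone areas of
5-arcmin ocean-mask cells whose centres fall in the band. Environmental
layers are sampled at cell mid-points by nearest-cell-centre lookup, the
conventional way of collating point summaries with gridded layers.

## Occurrence cleaning

The ingest pipeline reads Darwin-Core-style CSV (column dialects are
remappable), then: flags unparseable or out-of-range coordinates/depths/
dates as `dubious` and fossil records as `fossil`; removes exact
duplicates on (name, latitude, longitude, depth, date), keeping the first
in input order; reconciles names against a user-supplied synonym table
(made idempotent by construction: accepted names map to themselves);
restricts to the study box (closed edges); and drops flagged records.
Every step reports its count so input = kept + dropped always balances.
Records without depth stay in latitude analyses but are excluded (and
counted) from depth-stratified ones. The shallow/deep boundary is depth
≤ 500 m vs > 500 m. Habitat classification crosses this split with a
benthic/pelagic trait table; species recorded as both benthic and pelagic
contribute one category-record to each group, so category totals may
exceed the record count. Manual expert vetting of individual records is
out of scope; only rule-based flags are implemented.

## Models of environmental drivers

Per hexagon, richness responses (species counts, or ES50 rounded to the
nearest integer so the count family applies; a high dispersion then simply
reflects the rounding) are modelled with log-link negative-binomial
regressions fitted by penalized IRLS:

* environmental terms enter as cubic B-spline expansions (default 5 basis
  functions; 1 requests a plain linear term) with a second-difference
  ridge penalty; the penalty weight is chosen by generalized
  cross-validation, `n·D/(n − edf)²`, on the fixed grid `10^(-3..4)`;
* the spatial term is the real spherical-harmonic basis of degree 1–3
  (15 functions) evaluated on the unit sphere at cell mid-points —
  a smooth on the sphere capturing broad spatial autocorrelation;
* sampling effort enters as a standardised log(records) covariate — only
  for species-count responses, never for ES50, which already standardizes
  effort;
* the dispersion θ is profiled by alternating a univariate
  maximum-likelihood solve with the IRLS;
* effective degrees of freedom are the trace of the influence matrix
  (so penalized terms are charged what they actually use), plus one for θ.

Candidate sets follow a fixed design: intercept-only; effort-only;
spatial-only; effort+spatial; one model per predictor (each with effort
and spatial terms); and an all-predictor model. The shallow stratum has 8
candidate predictors (temperature, dissolved oxygen, productivity,
chlorophyll, current velocity, oxygen saturation, salinity, nitrate); the
deep stratum omits the two surface-only ones (productivity, oxygen
saturation). That yields 13 / 11 / 11 / 9 models for
counts-shallow / ES50-shallow / counts-deep / ES50-deep. Models are ranked
by the small-sample Akaike criterion

$$AICc = -2\,\ell + 2k + \frac{2k(k+1)}{n-k-1},$$

with ΔAICc < 2 flagged as an inconclusive distinction. A deliberate
simplification relative to REML-based automatic term selection with
double-penalty shrinkage: smoothing weights come from GCV on a fixed grid
and term selection happens only through the AICc candidate set. This is
deterministic, dependency-free, and preserves the inferential currency —
ΔAICc between candidate models. At the 5°-band scale the reduced sample
size (≤ 18 bands) does not support smooths or spatial terms, so plain
Poisson GLMs with linear terms and a records-per-band effort covariate are
used, as is conventional.

Trend curves drawn through aggregated profiles are ordinary least squares:
order-6 polynomials against latitude, logarithmic (`y = a + b ln x`)
against depth.

## The synthetic-data generator

The generator builds worlds with the structure the analysis assumes, plus
ground truth for recovery testing. Its defaults are the package's
canonical study conditions:

* **Latitudinal richness profile** — sum of two Gaussian bumps
  (primary μ = 10° N, σ = 12°, amplitude 1; secondary μ = 80° N, σ = 8°,
  amplitude 0.5) minus an equatorial dip (μ = 0°, σ = 4°, amplitude 0.6),
  plus a baseline 0.15, floored at 0.05 — a bimodal gradient peaking near
  10° N with a dip at the equator and a high-latitude secondary rise.
* **Depth decay** — exponential with an 800-m e-folding scale below a
  100-m onset.
* **Abundance distribution** — log-series (the macroecological default),
  shape x = 0.95; the shape is recoverable from draws by maximum
  likelihood (the MLE solves the standard mean equation).
* **Species ranges** — latitude/longitude boxes with centres drawn from
  the richness surface per unit area (degree-cell weights carry a
  cos-latitude factor so density is uniform per km²), log-normal
  latitudinal widths (median 15°), uniform 10–30° longitudinal widths
  drawn as equatorial degrees and widened by 1/cos(latitude) so a range
  spans the same east–west distance at any latitude (high-latitude
  species tend circumpolar), and depth ranges drawn from the world's
  depth profile; ranges are truncated at the study box.
* **Record depths** — shallow with probability 0.83 (piecewise-uniform
  over 0–50/50–100/100–200/200–500 m with weights mirroring observed
  shallow sampling), truncated-exponential below 500 m; per record the
  profile is restricted to the chosen species' depth range, so every
  record lies inside its species' range by construction.
* **Effort** — an area-uniform background (cos-latitude weights per
  degree cell) blended with Gaussian hotspots (default 3 hotspots,
  σ = 3°, half the total effort), placed preferentially in species-rich
  cells; weights are normalised over ocean cells and vanish on land. A configurable land strip (60–70° N, west of
  165° E) emulates a nearly closed high-latitude band.
* **Sampling events** — records arrive in events (site × date); events are
  drawn from the effort surface and hold on average `records_per_sample`
  (default 3) records. Effort therefore scales the number of distinct
  samples, not the records per sample — which is exactly the quantity
  sample-based rarefaction standardizes for. Site positions and per-site
  date pools (default 3 dates per site, 5 sites per raster cell) are fixed
  features of a world. How many distinct samples underlie a real hexagon
  is not observable from aggregated datasets, so it is an explicit free
  parameter here.
* **Environment** — eight 2-D layers at 5-arcmin default resolution.
  Temperature decreases strictly with latitude and carries a longitudinal
  texture (two sinusoids, ~27° and 16° wavelengths) whose amplitude is
  configurable; a temperature-depth profile decreases strictly with depth.
  The remaining layers are latitude trends plus seeded mesoscale (~6°)
  Gaussian-bump noise fields, so predictors are correlated with latitude
  but mutually distinguishable, and no decoy predictor carries structure
  at the temperature texture's scale.
* **Coupling** — a coefficient in [0, 1] blends the geometric latitude
  profile (0, the default null condition) with a monotone transform of the
  temperature field (1), `exp(0.08·T)`, both normalised to unit mean over
  ocean.

What the generator deliberately does not emulate: real coastline geometry,
taxonomic structure (names are opaque identifiers), temporally clustered
survey campaigns, depth-varying environmental rasters, and observation
error in coordinates. Passing recovery tests therefore demonstrates that
the pipeline's statistics behave as designed under known structure — not
that any particular real-world dataset satisfies that structure.

## Problem sizes and evaluation conditions

Unit tests run on coarse worlds (30–60 arcmin rasters, 10²–10³ species,
10³–2·10⁴ records) — the package's chosen problem sizes for fast,
deterministic checks; the statistics are resolution-independent. The
recovery experiments use a "survey network" configuration: 8·10⁴ records
of 10⁴ species with compact ranges (median 10° latitudinal; 5–15°
equatorial-degree longitudinal widths scaled to a constant physical
width), 15 repeat-station hotspot regions holding a quarter of total
effort over an area-uniform background, ~1.5 records per event, and site
density scaled with raster resolution so hundreds of hexagons accumulate
the ≥ 50 sampling units ES50 needs. The driver-recovery experiment models
records-mode ES50: at survey-scale effort a cell's distinct-species count
is nearly its record count, so raw counts carry almost no pool-size
information beyond the effort covariate — the effort-standardized
statistic is where the environmental signal lives. Scattered, spatially spread sampling
is what gives an effort-standardized statistic leverage; concentrating
effort in a handful of blobs leaves any environmental signal confounded
with a few cluster means, and saturating a region's sampling capacity
converts effort into records-per-sample — both failure modes the spread
configuration avoids (and which are worth remembering when interpreting
real portal data).

A hard lesson from building the generator, documented here because it
shapes what recovery tests can show: richness signals expressed only
through the *placement of species ranges* are low-pass filtered by the
ranges themselves (a 20°-wide range smears any finer longitudinal
structure), and the residual local pool size fluctuates with the finite
species pool, with spatial correlation at exactly the range scale. Signal
recovery through a spatial-smooth-controlled model therefore needs either
a large pool, an environmental structure coarser than the range scale but
finer than the spatial smooth, or responses read at high effort.

## Numerical choices and degenerate inputs

* Binomial ratios in rarefaction via `lchoose`; impossible draws
  (`k > n`) give zero contribution; `m` exceeding the available units
  gives a missing value, `m ≤ 0` an error.
* IRLS convergence on relative deviance change (10⁻⁸, max 50 iterations);
  singular systems fall back to a 10⁻⁶ ridge; a 10⁻⁸ ridge floor sits on
  all non-intercept coefficients. Non-converged fits are excluded from
  selection tables with a warning rather than failing the run.
* θ is profiled on [10⁻³, 10⁷]; equidispersed data drive it to the upper
  bound and the fit is reported with the Poisson-limit likelihood.
* Boundary ties in cell assignment resolve by axial rounding
  (deterministic); the top latitude band and bottom depth interval are
  closed so 90° N and 11,000 m are representable.
* All randomness (generator, bootstrap, experiments) flows from explicit
  integer seeds through an RNG-state-preserving wrapper; reruns are
  byte-identical.

## Known limitations

* Sample-mode ES50 depends on the records-per-sample distribution; two
  datasets with different event granularity are not directly comparable
  on this statistic, and extreme effort concentration inflates it by a
  few percent when sampling events merge at shared (site, date) slots.
  Records mode is granularity-free and bounded by 50; both are provided.
* Bootstrap standard errors quantify resampling noise around the realized
  assemblage; differences between two cells also carry finite-pool
  variation in which species occur locally, which no within-cell
  resampling can see.
* The spherical-harmonic spatial term is global over the study box;
  hotspot-scale (< 20°) spatial autocorrelation is not absorbed by it and
  will inflate apparent environmental effects if predictors carry
  structure at that scale.
* GCV can over- or under-smooth at small cell counts (< 50); candidate
  comparison remains valid because every model faces the same rule.
* With many candidate predictors, the single best-AICc label is won by a
  chance predictor a substantial fraction of the time even under a null;
  the ΔAICc < 2 inconclusiveness rule, not the winner's identity, is the
  reliable inferential currency.
* Areas use a spherical Earth; geodesic refinements change hexagon areas
  by < 0.3% and are out of scope.
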