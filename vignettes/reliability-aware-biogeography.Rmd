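---
title: "Reliability-aware biogeography of larval developmental modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability-aware biogeography of larval developmental modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thorsonr)
```

## The problem

Thorson's rule asserts that the fraction of marine invertebrate species
developing without a pelagic larva increases toward the poles. Testing
it from modern data means building maps: species ranges are rasterised,
stacked by developmental mode, and the per-pixel proportion of each
mode is summarised along latitude. Every step of that chain can
manufacture a gradient that is not there — pixels holding a handful of
species yield wildly unstable proportions, and regions that were never
properly surveyed contribute pixels whose species lists reflect effort,
not ecology. `thorsonr` implements the mapping chain together with two
explicit reliability filters and the statistical models used downstream,
and pairs them with a synthetic-data generator so the whole pipeline can
be exercised against known truth.

## Hydrographic and productivity fields

Three scalar fields summarise the water column per pixel: mean
temperature `T` (°C), mean current `U` (m/s) — speeds
`sqrt(u² + v²)` are computed per (depth, time) sample *first* and then
averaged — and dynamic stratification `DS = sqrt(sd(u)² + sd(v)²)`
(m/s), the vector combination of the component standard deviations over
the whole stack. `DS` deliberately differs from `sd(U)`: reversals in
flow direction change `u` and `v` but hardly change the speed, and it
is that directional variability that vertically migrating larvae can
exploit. Standard deviations use the sample (n−1) denominator.
Depth-level averaging is unweighted even though model levels are
unevenly spaced; a `depth_weighting = "thickness"` switch exists for
sensitivity analyses.

Productivity seasonality is measured on monthly chlorophyll-a series by
Colwell's indices. The series is binned into `s` equal-width magnitude
classes spanning the observed range (default `s = 11`; the maximum
falls in the top class; missing months are dropped, never imputed), and
a month × class contingency table gives, with natural-log entropies,

* constancy `C = 1 − H(Y)/log s` — 1 when every observation falls in a
  single class;
* contingency `M = (H(X) + H(Y) − H(XY))/log s` — 1 when each month
  maps deterministically to its own class (pure seasonality);
* predictability `P = C + M`, an exact identity the tests enforce to
  1e−10.

`s` in the denominators is the *configured* class count, not the number
of occupied classes: the state space is fixed a priori, so a constant
series scores `C = 1` regardless of how many classes it could have
occupied. Equal-width binning has a known quirk worth stating: under
heavy-tailed noise the range stretches, observations concentrate in the
low classes, and apparent constancy can *rise* with noise. Our tests of
the "noisier is less predictable" property therefore stay in the
moderate-noise regime, and a `binning = "log_width"` option is
available.

## Life-history scaling

Shell volumes use idealised solids (sphere for embryos and juveniles;
cylinder, cone, parallelepiped or semi-spheroid for adults — the
semi-spheroid takes two equal equatorial semi-axes from the width and
the height as polar semi-axis). Literature size ranges collapse to
midpoints before volume computation. Developmental time follows the
metabolic temperature–size model `DT = (4/a₀)·e^{E/kT}·ΔS^α` with
activation energy `E = 0.65` eV, Boltzmann constant in eV/K, `α = 0.25`
and `ΔS = JS − IS` in mm³. The constant `4/a₀` is calibrated by
ordinary least squares of observed developmental times on the metabolic
term, *through the origin*: the slope is the constant, and a free
intercept would change its meaning. R² is reported about the mean of
the observations; an `intercept = TRUE` option exists because the
through-origin choice is a modelling convention, not a law. Species
lacking a juvenile volume get `DT = NA` rather than an imputation.

Fecundity uses the mass scaling `ln Cx = −0.99 ln m₀ + 19.15` with
`C = Cx·M^0.75·e^{−E/kT}`; masses come from volumes at a density of
1 g/L taken literally (1 mm³ = 10⁻⁶ g), with a `density_g_per_L`
override for users who prefer a tissue-like density — the default
reproduces the published constant's calibration.

## From ranges to reliable proportion maps

A species' literature range (one or more lat/lon rectangles) is
rasterised by cell centres, then intersected with its depth range
(inclusive bounds against cell bathymetry) and its habitat classes;
latitude-corrected cell areas (`(res·111.32 km)²·cos φ`) sum to a
potential habitat surface. Stacking the per-species masks gives pixel
richness and per-mode proportions (proportions are undefined, not zero,
in empty pixels).

Two filters decide which pixels can be trusted:

* **Minimum richness.** To detect an absolute deviation `ΔP` from a
  reference proportion `P` with power `1−β` at two-sided level `α`, a
  pixel needs `N_min = ⌈((z_{1−α/2}+z_{β})/ΔP)²·P(1−P)⌉` species. At
  `P = 0.351` (33 non-pelagic among 94 species) and `ΔP = 0.30`, the
  default α = 0.05 / power = 0.8 give `N_min = 20`. `ΔP` is an
  *absolute* proportion deviation; that reading is forced by
  back-solving the formula to the published threshold.
* **Survey completeness.** Occurrence records binned into 0.5° pixels
  give observed richness `S_obs` and singleton/doubleton counts; the
  Chao1 lower bound `S_obs + f1²/(2f2)` (classic fallback
  `S_obs + f1(f1−1)/2` when `f2 = 0`; bias-corrected form available)
  yields a relative index `Chao1/S_obs`, and a pixel counts as
  well-surveyed when it is below 1.2. Pixels with no records fail.
  The N_min filter is what protects against the low-effort pathology in
  which a pixel with one or two records looks spuriously "complete".

Band summaries over 5° latitude bins come in the three methodologies —
`pooled` (one proportion from the species present anywhere in the
band), `pixel_mean` (mean ± sd over occupied pixels), `filtered`
(`pixel_mean` over pixels passing both filters) — with empty bands
reported as `NA`, never dropped. A permutation test draws same-size
species sets from the full pool *without replacement* and counts, over
100 permutations, how often the permuted non-pelagic proportion
deviates from the pool reference at least as much as the observed one
(two-sided, ties counted as extreme — conservative). The resampling
scheme and sidedness were genuinely open design choices; both are
recorded here as the package's convention.

## Spatial and mixed models

Proportions are logit-transformed with clipping at `eps = 1e−3`
(species-poor pixels produce exact 0s and 1s). Candidate predictor
subsets are screened by pairwise |Pearson r| < 0.65 and VIF < 3.
Moran's I correlograms use binary membership weights in 50-km
great-circle distance bins (haversine, Earth radius 6371 km); the patch
size is the first positive-to-negative zero crossing, linearly
interpolated between bin centres, and is reported as missing when the
correlogram never crosses zero. Spatial weights are inverse-distance
(`1/d`, exponent configurable) truncated at the patch size and
row-standardised; isolated points keep all-zero rows and are flagged.

The spatial lag model `y = ρWy + Xβ + ε` is fitted by profile maximum
likelihood with the log-determinant `log|I − ρW|` evaluated exactly
from the eigenvalues of `W` — exact and cheap at the few-hundred-pixel
scale of filtered maps, where sparse approximations would buy nothing.
`ρ` is searched inside the interval defined by the extreme eigenvalues;
standard errors come from the numeric Hessian of the full likelihood;
`ρ`'s significance is a likelihood-ratio test against the `ρ = 0`
(OLS) model, whose AIC is reported alongside. Model R² is from an
ordinary regression of observed on predicted values, with predictions
taken from the reduced form `(I − ρW)^{-1}Xβ`. AIC selects among
admissible candidate subsets; exact ties go to the smaller subset.

Trait structure uses PCA on natural-log, z-scored continuous traits
with unscaled 0/1 dummies for mode and diet (all levels kept in the
PCA; regression designs drop a reference level). PC scores are
modelled with linear mixed models (superfamily random intercept, ML
rather than REML so likelihoods are comparable across random
structures), and the binary pelagic/non-pelagic outcome with a weighted
binomial mixed model. Class weights are inverse-frequency, normalised
to sum to n. The binomial fits use `glmmTMB`, which accepts
non-integer prior weights cleanly. R² components follow the
variance-partition convention (fixed variance over total; group
variance over total), which guarantees `r2_total ≥ r2_fixed`; accuracy
is reported at a 0.5 probability threshold overall and as per-class
recall, so total accuracy is exactly the frequency-weighted mean of the
class accuracies.

## The synthetic world and what it does (and does not) show

`gen_world()` draws a complete seeded study system. Its defaults encode
one fixed scenario, chosen to emulate the study system's stated
conditions and then left alone:

* a 0.5°, 25–70°N grid whose shallow (shelf/bank) cells are scattered
  across longitude with an areal fraction declining poleward from 0.8
  to 0.1 — high latitudes are mostly deep sea; shelf depths 10–120 m,
  deep cells 400–1500 m;
* temperature declining poleward 20 → 5 °C with a mild depth term;
  AR(1) current series with planted stationary moments so `U` and `DS`
  have known expectations;
* 19 years of monthly chlorophyll per pixel whose seasonal amplitude
  varies from pixel to pixel *without any spatial trend*, putting the
  contingency field in the realistic 0.1–0.35 range;
* 94 species: 15% deep-ranged (so deep pixels hold ~5–10 species, an
  order of magnitude below `N_min`), depth/habitat-filtered
  distributions, longitudinal range rectangles drawn at random, and
  latitudinal extents spanning the grid by default;
* developmental mode drawn per species from
  `P(pelagic) = plogis(3.4 − 0.0047·depth − 14.2·M_CHLA)` on the
  species' range means — deep-ranged species come out overwhelmingly
  non-pelagic; latitude never enters; superfamily labels are
  independent of mode by default, with a coupling knob
  (`superfamily_sd`) for power analyses;
* occurrence records per pixel and species as Poisson counts with mean
  equal to a sampling-effort field, defaulting to a poleward-declining
  exponential (`8·e^{−(φ−25)/15}` records per present species).

Two default choices deserve their rationale spelled out, because both
were forced by what the sampling-artefact experiment is *for* — a world
whose only latitudinal structure is geography and effort. First, the
shallow cells are scattered banks rather than one contiguous western
shelf: with a contiguous margin, northern shelf pixels exist only at
low longitudes, and any random longitudinal composition gradient (from
species' longitudinal range edges) masquerades as a latitudinal trend.
Second, default latitudinal ranges span the grid: range edges inside
the well-surveyed zone make band composition drift as a random walk
across bands, which a scale-free trend test reads as a monotone trend
in either direction. Narrower, edge-rich pools — useful for studying
exactly those turnover effects — are one knob away
(`lat_start_frac`, `lat_extent_frac`), but they are not the null
scenario.

The headline experiment (`sampling_artefact_experiment()`) then runs
replicate worlds and summarises the non-pelagic band proportions two
ways. The naive per-pixel average inherits the geography: northern
bands are dominated by deep, species-poor pixels whose few residents
are non-pelagic, so a strong, significant poleward rise appears in
essentially every world. The reliability-filtered method (richness ≥
`N_min`, relative Chao < 1.2) discards those pixels and shows no
monotone trend (Mann–Kendall at α = 0.05) in ≥ 90% of worlds. What
passing this experiment shows is that the *filters* remove the
artefact under these controlled conditions; it does not show that real
European data are free of other biases (taxonomic error, range-map
error, habitat-map error are not modelled), nor does the generator
attempt real coastline geometry or the real 94 species' trait values.

## Numerical conventions and degenerate inputs

Sample standard deviations everywhere; natural logs everywhere; ties in
AIC broken toward fewer predictors; the permutation p-value counts ties
as extreme; `classify_states` sends the maximum to the top class and a
constant series to class 1 (no error); `chao1` requires
`S_obs ≥ f1 + f2`; empty distributions, empty bands and unsurveyed
pixels are reported (NA/flags/warnings), never silently dropped;
`build_weights` refuses coincident points; `fit_sar_lag` refuses
singular designs and reports convergence context on failure. All
generators take an explicit seed and are bit-reproducible for a fixed
seed and parameter set.

## Problem sizes used in the checks

The test suite exercises the identity and oracle checks at 100–1000
random instances (Colwell identities at 1000 series; Chao1 against
brute-force counting at 500 assemblages; permutation calibration at
1000 null pixels × 100 permutations), parameter recovery at 100
replicates (SAR at n = 200 pixels; binomial mixed models at n = 500
species), and the sampling-artefact experiment at 50 replicate worlds
of 94 species on a 90 × 20 grid. These sizes keep Monte-Carlo error
comfortably inside the asserted bounds while the full suite runs in a
few minutes.

## Known limitations

* Real-data ingestion (NetCDF/GeoTIFF) is out of scope here; grids are
  plain tibbles and CSV round-trips are the supported exchange format.
* Equal-width Colwell binning is sensitive to outliers (see above).
* The SAR eigenvalue approach is dense: fine for hundreds of pixels,
  not for 10⁵.
* Superfamily random intercepts are a coarse stand-in for phylogeny;
  no branch lengths exist, so true phylogenetic comparative methods are
  deliberately not offered.
* The normal-approximation behind `N_min` is anti-conservative for
  proportions near 0 or 1; at the reference proportions involved here
  it is adequate.
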