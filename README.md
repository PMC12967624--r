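# thorsonr

Thorson's rule is the classical claim that the proportion of marine
invertebrate species with non-pelagic (direct) development rises toward
high latitudes. Whether such a gradient is real or an artefact of where
the sea has actually been sampled is a question about *map reliability*
as much as about larval biology. `thorsonr` is an R package for
macroecologists and larval biologists that implements a spatially
explicit, reliability-aware pipeline for testing latitudinal gradients
in developmental mode, together with a seeded synthetic-world generator
that lets every stage be validated against known ground truth.

## What the package computes

**Environmental and productivity fields.** Per-pixel hydrographic
summaries from velocity/temperature stacks — water-column mean
temperature `T`, mean current `U = mean(sqrt(u² + v²))`, and dynamic
stratification `DS = sqrt(sd(u)² + sd(v)²)` — plus Colwell's
predictability decomposition of monthly chlorophyll-a series into
constancy and contingency (seasonality):

    C = 1 − H(Y)/log s,   M = (H(X) + H(Y) − H(XY))/log s,   P = C + M

computed from a month × magnitude-class contingency table with `s = 11`
equal-width classes and natural-log entropies.

**Metabolic-theory life history.** Per species: shell volumes from
idealised solids, growth ratios `Gr1 = JS/IS`, `Gr2 = AS/JS`,
`Gr3 = AS/IS`, developmental time from the temperature–size scaling

    DT = (4/a₀) · e^{E/kT} · ΔS^α,   E = 0.65 eV, α = 0.25

with the constant `4/a₀` calibrated by a through-origin regression of
observed developmental times on the metabolic term, and fecundity
`C = Cx · M^0.75 · e^{−E/kT}` with `ln Cx = −0.99 ln m₀ + 19.15`.

**Proportion maps and reliability filtering.** Literature ranges are
rasterised, filtered by depth and bottom habitat into potential
distributions, and stacked into per-pixel richness and per-mode
proportions. Two reliability filters define trustworthy pixels: a
minimum species count from a normal-approximation power calculation,

    N_min = ⌈((z_{1−α/2} + z_power)/ΔP)² · P(1−P)⌉

(20 species at the reference proportion P = 0.351, ΔP = 0.30, α = 0.05,
power 0.8), and a Chao1-based survey-completeness test on an independent
occurrence database (`relative Chao = (S_obs + f1²/(2f2)) / S_obs < 1.2`).
Latitudinal band summaries come in three methodologies (species pooling,
per-pixel averaging, reliability-filtered averaging), plus a permutation
test for per-pixel deviations from the pool reference proportion.

**Spatial and trait modelling.** Collinearity screening (pairwise
|r| < 0.65, VIF < 3), Moran's I correlograms with patch size (first
zero crossing), inverse-distance row-standardised weights, maximum
likelihood spatial-lag (SAR) models `y = ρWy + Xβ + ε` with exact
eigenvalue log-determinants, AIC model selection; trait PCA with dummy
coding; linear and weighted binomial mixed models with superfamily
random intercepts, likelihood-ratio tests and variance-partitioned R².

**Synthetic worlds.** `gen_world()` builds a seeded study system —
bathymetry with a poleward-shrinking shallow fraction, temperature,
currents, seasonal chlorophyll, a species pool whose developmental mode
follows a logistic model on depth and seasonality (never latitude),
and occurrence records under spatially biased sampling effort — with
the planted parameters stored as ground truth.

## Worked example: manufacturing and dissolving a false gradient

```r
library(thorsonr)
library(dplyr)

w  <- gen_world(42)                     # seeded synthetic study system
p_ref <- mean(w$species$mode == "non_pelagic")   # 0.394
nm <- n_min(p_ref, 0.3)                 # 21 species
pm <- reliability_mask(w$prop_map, w$occ_summary, nmin = nm)

naive    <- band_summary(pm, "pixel_mean")
filtered <- band_summary(pm, "filtered")
np <- function(b) b$proportion[b$mode == "non_pelagic"]
mann_kendall(np(naive))
mann_kendall(np(filtered))
```

The naive per-pixel average shows a smooth poleward rise in the
non-pelagic proportion, 0.54 in the 25–30° band to 0.89 in the 65–70°
band, and the Mann–Kendall test calls it a perfect monotone trend
(tau = 1, p = 5.5e-6) — even though developmental mode in this world
depends only on depth and productivity seasonality. The filtered method
keeps only pixels with at least 21 modelled species inside
well-surveyed 0.5° cells (relative Chao < 1.2); its band means hover
around 0.27–0.35 with no trend (tau = 0.14, p = 0.77). The false
gradient was manufactured entirely by deep, species-poor,
under-surveyed high-latitude pixels.

The filtered pixels can then be modelled spatially:

```r
px <- pm |> filter(passes) |> mutate(logit_np = logit_transform(prop_np))
cg <- morans_correlogram(px, "logit_np", bin_width_km = 50)
cg$patch_size_km                        # 466 km
W  <- build_weights(px, cg$patch_size_km)
sel <- select_model(px, "logit_np", candidate_screen(px, c("depth", "T", "M_CHLA")), W)
sel$best
```

AIC selects depth with a positive coefficient (0.0025 per m,
z = 4.6): even inside the reliable region, deeper pixels carry more
non-pelagic developers, the planted biology. The spatial lag parameter
is large and strongly supported (ΔAIC ≈ 200 against ordinary least
squares) because neighbouring pixels share much of their species
composition.

Fitted objects have `tidy()`, `glance()` and `autoplot()` methods;
`plot_map()` and `plot_band_summary()` draw the standard figures.

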