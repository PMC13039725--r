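# bioclimfutures

Projecting community turnover and extinction debt under combined climate
and land-use scenarios.

National biodiversity policy needs spatially explicit projections of how
whole communities — not single species — respond to plausible futures.
`bioclimfutures` implements a community-level projection pipeline for
ecologists working with structured monitoring data (site × species × year
incidence records) and scenario-based environmental layers:

1. **Generalised dissimilarity models (GDMs).** Pairwise Jaccard
   dissimilarity between sites is regressed on environmental separation
   through monotone I-spline transforms and a negative exponential link,

   *d<sub>ij</sub>* = 1 − exp(−(*a*₀ + Σ<sub>p,k</sub> β<sub>pk</sub>
   |I<sub>pk</sub>(x<sub>pi</sub>) − I<sub>pk</sub>(x<sub>pj</sub>)|)),
   with *a*₀, β<sub>pk</sub> ≥ 0,

   fitted by damped Gauss–Newton over non-negative least squares
   subproblems, with site pairs weighted by Chao incidence sample
   coverage.
2. **Beta-diversity projections.** The fitted transforms map current and
   future climates into a common "bioclimate space", yielding per-cell
   compositional change, disappearing bioclimates (current cells with no
   future analogue within a 10% dissimilarity threshold), novel
   bioclimates (the mirror image), and their spatial overlap.
3. **Habitat condition.** Land-use projections are converted to per-cell
   condition maps via per-class Biodiversity Intactness Index (BII)
   coefficients — estimable from multi-study abundance tables (abundance
   and balanced Bray–Curtis compositional-similarity components), with
   urban-imperviousness, agroforestry-averaging and time-varying
   hyper-intensive adjustments.
4. **Species heading for extinction.** The species–area relationship
   (exponent *z* = 0.25) translates bioclimate-similarity-weighted
   habitat loss into per-cell persistence
   *p<sub>i</sub>* = [Σ Sim·hab<sub>fut</sub> / Σ Sim·hab<sub>cur</sub>]<sup>z</sup>,
   aggregated as a weighted geometric mean whose complement, scaled by the
   regional species total, counts species heading for extinction.

Every input can be simulated by the built-in generators (niche-structured
communities, smooth climate shifts, Markov land-use change, multi-study
abundance tables) with exposed ground truth, so all estimators are
testable by parameter recovery. See the vignette
(`vignettes/projecting-biodiversity-futures.Rmd`) for models, assumptions
and design choices.

## Worked example

A complete synthetic run — landscape, communities, model fit, projections
under a mild (RCP2.6-SSP1-like) and a severe (RCP8.5-SSP5-like) scenario,
habitat condition, extinction counts:

```r
library(bioclimfutures)

cfg <- default_run_config(seed = 42, grid_dims = c(16L, 16L),
                          n_species = 100L, n_sites = 90L, max_pairs = 2500L)
run <- run_pipeline(cfg)           # add out_dir = "run1" to write artefacts
run$model
#> gdm_model: 10 predictor(s), intercept 1.0728, sse objective
#>   sum of spline coefficients per predictor:
#>                tri                twi            soil_ph               tmin
#>             0.5365             0.5567             0.7289             0.3108
#>               tmax      diurnal_range      annual_precip precip_seasonality
#>             0.9734             0.2080             0.3385             0.4224
#>        peti_driest           sunshine
#>             0.6513             0.2762
#>   explained deviance (binomial form): 28.7%

ext <- run$extinction
ext[ext$slice_start == 2060,
    c("scenario", "p_bar", "n_extinction_rounded", "median_comp_change")]
#>     scenario p_bar n_extinction_rounded median_comp_change
#>  RCP2.6-SSP1 0.916                    8              0.169
#>  RCP8.5-SSP5 0.827                   17              0.481
```

Reading the output: the fitted model explains ~29% of the deviance in
pairwise dissimilarity (typical for turnover models); the per-predictor
coefficient sums are each variable's total contribution to predicted
turnover across its range. By 2060–2080 the severe scenario roughly
doubles the species heading for extinction (17 vs 8 of 100 synthetic
species) and triples the median compositional change (48% vs 17% of a
cell's community not shared between present and future). On this small,
strongly shifted synthetic landscape every cell loses its current
bioclimate analogue under the severe scenario (`disappearing_area_pct`
= 100).

Individual stages are ordinary functions — `generate_landscape()`,
`prepare_site_pairs()`, `fit_gdm()`, `gdm_transform()`,
`compositional_change()`, `disappearing_bioclimates()`,
`estimate_bii_coefficients()`, `habitat_condition_map()`,
`persistence_map()`, `aggregate_persistence()` — and compose freely
outside the pipeline wrapper.

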