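# batscape

Weather-surveillance radar incidentally records flying animals, and with an
upstream classifier that turns each scan into a binary bat presence grid,
a season of radar becomes a wall-to-wall map of where insectivorous bats
forage. batscape is an R package for everything downstream of that
classifier: it aggregates per-scan presence grids into seasonal activity
surfaces, corrects them for roost-commute inflation, computes area-weighted
land-cover foraging statistics with bootstrap confidence intervals, derives
a temperature-driven relative mosquito-abundance proxy for flying insect
prey, and fits a spatial GAM asking whether bats are more active where prey
density is predicted to be high. It is aimed at aeroecologists and
ecosystem-services researchers working with radar-derived activity maps
over agricultural landscapes.

Because radar-derived activity stacks are rarely redistributable, the
package includes a first-class synthetic landscape generator with known
ground truth (`landscapeConfig()`, `simulateLandcover()`,
`simulateActivity()`, `simulateCovariates()`), so every stage is testable
end to end without any download.

## The core quantities

* **Activity rate.** A pixel detected in *k* scans over the season holds
  count *k*; rates are `count / (pixel area in ha × nights)`, in
  occurrences·ha⁻¹·night⁻¹ (a 70 m pixel is 0.49 ha).
* **Roost correction.** Counts near roosts are inflated by commuting
  rather than foraging bats; each pixel is multiplied by
  `f(d) = 1 / (1 + A·exp(−d/λ))` with distance *d* to the nearest roost
  (defaults A = 1, λ = 5000 m).
* **Class statistics.** Parcel means are combined into area-weighted class
  means `Σ aᵢr̄ᵢ / Σ aᵢ` with a seeded parcel bootstrap 95% CI.
* **Prey proxy.** Relative mosquito abundance
  `M(T) = EFD(T)·pEA(T)·MDR(T) / max(μ(T), floor)²` from Briere/quadratic
  thermal performance curves, zero outside the trait thermal limits.
* **Association model.** `activity ~ s(mosquito, bs="cr") + lights +
  irrigated_ha + class + s(x, y, bs="gp")`, Gaussian, fitted by REML
  (mgcv).

See `vignettes/batscape-methods.Rmd` for assumptions, parameter meanings
and limitations.

## Worked example

The rate normalization on the season's bookkeeping numbers:

```r
library(batscape)
a <- activityRaster(matrix(7431L, 1, 1), nNights = 152, nScenes = 19169)
gridValues(toRate(a))[1, 1]
#> [1] 99.77175
```

7431 occurrences in one 0.49 ha pixel over 152 nights is ≈ 99.77
occurrences per hectare per night.

A small synthetic season, end to end:

```r
cfg <- landscapeConfig(gridWidth = 60, gridHeight = 50, nNights = 20,
                       scansPerNight = 30, nPatches = 60, seed = 42)
lc   <- simulateLandcover(cfg)
act  <- simulateActivity(cfg, lc)          # 600 scans, streamed
corr <- correctActivity(toRate(act), roostSet(cfg@roosts),
                        decayParams(cfg@amplitude, cfg@scale))
st   <- extractParcelStats(corr, lc, counts = act)
s    <- classSummaries(st, nBoot = 1000, seed = 42)
head(rankAndRatios(s), 4)
#>   rank        class mean_rate ratio_to_overall ratio_to_next
#> 1    1         rice      6.59             1.90          1.47
#> 2    2 barren/other      4.47             1.29          1.11
#> 3    3   herbaceous      4.04             1.17          1.00
#> 4    4      conifer      4.03             1.16          1.04
```

Rice tops the ranking (the generator's weights put it there), 1.47× the
runner-up; `mean_rate` is the area-weighted class mean in
occurrences·ha⁻¹·night⁻¹ after roost correction and `ratio_to_overall`
compares it with the study-wide mean. Continuing to the association model:

```r
cov  <- simulateCovariates(cfg, lc)
mosq <- abundanceRaster(cov$temperature, readTraitConfig(), pixelSize = 70)
tab  <- buildPixelTable(corr, mosq, cov$lights, cov$irrigated, lc,
                        cellSizePx = 10)
fit  <- fitGam(tab, kSpace = 20)
#> Warning: dropping class(es) with < 2 cells: desert, miscellaneous
modelTerms(fit)[modelTerms(fit)$term == "LULC: rice", ]
#>         term estimate   ci_lo  ci_hi         p
#>   LULC: rice  2.41273 1.50494 3.3205 0.0001684
```

At this toy size (28 cells) thin classes are dropped with a warning and
the reference class falls back to the most frequent one; the rice contrast
is positive and significant, consistent with the simulated weights. The
whole chain — plus covariate simulation, the mosquito surface and a
checksummed output manifest — is also available as one call:

```r
runPipeline(cfg, "out/", nBoot = 1000, cellSizePx = 10, kSpace = 20)
```

and as a shell wrapper, `Rscript inst/scripts/batscape.R run --seed 42
--out out/`.

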