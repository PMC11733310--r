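---
title: "Methods: from radar scans to foraging surfaces and prey association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from radar scans to foraging surfaces and prey association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batscape)
```

## The measurement model

Weather-surveillance radar incidentally detects flying animals. An upstream
classifier turns each radar scan into a binary presence/absence grid at 70 m
resolution: a pixel is "present" in a scan when a group of bats dense enough
to register in the radar signal is flying over it. batscape starts from
those per-scan binary grids (`PresenceScene`) and everything downstream is
arithmetic on them — there is no radar physics in this package.

Summed over a season, a pixel detected in five scans of one evening
contributes five occurrences. The seasonal count raster (`ActivityRaster`)
is normalized to the standardized unit *occurrences per hectare per night*:

$$\mathrm{rate} = \frac{\mathrm{count}}{\mathrm{pixel\ area\ (ha)}
  \times \mathrm{nights}}$$

A 70 m pixel is $0.49$ ha, so a pixel with 7431 occurrences over a 152-night
season normalizes to $7431 / (0.49 \times 152) \approx 99.77$
occurrences ha$^{-1}$ night$^{-1}$ — the worked example in the README shows
this computed by `toRate()`. Counts are stored as integers, rates as
doubles. Coverage or clutter masking (`applyMask()`) sets pixels to
*missing*, never zero: a zero would silently drag every area-weighted mean
toward zero, a missing value drops out of them.

## Roost-commute correction

Colonial bats concentrate at roosts, and detections near a roost are
dominated by departing and returning animals rather than foraging. We
remove this commute artifact with a multiplicative exponential
distance-decay factor applied to each pixel at distance $d$ (meters) from
its nearest roost:

$$f(d) = \frac{1}{1 + A\,e^{-d/\lambda}}$$

with amplitude $A \ge 0$ (how strongly a pixel *at* the roost is
down-weighted: factor $1/(1+A)$ at $d = 0$) and scale $\lambda > 0$ m (the
e-folding distance of the commute plume). The factor rises strictly with
distance and approaches 1, so pixels far from any roost are untouched, the
correction never inflates a value and never produces a negative one.
Defaults are $A = 1$ and $\lambda = 5000$ m — the order of a nightly
commute radius for a colonial, fast-flying insectivore — and both are
recorded in every pipeline manifest. This bounded multiplicative form was
chosen over subtracting an expected commute surface because it cannot go
negative and because it reduces exactly to inverse-distance-style
down-weighting near the roost; `correctActivity()` isolates it behind one
function, and a sum-over-roosts variant (`sumOverRoosts = TRUE`) is
available for sensitivity analysis where colonies are close together.
Nearest-roost distance is the default reading; $A$ and $\lambda$ are fixed
a priori, not estimated from the data.

The correction is validated by construction: the synthetic generator
injects the same plume multiplicatively into presence probabilities, and
correcting with matched $(A, \lambda)$ must leave no residual association
between corrected rates and $e^{-d/\lambda}$. The test suite checks the
regression slope's $|t| < 2$ on a 1000-pixel landscape. Since $t$ is
(asymptotically) standard normal once the trend is fully removed, any
single seed has roughly a 5% chance of exceeding 2 even under a perfect
correction; the suite uses a fixed seed, and the acceptance script
additionally reports the slope-reduction percentage, which concentrates
near 100% regardless of seed.

## Land-cover harmonization and area-weighted statistics

Two sources are merged into 13 classes nested in 4 broad types
(agricultural, natural, urban/other, water): a natural-vegetation raster
and a crop-parcel layer with field boundaries. Crop labels win wherever a
crop parcel exists; natural-layer pixels labeled generic agriculture with
no crop parcel become *miscellaneous* (field margins, fallowed ground).
The raw-label mapping ships as an editable TSV
(`inst/extdata/class_mapping.tsv`) rather than hard-coded, because source
vocabularies differ between deployments; the class-to-type nesting is
fixed.

Pixels are assigned to the parcel containing their center — reproducible
and order-independent; exact area-fraction overlap would change results by
less than a pixel width and is not implemented. Each parcel's mean rate is
the mean of its unmasked pixels; a fully masked parcel is recorded missing
and excluded. The class mean is the area-weighted mean over parcels,

$$\bar{R}_c = \frac{\sum_{i \in c} a_i \bar{r}_i}{\sum_{i \in c} a_i},$$

and the study-wide mean is computed identically over all parcels, which
makes it algebraically equal to total occurrences / (total area × nights)
when no pixels are masked — a consistency the tests assert to $10^{-9}$
relative tolerance.

### Confidence intervals

Parcels, not pixels, are the independent units (pixels within a field
share management, flooding and prey conditions), so uncertainty comes from
a seeded bootstrap that resamples parcels with replacement and recomputes
the area-weighted mean on each resample (1000 resamples by default).
Resampling uniformly and re-weighting by area is deliberate;
sampling *proportional to* area and also weighting by area would count
large parcels twice.

The interval itself is the bootstrap standard error with a Student-t
quantile at the Kish effective sample size of the area weights,
$n_\mathrm{eff} = (\sum a_i)^2 / \sum a_i^2$. We first implemented the
plain percentile interval and measured its calibration on synthetic
landscapes with known class means: coverage ran at 92–93% for a nominal
95% interval. The mechanism is the weights: parcel areas from a realistic
tessellation are strongly skewed, $n_\mathrm{eff}$ was ~61 where there
were 160 parcels, and percentile intervals are systematically narrow at
small effective sample sizes. The effective-df t interval measured 94%
under identical conditions and is the default; `ciMethod = "percentile"`
restores the plain percentile interval. The calibration experiment (500
seeded replicates of a 48×48-pixel two-class landscape, 160 parcels, 120
scans over 5 nights) is frozen in the acceptance tests. Classes with a
single parcel report a mean with an undefined CI.

`rankAndRatios()` orders classes by unrounded means (ties alphabetical)
and reports each class's ratio to the study-wide mean and the top class's
ratio to the runner-up — the "rice is 1.5× the next class" form of
statement.

## The mosquito-abundance proxy

Flying insect prey density is unobservable wall-to-wall, but mosquito
abundance is strongly temperature-driven and has been modeled and
field-validated in comparable irrigated landscapes; other soft-bodied
aerial taxa in bat diets (midges, moths, flies) follow similar thermal
responses. We therefore compute a *relative* abundance index from
trait-based thermal performance curves:

$$M(T) = \frac{\mathrm{EFD}(T)\,\mathrm{pEA}(T)\,\mathrm{MDR}(T)}
             {\max(\mu(T), \mu_\mathrm{floor})^2}$$

with eggs per female per day (EFD), egg-to-adult survival (pEA),
development rate (MDR, day$^{-1}$) and adult mortality
$\mu = 1/\mathrm{lifespan}$ (day$^{-1}$). Each trait is a Briere curve
$cT(T - T_\mathrm{min})\sqrt{T_\mathrm{max} - T}$ or a quadratic
$c(T - T_\mathrm{min})(T_\mathrm{max} - T)$, exactly zero outside
$[T_\mathrm{min}, T_\mathrm{max}]$, so $M$ vanishes outside the
intersection of the trait supports and is zero whenever any numerator
trait is zero. The $\mu$ floor (default 0.01 day$^{-1}$, configurable)
keeps the index finite where the lifespan curve approaches its thermal
limits. Parameters ship as an editable TSV in the style of published
*Culex tarsalis* fits; the package validates structure (one curve per
trait, $T_\mathrm{min} < T_\mathrm{max}$, $c > 0$), not values.

$M$ is unitless and only defined up to monotone rescaling — the downstream
model uses it inside a spline smooth, which is invariant to that — so no
calibration against trap counts is attempted here. `abundanceRaster()`
averages $M(T_t)$ per pixel over the seasonal temperature stack; missing
temperatures propagate.

## The association model

All layers are aggregated to coarse cells (default 14 base pixels = 980 m,
the closest integer-block approximation to 1 km at 70 m resolution, chosen
because mosquitoes disperse on the order of a kilometer) by the mean over
unmasked base pixels, with the modal land-cover class by area (ties
alphabetical) and cell centroids as coordinates. Cells under 50% unmasked
area are dropped and counted. The model is a Gaussian GAM on the raw rate
scale:

```
activity ~ s(mosquito, bs = "cr", k = 10) + lights + irrigated_ha
           + class + s(x, y, bs = "gp", k = 50)
```

a cubic regression spline for the prey effect (nonlinearity allowed,
monotonicity not imposed), linear nighttime-lights and irrigated-area
controls, a land-cover factor with a declared reference class (default
*miscellaneous*; always recorded in the output since every class estimate
is a contrast against it), and an isotropic Gaussian-process smooth over
the cell coordinates for residual spatial autocorrelation, fitted by REML
via mgcv. Basis dimensions are defaults, not estimates; both are exposed
and should be halved/doubled as a sensitivity check. Classes with fewer
than two cells are dropped with a warning rather than fitted as
zero-variance contrasts. Parametric-term CIs are Wald 95% intervals;
smooth terms report effective degrees of freedom and approximate p-values,
which are known to be mildly liberal — the suite measures the null
rejection rate of the mosquito smooth at $\alpha = 0.05$ over 50 seeded
null simulations ($n = 2000$ each) and requires it to stay at or below 10%.

## What the synthetic generator emulates — and what it does not

`landscapeConfig()` defaults encode the study season: 152 nights × 126
scans per night on a 70 m grid, 8 roosts, a commute plume with $A = 1$,
$\lambda = 5000$ m, and a baseline detection rate $r = 0.06$ chosen so the
corrected landscape mean lands in the mid-teens of occurrences
ha$^{-1}$ night$^{-1}$. Class foraging weights put rice highest (1.8× the
all-class mean scale), water/wetland below average and shrub/desert
lowest, mirroring the qualitative contrasts the pipeline is meant to
detect. The spatial window defaults to 120×100 pixels (8.4 × 7 km): large
enough to contain the plume and a realistic parcel mosaic, small enough
that a full season simulates in seconds.

The generator draws each pixel independently per scan as Bernoulli with
probability $\min\{1, r\,w(\mathrm{class})(1 + A e^{-d/\lambda})\}$, on a
Voronoi patch mosaic so parcel extraction sees contiguous fields.
Temperature is a west–east gradient plus a seasonal sinusoid and pixel
noise, clipped to configured bounds; lights are elevated over urban
pixels, irrigated fraction over agricultural classes. All randomness flows
from one integer seed through fixed per-night/per-stage sub-seeds, so any
slice of a run is reproducible independently.

Real radar data violate these assumptions in ways the generator does not
emulate: detections are spatially and temporally autocorrelated within a
night (a group of bats spans many pixels and minutes), detection
probability decays with range from the radar, classifier errors are
structured (clutter, precipitation), and land-cover classes are spatially
organized rather than randomly assigned to patches. Passing tests
therefore demonstrate that the *arithmetic and inference machinery* is
correct under the stated generative model — not that the upstream
classifier is accurate, nor that the effect sizes the generator uses are
the field's.

## Numerical and scale choices

* Probabilities are clipped at 1 silently; a configuration whose unclipped
  maximum exceeds 5 warns about a saturated, degenerate regime.
* Distances are exact Euclidean pixel-center distances; no spatial index is
  needed at these problem sizes.
* `blockAggregate()` drops trailing rows/columns that do not fill a
  complete cell; at default sizes that is at most 13 of 120 columns.
* Test and acceptance problem sizes (48×48 to 120×100 grids, 120–19,152
  scans, 500 calibration replicates, 50 null GAM fits at $n = 2000$) were
  chosen as the smallest sizes at which the asymptotics the checks rely on
  are comfortably in force.
* Ties in modal-class and ranking computations break alphabetically,
  making every report order-deterministic.
* Pipeline outputs are plain text (ESRI ASCII grids, TSV, JSON) and the
  manifest stores an MD5 checksum per file; identical configuration and
  seed reproduce identical checksums end to end.

## Known limitations

Whole-season aggregation only (no nightly or weekly surfaces); $A$ and
$\lambda$ are assumed, not estimated, and misspecifying them leaves a
residual roost trend with the same sign as the misspecification; the
abundance index is relative, so only shape — not magnitude — of the
prey–activity relationship is interpretable; and the GAM is associative,
with no causal claim: bats may forage where prey are, or both may track a
third gradient the controls miss.
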