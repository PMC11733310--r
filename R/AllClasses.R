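#' @import methods
NULL

## ---------------------------------------------------------------------------
## Grid containers
##
## All gridded layers share one geometry convention: a regular grid of square
## pixels in a projected coordinate system (meters). Matrices are stored with
## row 1 = northernmost row; pixel (r, c) has its center at
##   x = xll + (c - 0.5) * pixelSize
##   y = yll + (nrow - r + 0.5) * pixelSize
## where (xll, yll) is the lower-left corner of the grid.
## ---------------------------------------------------------------------------

#' GridRaster: a single-band georeferenced raster
#'
#' Lightweight container for one band of gridded values on a regular square
#' grid in projected coordinates. `NA` encodes masked / missing pixels and is
#' excluded from all downstream statistics (never treated as zero).
#'
#' @slot values numeric matrix of pixel values (row 1 = north).
#' @slot pixelSize pixel edge length in meters.
#' @slot xll,yll projected coordinates (m) of the grid's lower-left corner.
#' @exportClass GridRaster
setClass("GridRaster",
  representation(values = "matrix", pixelSize = "numeric",
                 xll = "numeric", yll = "numeric"),
  prototype(pixelSize = 70, xll = 0, yll = 0))

setValidity("GridRaster", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (meters)")
  if (length(object@xll) != 1L || length(object@yll) != 1L ||
      !is.finite(object@xll) || !is.finite(object@yll))
    msg <- c(msg, "'xll' and 'yll' must be single finite numbers")
  if (length(msg)) msg else TRUE
})

#' PresenceScene: one radar scan's binary bat detections
#'
#' A single radar scan classified into binary bat presence/absence on the
#' analysis grid. Values are strictly 0/1 (no missing values at scene level;
#' coverage masking is applied to the aggregated raster).
#'
#' @slot timestamp free-form scan identifier (e.g. "night012_scan005").
#' @exportClass PresenceScene
setClass("PresenceScene", contains = "GridRaster",
  representation(timestamp = "character"),
  prototype(timestamp = ""))

setValidity("PresenceScene", function(object) {
  v <- object@values
  if (anyNA(v) || !all(v == 0 | v == 1))
    return("scene values must be strictly binary (0/1), no NA")
  TRUE
})

#' ActivityRaster: seasonal per-pixel occurrence counts
#'
#' Aggregated bat-presence counts over a season: each pixel holds the number
#' of scans in which bats were detected there. Convertible to the
#' standardized rate unit occurrences per hectare per night with [toRate()].
#' `NA` pixels are masked (outside coverage / clutter) and excluded from all
#' statistics.
#'
#' @slot nNights number of nights aggregated over.
#' @slot nScenes total number of scans aggregated.
#' @exportClass ActivityRaster
setClass("ActivityRaster", contains = "GridRaster",
  representation(nNights = "integer", nScenes = "integer"),
  prototype(nNights = 1L, nScenes = 1L))

setValidity("ActivityRaster", function(object) {
  msg <- character()
  v <- object@values
  ok <- !is.na(v)
  if (any(v[ok] < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(v[ok] != round(v[ok])))
    msg <- c(msg, "counts must be integers")
  if (object@nNights < 1L) msg <- c(msg, "'nNights' must be >= 1")
  if (object@nScenes < 1L) msg <- c(msg, "'nScenes' must be >= 1")
  if (any(v[ok] > object@nScenes))
    msg <- c(msg, "no pixel count may exceed the number of scenes")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Land cover
## ---------------------------------------------------------------------------

#' The 13 harmonized land-cover classes and their 4 broad types
#'
#' Harmonized vocabulary nesting 13 classes within 4 types (agricultural,
#' natural, urban/other, water).
#'
#' @export
landCoverClasses <- function() {
  c("barren/other"          = "urban/other",
    "conifer"               = "natural",
    "desert"                = "natural",
    "fruits/nuts/vineyards" = "agricultural",
    "grassland"             = "natural",
    "hardwood"              = "natural",
    "herbaceous"            = "natural",
    "rice"                  = "agricultural",
    "row/field crops"       = "agricultural",
    "shrub"                 = "natural",
    "water/wetland"         = "water",
    "urban"                 = "urban/other",
    "miscellaneous"         = "agricultural")
}

#' LandCoverLayer: harmonized parcels labeled with 13 classes in 4 types
#'
#' Rasterized land-cover layer in which every pixel belongs to exactly one
#' parcel (a contiguous field or patch) and every parcel carries one of the
#' 13 harmonized classes, each nested in one of 4 broad types. The parcel
#' table is the vector (per-field) view; `classOf`/`parcelOf` matrices are
#' the co-registered raster view.
#'
#' @slot classOf integer matrix; index into `levels` per pixel.
#' @slot parcelOf integer matrix; parcel id per pixel (matches `parcels$parcel_id`).
#' @slot levels character vector of class names in use.
#' @slot parcels data.frame with columns parcel_id, class, type, area_ha.
#' @slot pixelSize,xll,yll grid geometry as for [GridRaster-class].
#' @exportClass LandCoverLayer
setClass("LandCoverLayer",
  representation(classOf = "matrix", parcelOf = "matrix",
                 levels = "character", parcels = "data.frame",
                 pixelSize = "numeric", xll = "numeric", yll = "numeric"),
  prototype(pixelSize = 70, xll = 0, yll = 0))

setValidity("LandCoverLayer", function(object) {
  msg <- character()
  vocab <- names(landCoverClasses())
  if (!all(object@levels %in% vocab))
    msg <- c(msg, paste0("unknown land-cover class(es): ",
                         paste(setdiff(object@levels, vocab), collapse = ", ")))
  if (!identical(dim(object@classOf), dim(object@parcelOf)))
    msg <- c(msg, "'classOf' and 'parcelOf' must share dimensions")
  idx <- object@classOf
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(object@levels)))
    msg <- c(msg, "every pixel must carry a valid class index")
  need <- c("parcel_id", "class", "type", "area_ha")
  if (!all(need %in% names(object@parcels)))
    msg <- c(msg, "parcel table must have parcel_id, class, type, area_ha")
  else {
    if (any(object@parcels$area_ha <= 0))
      msg <- c(msg, "parcel areas must be positive")
    want <- landCoverClasses()[object@parcels$class]
    if (anyNA(want) || !identical(unname(want), object@parcels$type))
      msg <- c(msg, "each parcel's type must match the class->type mapping")
  }
  if (length(msg)) msg else TRUE
})

#' RoostSet: known bat colony locations
#'
#' Point locations of known roosts (colonies) in projected meters, with an
#' optional per-roost weight (unused by the nearest-roost distance but kept
#' for sensitivity variants).
#'
#' @slot coords numeric matrix, n x 2 (x, y in meters).
#' @slot weights numeric vector of per-roost weights.
#' @exportClass RoostSet
setClass("RoostSet",
  representation(coords = "matrix", weights = "numeric"))

setValidity("RoostSet", function(object) {
  if (nrow(object@coords) < 1L) return("at least one roost is required")
  if (ncol(object@coords) != 2L) return("'coords' must be an n x 2 matrix")
  if (!all(is.finite(object@coords))) return("roost coordinates must be finite")
  if (length(object@weights) != nrow(object@coords))
    return("'weights' length must equal the number of roosts")
  if (any(object@weights < 0)) return("roost weights must be >= 0")
  TRUE
})

#' DecayParams: exponential roost-distance decay parameters
#'
#' Parameters of the multiplicative roost-commute correction
#' \eqn{f(d) = 1 / (1 + A e^{-d/\lambda})}: `amplitude` A (dimensionless,
#' >= 0) sets how strongly pixels at a roost are down-weighted
#' (factor 1/(1+A) at d = 0); `scale` lambda (meters, > 0) is the e-folding
#' distance of the commute plume.
#'
#' @slot amplitude dimensionless amplitude A >= 0.
#' @slot scale decay scale lambda in meters, > 0.
#' @exportClass DecayParams
setClass("DecayParams",
  representation(amplitude = "numeric", scale = "numeric"),
  prototype(amplitude = 1, scale = 5000))

setValidity("DecayParams", function(object) {
  if (length(object@amplitude) != 1L || !is.finite(object@amplitude) ||
      object@amplitude < 0)
    return("'amplitude' must be a single number >= 0")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    return("'scale' must be a single positive number (meters)")
  TRUE
})

## ---------------------------------------------------------------------------
## Thermal performance curves
## ---------------------------------------------------------------------------

#' TraitCurve: one thermal performance curve
#'
#' A unimodal trait-versus-temperature function, zero outside its thermal
#' limits. Two forms are supported: Briere, \eqn{c T (T - Tmin) \sqrt{Tmax - T}},
#' and quadratic, \eqn{c (T - Tmin)(Tmax - T)}; a constant form is allowed
#' for degenerate/testing use.
#'
#' @slot trait trait name, e.g. "EFD", "pEA", "MDR", "lf", "mu".
#' @slot form one of "briere", "quadratic", "constant".
#' @slot c scale constant (trait-specific units), > 0.
#' @slot Tmin,Tmax critical thermal minimum / maximum, degrees C (Tmin < Tmax).
#' @exportClass TraitCurve
setClass("TraitCurve",
  representation(trait = "character", form = "character", c = "numeric",
                 Tmin = "numeric", Tmax = "numeric"))

setValidity("TraitCurve", function(object) {
  msg <- character()
  if (!object@form %in% c("briere", "quadratic", "constant"))
    msg <- c(msg, "'form' must be 'briere', 'quadratic' or 'constant'")
  if (object@c <= 0) msg <- c(msg, "'c' must be > 0")
  if (object@form != "constant" && !(object@Tmin < object@Tmax))
    msg <- c(msg, "'Tmin' must be < 'Tmax'")
  if (length(msg)) msg else TRUE
})

#' AbundanceParams: trait curves composing the relative abundance index
#'
#' The set of trait curves entering the relative mosquito-abundance index
#' M(T) = EFD(T) pEA(T) MDR(T) / max(mu(T), floor)^2, plus the mortality
#' floor (day^-1) preventing division blow-up where the lifespan curve
#' approaches its thermal limits. Mortality may be supplied directly as a
#' "mu" curve or derived as 1/lifespan from an "lf" curve.
#'
#' @slot curves named list of [TraitCurve-class] (names EFD, pEA, MDR, and mu or lf).
#' @slot muFloor mortality-rate floor, day^-1, > 0.
#' @exportClass AbundanceParams
setClass("AbundanceParams",
  representation(curves = "list", muFloor = "numeric"),
  prototype(muFloor = 0.01))

setValidity("AbundanceParams", function(object) {
  msg <- character()
  nm <- names(object@curves)
  need <- c("EFD", "pEA", "MDR")
  if (!all(need %in% nm))
    msg <- c(msg, paste0("missing trait curve(s): ",
                         paste(setdiff(need, nm), collapse = ", ")))
  if (!any(c("mu", "lf") %in% nm))
    msg <- c(msg, "a mortality curve is required ('mu' or 'lf')")
  if (anyDuplicated(nm))
    msg <- c(msg, "each trait may appear exactly once")
  if (!all(vapply(object@curves, is, logical(1), "TraitCurve")))
    msg <- c(msg, "all elements of 'curves' must be TraitCurve objects")
  if (object@muFloor <= 0) msg <- c(msg, "'muFloor' must be > 0 (day^-1)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GAM result
## ---------------------------------------------------------------------------

#' GAMResult: fitted bat-activity association model
#'
#' Result container for the spatial generalized additive model of bat
#' activity on modeled mosquito abundance (smooth), nighttime lights,
#' irrigated area, land-cover class, and an isotropic spatial smooth.
#'
#' @slot terms data.frame of parametric terms: term, estimate, ci_lo, ci_hi, p.
#' @slot smooths data.frame of smooth terms: term, edf, p.
#' @slot r2 adjusted R-squared.
#' @slot n number of observations fitted.
#' @slot referenceClass the land-cover class absorbed into the intercept.
#' @slot fit the underlying [mgcv::gam] object.
#' @exportClass GAMResult
setClass("GAMResult",
  representation(terms = "data.frame", smooths = "data.frame",
                 r2 = "numeric", n = "integer",
                 referenceClass = "character", fit = "ANY"))

setValidity("GAMResult", function(object) {
  tt <- object@terms
  if (!all(c("term", "estimate", "ci_lo", "ci_hi", "p") %in% names(tt)))
    return("terms table must have term, estimate, ci_lo, ci_hi, p")
  bad <- tt$estimate < tt$ci_lo - 1e-9 | tt$estimate > tt$ci_hi + 1e-9
  if (any(bad)) return("every CI must contain its estimate")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic landscape configuration
## ---------------------------------------------------------------------------

#' LandscapeConfig: full specification of a synthetic study landscape
#'
#' All parameters of the synthetic-data generator. Defaults mirror the study
#' season (152 nights, 126 scans per night, 70 m pixels, 8 roosts, rice
#' foraging intensity elevated about two-fold) on a desk-scale spatial
#' window. See [landscapeConfig()] for construction with defaults.
#'
#' @slot gridWidth,gridHeight grid size in pixels.
#' @slot pixelSize pixel edge, meters.
#' @slot nNights number of nights in the season.
#' @slot scansPerNight radar scans per night.
#' @slot classWeights named numeric; relative foraging intensity per class (>= 0).
#' @slot nPatches number of contiguous landscape patches (Voronoi cells).
#' @slot roosts n x 2 matrix of roost coordinates (m).
#' @slot amplitude,scale commute-plume amplitude A_sim and e-folding scale
#'   lambda_sim (m) injected into presence probabilities.
#' @slot detectionRate baseline per-scan per-pixel presence probability scale r.
#' @slot seed integer RNG seed; identical config + seed gives bit-identical output.
#' @slot nTimeSteps temperature stack depth (seasonal steps).
#' @slot tBase,tGradient,tSeasonal,tNoise,tLo,tHi temperature-field parameters
#'   (degrees C): west-east mean, spatial gradient span, seasonal sinusoid
#'   amplitude, pixel noise SD, and clipping bounds.
#' @exportClass LandscapeConfig
setClass("LandscapeConfig",
  representation(gridWidth = "integer", gridHeight = "integer",
                 pixelSize = "numeric",
                 nNights = "integer", scansPerNight = "integer",
                 classWeights = "numeric", nPatches = "integer",
                 roosts = "matrix",
                 amplitude = "numeric", scale = "numeric",
                 detectionRate = "numeric", seed = "integer",
                 nTimeSteps = "integer",
                 tBase = "numeric", tGradient = "numeric",
                 tSeasonal = "numeric", tNoise = "numeric",
                 tLo = "numeric", tHi = "numeric"))

setValidity("LandscapeConfig", function(object) {
  msg <- character()
  if (object@gridWidth < 1L || object@gridHeight < 1L)
    msg <- c(msg, "grid dimensions must be >= 1")
  if (object@nNights < 1L) msg <- c(msg, "'nNights' must be >= 1")
  if (object@scansPerNight < 1L) msg <- c(msg, "'scansPerNight' must be >= 1")
  w <- object@classWeights
  if (is.null(names(w)) || any(!nzchar(names(w))))
    msg <- c(msg, "'classWeights' must be a named vector")
  else if (!all(names(w) %in% names(landCoverClasses())))
    msg <- c(msg, paste0("unknown class name(s) in 'classWeights': ",
                         paste(setdiff(names(w), names(landCoverClasses())),
                               collapse = ", ")))
  if (any(w < 0)) msg <- c(msg, "all class weights must be >= 0")
  if (!any(w > 0)) msg <- c(msg, "at least one class weight must be > 0")
  if (object@amplitude < 0) msg <- c(msg, "'amplitude' must be >= 0")
  if (object@scale <= 0) msg <- c(msg, "'scale' must be > 0 (meters)")
  if (object@detectionRate < 0 || object@detectionRate > 1)
    msg <- c(msg, "'detectionRate' must be in [0, 1]")
  if (ncol(object@roosts) != 2L || nrow(object@roosts) < 1L)
    msg <- c(msg, "'roosts' must be an n x 2 coordinate matrix")
  if (!(object@tLo < object@tHi))
    msg <- c(msg, "'tLo' must be < 'tHi'")
  if (length(msg)) msg else TRUE
})
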