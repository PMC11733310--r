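#' @include AllClasses.R
NULL

#' Pixel values of a gridded layer
#' @param x a grid object.
#' @return the numeric matrix of pixel values (row 1 = north).
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Pixel edge length in meters
#' @param x a grid object.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Pixel area in hectares
#'
#' For a pixel of edge `e` meters the area is `(e / 100)^2` hectares; a 70 m
#' pixel is 0.49 ha.
#' @param x a grid object.
#' @export
setGeneric("pixelAreaHa", function(x) standardGeneric("pixelAreaHa"))

#' Number of nights an activity raster aggregates over
#' @param x an [ActivityRaster-class].
#' @export
setGeneric("nNights", function(x) standardGeneric("nNights"))

#' Total number of scans an activity raster aggregates over
#' @param x an [ActivityRaster-class].
#' @export
setGeneric("nScenes", function(x) standardGeneric("nScenes"))

#' Parcel table of a land-cover layer
#' @param x a [LandCoverLayer-class].
#' @return data.frame with parcel_id, class, type, area_ha.
#' @export
setGeneric("parcels", function(x) standardGeneric("parcels"))

#' Per-pixel class labels of a land-cover layer
#' @param x a [LandCoverLayer-class].
#' @return character matrix of class names, co-registered with the grid.
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))

#' Roost coordinate matrix
#' @param x a [RoostSet-class].
#' @export
setGeneric("roostCoords", function(x) standardGeneric("roostCoords"))

#' Evaluate a thermal performance curve
#' @param curve a [TraitCurve-class].
#' @param temp temperatures, degrees C (vectorized).
#' @return trait values, >= 0, exactly 0 outside `[Tmin, Tmax]` for the
#'   briere and quadratic forms.
#' @export
setGeneric("evalCurve", function(curve, temp) standardGeneric("evalCurve"))

#' Parametric-term table of a fitted association model
#' @param x a [GAMResult-class].
#' @export
setGeneric("modelTerms", function(x) standardGeneric("modelTerms"))

#' Smooth-term table of a fitted association model
#' @param x a [GAMResult-class].
#' @export
setGeneric("modelSmooths", function(x) standardGeneric("modelSmooths"))
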