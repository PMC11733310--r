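#' @include AllGenerics.R
NULL

#' @rdname gridValues
#' @aliases gridValues,GridRaster-method
setMethod("gridValues", "GridRaster", function(x) x@values)

#' @rdname pixelSize
#' @aliases pixelSize,GridRaster-method
setMethod("pixelSize", "GridRaster", function(x) x@pixelSize)

#' @rdname pixelSize
#' @aliases pixelSize,LandCoverLayer-method
setMethod("pixelSize", "LandCoverLayer", function(x) x@pixelSize)

#' @rdname pixelAreaHa
#' @aliases pixelAreaHa,GridRaster-method
setMethod("pixelAreaHa", "GridRaster", function(x) (x@pixelSize / 100)^2)

#' @rdname pixelAreaHa
#' @aliases pixelAreaHa,LandCoverLayer-method
setMethod("pixelAreaHa", "LandCoverLayer", function(x) (x@pixelSize / 100)^2)

#' @rdname nNights
#' @aliases nNights,ActivityRaster-method
setMethod("nNights", "ActivityRaster", function(x) x@nNights)

#' @rdname nScenes
#' @aliases nScenes,ActivityRaster-method
setMethod("nScenes", "ActivityRaster", function(x) x@nScenes)

#' @rdname parcels
#' @aliases parcels,LandCoverLayer-method
setMethod("parcels", "LandCoverLayer", function(x) x@parcels)

#' @rdname classMap
#' @aliases classMap,LandCoverLayer-method
setMethod("classMap", "LandCoverLayer", function(x) {
  m <- matrix(x@levels[x@classOf], nrow = nrow(x@classOf))
  m
})

#' @rdname roostCoords
#' @aliases roostCoords,RoostSet-method
setMethod("roostCoords", "RoostSet", function(x) x@coords)

#' @rdname modelTerms
#' @aliases modelTerms,GAMResult-method
setMethod("modelTerms", "GAMResult", function(x) x@terms)

#' @rdname modelSmooths
#' @aliases modelSmooths,GAMResult-method
setMethod("modelSmooths", "GAMResult", function(x) x@smooths)

setMethod("dim", "GridRaster", function(x) dim(x@values))
setMethod("dim", "LandCoverLayer", function(x) dim(x@classOf))

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d pixels @ %g m (%.2f ha/pixel)\n",
              class(object), nrow(v), ncol(v), object@pixelSize,
              (object@pixelSize / 100)^2))
  ok <- !is.na(v)
  cat(sprintf("  values: min %.4g, max %.4g; %d masked pixel(s)\n",
              suppressWarnings(min(v[ok])), suppressWarnings(max(v[ok])),
              sum(!ok)))
  invisible(NULL)
})

setMethod("show", "ActivityRaster", function(object) {
  callNextMethod()
  cat(sprintf("  season: %d nights, %d scans\n",
              object@nNights, object@nScenes))
  invisible(NULL)
})

setMethod("show", "LandCoverLayer", function(object) {
  cat(sprintf("LandCoverLayer: %d x %d pixels @ %g m, %d parcels, %d classes\n",
              nrow(object@classOf), ncol(object@classOf), object@pixelSize,
              nrow(object@parcels), length(unique(object@parcels$class))))
  tab <- sort(tapply(object@parcels$area_ha, object@parcels$class, sum),
              decreasing = TRUE)
  cat("  area (ha) by class:\n")
  for (nm in names(tab)) cat(sprintf("    %-22s %10.1f\n", nm, tab[[nm]]))
  invisible(NULL)
})

setMethod("show", "RoostSet", function(object) {
  cat(sprintf("RoostSet: %d roost(s)\n", nrow(object@coords)))
  invisible(NULL)
})

setMethod("show", "DecayParams", function(object) {
  cat(sprintf("DecayParams: amplitude A = %g, scale lambda = %g m\n",
              object@amplitude, object@scale))
  cat(sprintf("  factor at d = 0: %.4f; at d = lambda: %.4f\n",
              1 / (1 + object@amplitude),
              1 / (1 + object@amplitude * exp(-1))))
  invisible(NULL)
})

setMethod("show", "TraitCurve", function(object) {
  if (object@form == "constant")
    cat(sprintf("TraitCurve '%s': constant %g\n", object@trait, object@c))
  else
    cat(sprintf("TraitCurve '%s': %s, c = %g, Tmin = %g, Tmax = %g degC\n",
                object@trait, object@form, object@c, object@Tmin, object@Tmax))
  invisible(NULL)
})

setMethod("show", "AbundanceParams", function(object) {
  cat(sprintf("AbundanceParams: %d trait curve(s), mortality floor %g /day\n",
              length(object@curves), object@muFloor))
  for (cu in object@curves) show(cu)
  invisible(NULL)
})

setMethod("show", "GAMResult", function(object) {
  cat(sprintf("GAMResult: n = %d, adjusted R-squared = %.3f (reference class: %s)\n",
              object@n, object@r2, object@referenceClass))
  cat("Parametric terms:\n")
  print(object@terms, row.names = FALSE, digits = 4)
  cat("Smooth terms:\n")
  print(object@smooths, row.names = FALSE, digits = 4)
  invisible(NULL)
})

setMethod("show", "LandscapeConfig", function(object) {
  cat(sprintf(paste0("LandscapeConfig: %d x %d px @ %g m, %d nights x %d ",
                     "scans, %d roosts, seed %d\n"),
              object@gridWidth, object@gridHeight, object@pixelSize,
              object@nNights, object@scansPerNight, nrow(object@roosts),
              object@seed))
  cat(sprintf("  commute plume: A = %g, lambda = %g m; detection rate r = %g\n",
              object@amplitude, object@scale, object@detectionRate))
  invisible(NULL)
})
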