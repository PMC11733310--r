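#' @include grid-utils.R
NULL

#' Distance from each pixel center to the nearest roost
#'
#' Euclidean distance in projected meters from every pixel center to its
#' nearest roost point.
#'
#' @param nr,nc grid dimensions (rows, columns).
#' @param roosts a [RoostSet-class].
#' @param pixelSize pixel edge, meters.
#' @param xll,yll grid lower-left corner, meters.
#' @return numeric matrix of distances (m), co-registered with the grid.
#' @export
distanceToNearestRoost <- function(nr, nc, roosts, pixelSize = 70,
                                   xll = 0, yll = 0) {
  stopifnot(is(roosts, "RoostSet"))
  ctr <- pixelCenters(nr, nc, pixelSize, xll, yll)
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(roosts@coords))) {
    dx <- ctr$x - roosts@coords[k, 1]
    dy <- ctr$y - roosts@coords[k, 2]
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Roost-commute correction factor
#'
#' Multiplicative factor \eqn{f(d) = 1 / (1 + A e^{-d/\lambda})} removing the
#' inflation of detections near roosts caused by departing and returning
#' (rather than foraging) bats. The factor is 1/(1+A) at a roost, strictly
#' increasing with distance, and approaches 1 far from any roost, so
#' distant pixels are untouched.
#'
#' @param d distance(s) to the nearest roost, meters, >= 0 (vectorized).
#' @param params a [DecayParams-class] (amplitude A, scale lambda).
#' @return factor(s) in (0, 1].
#' @examples
#' p <- decayParams(amplitude = 1, scale = 5000)
#' correctionFactor(0, p)     # 0.5
#' correctionFactor(5000, p)  # 1 / (1 + exp(-1)) ~= 0.7311
#' @export
correctionFactor <- function(d, params) {
  stopifnot(is(params, "DecayParams"))
  if (any(d < 0, na.rm = TRUE))
    stop("distances must be >= 0", call. = FALSE)
  1 / (1 + params@amplitude * exp(-d / params@scale))
}

#' Construct DecayParams
#'
#' @param amplitude commute-plume amplitude A (dimensionless, >= 0); default 1.
#' @param scale e-folding distance lambda in meters (> 0); default 5000 m,
#'   the order of a nightly commute radius.
#' @return a [DecayParams-class].
#' @export
decayParams <- function(amplitude = 1, scale = 5000) {
  new("DecayParams", amplitude = amplitude, scale = scale)
}

#' Apply the roost-distance correction to an activity surface
#'
#' Multiplies each pixel by [correctionFactor()] evaluated at its distance
#' to the nearest roost. Works on counts or rates; masked pixels stay
#' masked. With `sumOverRoosts = TRUE` the plume term is summed over all
#' roosts, \eqn{1/(1 + A \sum_k e^{-d_k/\lambda})}, a sensitivity variant for
#' pixels near several colonies.
#'
#' @param raster an [ActivityRaster-class] or [GridRaster-class].
#' @param roosts a [RoostSet-class] in the same coordinate system.
#' @param params a [DecayParams-class].
#' @param sumOverRoosts use the sum-over-roosts plume instead of
#'   nearest-roost distance (default FALSE).
#' @return a [GridRaster-class] of corrected values.
#' @export
correctActivity <- function(raster, roosts, params,
                            sumOverRoosts = FALSE) {
  stopifnot(isS4(raster), is(roosts, "RoostSet"), is(params, "DecayParams"))
  nr <- nrow(raster@values); nc <- ncol(raster@values)
  ctr <- pixelCenters(nr, nc, raster@pixelSize, raster@xll, raster@yll)
  pad <- 10 * raster@pixelSize * max(nr, nc)  # allow roosts well off-grid
  lo <- c(min(ctr$x), min(ctr$y)) - pad
  hi <- c(max(ctr$x), max(ctr$y)) + pad
  rc <- roosts@coords
  if (any(rc[, 1] < lo[1] | rc[, 1] > hi[1] |
          rc[, 2] < lo[2] | rc[, 2] > hi[2]))
    stop("roost coordinates are wildly outside the raster extent; ",
         "coordinate systems likely differ", call. = FALSE)
  if (sumOverRoosts) {
    plume <- matrix(0, nr, nc)
    for (k in seq_len(nrow(rc))) {
      dx <- ctr$x - rc[k, 1]; dy <- ctr$y - rc[k, 2]
      plume <- plume + exp(-sqrt(dx * dx + dy * dy) / params@scale)
    }
    fac <- 1 / (1 + params@amplitude * plume)
  } else {
    d <- distanceToNearestRoost(nr, nc, roosts, raster@pixelSize,
                                raster@xll, raster@yll)
    fac <- correctionFactor(d, params)
  }
  gridRaster(raster@values * fac, pixelSize = raster@pixelSize,
             xll = raster@xll, yll = raster@yll)
}
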