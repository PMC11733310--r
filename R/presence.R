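#' @include grid-utils.R
NULL

#' Aggregate per-scan presence scenes into a seasonal activity raster
#'
#' Collapses a stack of binary radar scenes into per-pixel occurrence
#' counts: a pixel in which bats were detected in five scans receives the
#' value five. The number of scenes and nights is recorded so the counts
#' can later be normalized to occurrences per hectare per night.
#'
#' @param scenes list of [PresenceScene-class], all on the same grid.
#' @param nNights number of nights the scenes span.
#' @return an [ActivityRaster-class] of counts.
#' @examples
#' sc <- replicate(5, presenceScene(matrix(1, 2, 2)), simplify = FALSE)
#' gridValues(aggregateScenes(sc, nNights = 1))  # all pixels count 5
#' @export
aggregateScenes <- function(scenes, nNights) {
  if (length(scenes) < 1L) stop("at least one scene is required", call. = FALSE)
  ref <- scenes[[1L]]
  acc <- matrix(0, nrow(ref@values), ncol(ref@values))
  for (k in seq_along(scenes)) {
    s <- scenes[[k]]
    if (!identical(dim(s@values), dim(acc)))
      stop(sprintf("scene %d ('%s') has mismatched shape %dx%d (expected %dx%d)",
                   k, s@timestamp, nrow(s@values), ncol(s@values),
                   nrow(acc), ncol(acc)), call. = FALSE)
    acc <- acc + s@values
  }
  activityRaster(acc, nNights = nNights, nScenes = length(scenes),
                 pixelSize = ref@pixelSize, xll = ref@xll, yll = ref@yll)
}

#' Convert occurrence counts to occurrences per hectare per night
#'
#' The standardized activity unit: per-pixel seasonal count divided by the
#' pixel area in hectares and the number of nights. A 70 m pixel is 0.49 ha,
#' so 7431 occurrences over 152 nights normalize to 99.77
#' occurrences per hectare per night.
#'
#' @param raster an [ActivityRaster-class].
#' @return a [GridRaster-class] of rates (occurrences ha^-1 night^-1);
#'   masked pixels stay `NA`.
#' @export
toRate <- function(raster) {
  stopifnot(is(raster, "ActivityRaster"))
  area <- pixelAreaHa(raster)
  if (raster@nNights < 1L) stop("'nNights' must be >= 1", call. = FALSE)
  if (area <= 0) stop("pixel area must be positive", call. = FALSE)
  gridRaster(raster@values / (area * raster@nNights),
             pixelSize = raster@pixelSize, xll = raster@xll, yll = raster@yll)
}

#' Mask pixels out of an activity raster
#'
#' Applies a binary coverage/clutter mask: pixels where `mask` is 0 (or NA)
#' become missing (`NA`), not zero, so they are excluded from every
#' downstream mean rather than dragging it toward zero.
#'
#' @param raster an [ActivityRaster-class] or [GridRaster-class].
#' @param mask matrix (or GridRaster) of 0/1; 1 = keep.
#' @return the raster with masked pixels set to `NA`.
#' @export
applyMask <- function(raster, mask) {
  mv <- if (isS4(mask)) mask@values else mask
  checkSameGeometry(raster, if (isS4(mask)) mask else mv, "raster and mask")
  keep <- !is.na(mv) & mv != 0
  v <- raster@values
  v[!keep] <- NA_real_
  out <- raster
  out@values <- v
  out
}

#' Fraction of unmasked area with any bat detection
#'
#' Share of unmasked pixels whose seasonal count is at least one -- the
#' "bats were detected in X% of the area" statistic.
#'
#' @param raster an [ActivityRaster-class].
#' @return proportion in \[0, 1\].
#' @export
fractionAreaDetected <- function(raster) {
  v <- raster@values
  ok <- !is.na(v)
  if (!any(ok))
    stop("all pixels are masked; detected-area fraction is undefined",
         call. = FALSE)
  sum(v[ok] >= 1) / sum(ok)
}
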