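#' @include AllClasses.R
NULL

#' Construct a GridRaster
#'
#' @param values numeric matrix (row 1 = north).
#' @param pixelSize pixel edge, meters (default 70).
#' @param xll,yll lower-left corner, projected meters.
#' @return a [GridRaster-class].
#' @export
gridRaster <- function(values, pixelSize = 70, xll = 0, yll = 0) {
  new("GridRaster", values = values, pixelSize = pixelSize,
      xll = xll, yll = yll)
}

#' Construct a PresenceScene
#'
#' @param values binary 0/1 matrix of detections.
#' @param timestamp scan identifier.
#' @inheritParams gridRaster
#' @return a [PresenceScene-class].
#' @export
presenceScene <- function(values, timestamp = "", pixelSize = 70,
                          xll = 0, yll = 0) {
  new("PresenceScene", values = values, timestamp = timestamp,
      pixelSize = pixelSize, xll = xll, yll = yll)
}

#' Construct an ActivityRaster
#'
#' @param values matrix of non-negative integer counts (NA = masked).
#' @param nNights nights aggregated over.
#' @param nScenes scans aggregated over.
#' @inheritParams gridRaster
#' @return an [ActivityRaster-class].
#' @export
activityRaster <- function(values, nNights, nScenes, pixelSize = 70,
                           xll = 0, yll = 0) {
  new("ActivityRaster", values = values, nNights = as.integer(nNights),
      nScenes = as.integer(nScenes), pixelSize = pixelSize,
      xll = xll, yll = yll)
}

#' Construct a RoostSet
#'
#' @param coords n x 2 matrix (or data.frame with x, y) of roost locations,
#'   projected meters.
#' @param weights optional per-roost weights (default 1).
#' @return a [RoostSet-class].
#' @export
roostSet <- function(coords, weights = NULL) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y")])
  coords <- matrix(as.numeric(coords), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  new("RoostSet", coords = coords, weights = as.numeric(weights))
}

## Pixel-center coordinates (x east, y north), row 1 = northernmost.
## Returns a list of two matrices co-registered with the grid.
pixelCenters <- function(nr, nc, pixelSize, xll = 0, yll = 0) {
  x <- xll + (seq_len(nc) - 0.5) * pixelSize
  y <- yll + (nr - seq_len(nr) + 0.5) * pixelSize
  list(x = matrix(rep(x, each = nr), nrow = nr),
       y = matrix(rep(y, times = nc), nrow = nr))
}

## Hard check that two gridded layers are co-registered.
checkSameGeometry <- function(a, b, what = "layers") {
  da <- dim(a); db <- dim(b)
  if (!identical(da, db))
    stop(sprintf("%s are not co-registered: dimensions %dx%d vs %dx%d",
                 what, da[1], da[2], db[1], db[2]), call. = FALSE)
  if (isS4(a) && isS4(b)) {
    if (a@pixelSize != b@pixelSize || a@xll != b@xll || a@yll != b@yll)
      stop(sprintf("%s are not co-registered: geometry mismatch", what),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Average a matrix over square blocks
#'
#' Aggregates a base-resolution matrix to coarse cells of `block x block`
#' pixels by the mean over non-missing pixels; also reports the fraction of
#' valid (non-NA) base pixels per cell. Trailing rows/columns that do not
#' fill a complete block are dropped.
#'
#' @param m numeric matrix.
#' @param block block edge in pixels (integer >= 1).
#' @return list with `mean` (coarse matrix) and `validFrac` (coarse matrix).
#' @export
blockAggregate <- function(m, block) {
  block <- as.integer(block)
  stopifnot(block >= 1L)
  nr <- (nrow(m) %/% block) * block
  nc <- (ncol(m) %/% block) * block
  if (nr < block || nc < block)
    stop("matrix smaller than one aggregation block", call. = FALSE)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- (seq_len(nr) - 1L) %/% block
  ci <- (seq_len(nc) - 1L) %/% block
  grp <- outer(ri, ci, function(a, b) a + b * (nr %/% block)) + 1L
  ok <- !is.na(m)
  sums <- tapply(ifelse(ok, m, 0), grp, sum)
  nOk <- tapply(as.numeric(ok), grp, sum)
  mu <- ifelse(nOk > 0, sums / nOk, NA_real_)
  dimCoarse <- c(nr %/% block, nc %/% block)
  list(mean = matrix(as.numeric(mu), nrow = dimCoarse[1]),
       validFrac = matrix(as.numeric(nOk) / block^2, nrow = dimCoarse[1]))
}

## Modal (most frequent) integer label per block, ties broken by the
## alphabetically-first class name among the tied labels.
blockModalClass <- function(classIdx, levels, block) {
  nr <- (nrow(classIdx) %/% block) * block
  nc <- (ncol(classIdx) %/% block) * block
  classIdx <- classIdx[seq_len(nr), seq_len(nc), drop = FALSE]
  nrC <- nr %/% block; ncC <- nc %/% block
  out <- matrix(NA_character_, nrC, ncC)
  for (i in seq_len(nrC)) {
    for (j in seq_len(ncC)) {
      blk <- classIdx[((i - 1L) * block + 1L):(i * block),
                      ((j - 1L) * block + 1L):(j * block)]
      tab <- table(levels[as.vector(blk)])
      top <- names(tab)[tab == max(tab)]
      out[i, j] <- sort(top)[1L]
    }
  }
  out
}

## 4-connected component labeling of equal-valued regions of an integer
## matrix. Two-pass scan with union-find; small grids only, pure R.
labelPatches <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nextLab <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      up <- if (i > 1L && m[i - 1L, j] == m[i, j]) lab[i - 1L, j] else 0L
      lf <- if (j > 1L && m[i, j - 1L] == m[i, j]) lab[i, j - 1L] else 0L
      if (up == 0L && lf == 0L) {
        nextLab <- nextLab + 1L
        parent[nextLab] <- nextLab
        lab[i, j] <- nextLab
      } else if (up != 0L && lf != 0L) {
        ru <- findRoot(up); rl <- findRoot(lf)
        parent[max(ru, rl)] <- min(ru, rl)
        lab[i, j] <- min(ru, rl)
      } else {
        lab[i, j] <- max(up, lf)
      }
    }
  }
  if (nextLab == 0L) return(lab)
  roots <- vapply(seq_len(nextLab), findRoot, integer(1))
  dense <- match(roots, sort(unique(roots)))
  matrix(dense[lab], nr, nc)
}
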