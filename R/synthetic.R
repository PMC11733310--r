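#' @include AllClasses.R grid-utils.R roost.R landcover.R presence.R
NULL

## Deterministic sub-seed derivation so partial simulations (one night, one
## stage) reproduce the corresponding slice of a full run. Kept < 2^31.
subSeed <- function(seed, k) as.integer((as.numeric(seed) + 77003 * k) %%
                                          2147483629)

defaultClassWeights <- function() {
  # relative foraging intensity; rice elevated, water/wetland and low
  # vegetation depressed, qualitatively matching observed class contrasts
  c("rice"                  = 1.80,
    "barren/other"          = 1.20,
    "herbaceous"            = 1.10,
    "conifer"               = 1.10,
    "hardwood"              = 1.05,
    "urban"                 = 1.05,
    "miscellaneous"         = 0.95,
    "water/wetland"         = 0.78,
    "grassland"             = 0.85,
    "row/field crops"       = 0.75,
    "fruits/nuts/vineyards" = 0.70,
    "desert"                = 0.50,
    "shrub"                 = 0.40)
}

#' Construct a synthetic landscape configuration
#'
#' Defaults mirror the study season -- 152 nights of 126 radar scans on a
#' 70 m grid with 8 known roosts and a commute plume of amplitude 1 decaying
#' over 5 km -- on a desk-scale spatial window (120 x 100 pixels, 8.4 x
#' 7 km). The baseline detection rate 0.06 puts the landscape-average
#' activity near the mid-teens of occurrences per hectare per night.
#'
#' @param gridWidth,gridHeight grid size in pixels.
#' @param pixelSize pixel edge, m.
#' @param nNights nights in the season.
#' @param scansPerNight scans per night.
#' @param classWeights named relative foraging intensities (>= 0).
#' @param nPatches number of Voronoi landscape patches.
#' @param roosts n x 2 roost coordinate matrix (m); default 8 roosts spread
#'   over the window.
#' @param amplitude,scale commute plume A_sim (dimensionless) and
#'   lambda_sim (m).
#' @param detectionRate baseline per-scan presence probability r in \[0, 1\].
#' @param seed integer RNG seed.
#' @param nTimeSteps temperature stack depth.
#' @param tBase,tGradient,tSeasonal,tNoise,tLo,tHi temperature field
#'   parameters, degrees C.
#' @return a [LandscapeConfig-class].
#' @export
landscapeConfig <- function(gridWidth = 120, gridHeight = 100,
                            pixelSize = 70,
                            nNights = 152, scansPerNight = 126,
                            classWeights = defaultClassWeights(),
                            nPatches = 150,
                            roosts = NULL,
                            amplitude = 1, scale = 5000,
                            detectionRate = 0.06, seed = 1,
                            nTimeSteps = 6,
                            tBase = 18, tGradient = 6, tSeasonal = 6,
                            tNoise = 0.5, tLo = 5, tHi = 40) {
  W <- gridWidth * pixelSize; H <- gridHeight * pixelSize
  if (is.null(roosts))
    roosts <- cbind(x = W * c(.15, .35, .55, .80, .25, .60, .85, .45),
                    y = H * c(.20, .75, .40, .85, .50, .10, .55, .30))
  storage.mode(roosts) <- "double"
  new("LandscapeConfig",
      gridWidth = as.integer(gridWidth), gridHeight = as.integer(gridHeight),
      pixelSize = as.numeric(pixelSize),
      nNights = as.integer(nNights), scansPerNight = as.integer(scansPerNight),
      classWeights = vapply(classWeights, as.numeric,
                            numeric(1)),
      nPatches = as.integer(nPatches),
      roosts = roosts, amplitude = as.numeric(amplitude),
      scale = as.numeric(scale),
      detectionRate = as.numeric(detectionRate), seed = as.integer(seed),
      nTimeSteps = as.integer(nTimeSteps),
      tBase = as.numeric(tBase), tGradient = as.numeric(tGradient),
      tSeasonal = as.numeric(tSeasonal),
      tNoise = as.numeric(tNoise), tLo = as.numeric(tLo),
      tHi = as.numeric(tHi))
}

#' Simulate a patchy land-cover layer
#'
#' Tessellates the grid into `nPatches` contiguous Voronoi cells around
#' uniformly sampled seed points and labels each cell with a class drawn
#' uniformly from the names of `classWeights`. Patches, not per-pixel iid
#' labels, so parcel-level extraction is exercised on realistic contiguous
#' fields.
#'
#' @param config a [LandscapeConfig-class].
#' @return a [LandCoverLayer-class].
#' @export
simulateLandcover <- function(config) {
  stopifnot(is(config, "LandscapeConfig"))
  validObject(config)
  nr <- config@gridHeight; nc <- config@gridWidth
  classes <- names(config@classWeights)
  set.seed(subSeed(config@seed, 500009))
  if (length(classes) == 1L) {
    cls <- matrix(classes, nr, nc)
    return(layerFromMatrices(cls, NULL, config@pixelSize))
  }
  np <- min(config@nPatches, nr * nc)
  ctr <- pixelCenters(nr, nc, config@pixelSize)
  sx <- stats::runif(np, 0, nc * config@pixelSize)
  sy <- stats::runif(np, 0, nr * config@pixelSize)
  best <- matrix(1L, nr, nc); bestD <- (ctr$x - sx[1])^2 + (ctr$y - sy[1])^2
  for (k in seq_len(np)[-1L]) {
    d2 <- (ctr$x - sx[k])^2 + (ctr$y - sy[k])^2
    upd <- d2 < bestD
    best[upd] <- k
    bestD[upd] <- d2[upd]
  }
  patchClass <- sample(classes, np, replace = TRUE)
  cls <- matrix(patchClass[best], nr, nc)
  # Voronoi cells are convex, hence contiguous; keep them as parcels even
  # when neighbours share a class (fields of the same crop touch in reality)
  layerFromMatrices(cls, best, config@pixelSize)
}

#' Per-scan presence probability surface implied by a configuration
#'
#' \eqn{p = \min\{1,\ r\, w(\mathrm{class})\,(1 + A_{sim} e^{-d/\lambda_{sim}})\}}
#' -- multiplicative in the class foraging weight and the roost commute
#' plume, clipped at 1.
#'
#' @param config a [LandscapeConfig-class].
#' @param landcover a [LandCoverLayer-class] covering the grid.
#' @return matrix of per-scan per-pixel presence probabilities.
#' @export
presenceProbability <- function(config, landcover) {
  checkSameGeometry(landcover, emptySceneMatrix(config),
                    "land cover and configured grid")
  w <- config@classWeights[classMap(landcover)]
  if (anyNA(w))
    stop("land cover contains class(es) without a configured weight",
         call. = FALSE)
  rs <- roostSet(config@roosts)
  d <- distanceToNearestRoost(config@gridHeight, config@gridWidth, rs,
                              config@pixelSize)
  p <- config@detectionRate * as.numeric(w) *
    (1 + config@amplitude * exp(-d / config@scale))
  if (max(p) > 5)
    warning("presence probability exceeds 5 before clipping; ",
            "degenerate saturated regime", call. = FALSE)
  matrix(pmin(1, p), config@gridHeight, config@gridWidth)
}

emptySceneMatrix <- function(config)
  matrix(0, config@gridHeight, config@gridWidth)

#' Simulate the binary radar scenes of one night
#'
#' Each pixel is independently present in each scan with the probability
#' from [presenceProbability()]. Night `night` always reproduces the same
#' scenes for a given config seed, independent of which other nights are
#' simulated.
#'
#' @param config a [LandscapeConfig-class].
#' @param landcover a [LandCoverLayer-class].
#' @param night night index in 1..nNights.
#' @param prob optional precomputed probability matrix (avoids recomputing
#'   the roost plume per night).
#' @return list of [PresenceScene-class], one per scan.
#' @export
simulateNightScenes <- function(config, landcover, night, prob = NULL) {
  if (is.null(prob)) prob <- presenceProbability(config, landcover)
  set.seed(subSeed(config@seed, night))
  nr <- config@gridHeight; nc <- config@gridWidth
  lapply(seq_len(config@scansPerNight), function(s) {
    v <- matrix(as.numeric(stats::runif(nr * nc) < prob), nr, nc)
    presenceScene(v, timestamp = sprintf("n%03d_s%03d", night, s),
                  pixelSize = config@pixelSize)
  })
}

#' Simulate presence scenes for several nights
#'
#' Convenience wrapper over [simulateNightScenes()]; materializes all
#' requested scenes in memory, so use [simulateActivity()] for full-season
#' runs.
#'
#' @inheritParams simulateNightScenes
#' @param nights night indices (default all configured nights).
#' @return flat list of [PresenceScene-class].
#' @export
simulateScenes <- function(config, landcover,
                           nights = seq_len(config@nNights)) {
  prob <- presenceProbability(config, landcover)
  do.call(c, lapply(nights, function(n)
    simulateNightScenes(config, landcover, n, prob = prob)))
}

#' Simulate and aggregate a full season of scenes
#'
#' Streams scene simulation night by night through [aggregateScenes()],
#' accumulating counts without holding the full scene stack in memory.
#' Identical (config, seed) gives a bit-identical raster.
#'
#' @inheritParams simulateNightScenes
#' @return an [ActivityRaster-class] over all configured nights.
#' @export
simulateActivity <- function(config, landcover) {
  prob <- presenceProbability(config, landcover)
  acc <- emptySceneMatrix(config)
  for (n in seq_len(config@nNights)) {
    sc <- simulateNightScenes(config, landcover, n, prob = prob)
    acc <- acc + gridValues(aggregateScenes(sc, nNights = 1L))
  }
  activityRaster(acc, nNights = config@nNights,
                 nScenes = config@nNights * config@scansPerNight,
                 pixelSize = config@pixelSize)
}

#' Simulate environmental covariates
#'
#' Generates the three covariate layers consumed by the association model:
#' a seasonal temperature stack (west-east spatial gradient plus a seasonal
#' sinusoid and pixel noise, clipped to `[tLo, tHi]`), a nighttime-lights
#' raster elevated over urban pixels, and an irrigated-area raster (ha per
#' pixel) elevated over agricultural classes.
#'
#' @param config a [LandscapeConfig-class].
#' @param landcover a [LandCoverLayer-class].
#' @return list with `temperature` (list of matrices, degrees C), `lights`
#'   ([GridRaster-class], radiance units) and `irrigated`
#'   ([GridRaster-class], ha per pixel).
#' @export
simulateCovariates <- function(config, landcover) {
  checkSameGeometry(landcover, emptySceneMatrix(config),
                    "land cover and configured grid")
  nr <- config@gridHeight; nc <- config@gridWidth
  set.seed(subSeed(config@seed, 900007))
  xfrac <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  temperature <- lapply(seq_len(config@nTimeSteps), function(t) {
    seas <- config@tSeasonal * sin(pi * (t - 0.5) / config@nTimeSteps)
    tm <- config@tBase + config@tGradient * (xfrac - 0.5) + seas +
      stats::rnorm(nr * nc, 0, config@tNoise)
    matrix(pmin(config@tHi, pmax(config@tLo, tm)), nr, nc)
  })
  cls <- classMap(landcover)
  urban <- cls == "urban"
  lights <- stats::rlnorm(nr * nc, meanlog = log(0.5), sdlog = 0.3)
  lights[urban] <- lights[urban] + stats::rlnorm(sum(urban),
                                                 meanlog = log(30),
                                                 sdlog = 0.2)
  agClasses <- c("rice", "row/field crops", "fruits/nuts/vineyards",
                 "miscellaneous")
  ag <- cls %in% agClasses
  frac <- stats::runif(nr * nc, 0, 0.10)
  frac[ag] <- stats::runif(sum(ag), 0.60, 0.95)
  irr <- matrix(frac, nr, nc) * (config@pixelSize / 100)^2
  list(temperature = temperature,
       lights = gridRaster(matrix(lights, nr, nc),
                           pixelSize = config@pixelSize),
       irrigated = gridRaster(irr, pixelSize = config@pixelSize))
}
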