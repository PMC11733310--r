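test_that("single-class config yields a one-class landscape", {
  cfg <- tinyConfig(classWeights = c(rice = 1), nPatches = 10)
  lyr <- simulateLandcover(cfg)
  expect_true(all(classMap(lyr) == "rice"))
  expect_equal(sum(parcels(lyr)$area_ha), 30 * 20 * 0.49)
})

test_that("patch tessellation partitions the grid over the 13 classes", {
  cfg <- tinyConfig(seed = 5, nPatches = 60)
  lyr <- simulateLandcover(cfg)
  expect_equal(sum(parcels(lyr)$area_ha),
               cfg@gridWidth * cfg@gridHeight * 0.49)
  expect_true(all(unique(as.vector(classMap(lyr))) %in%
                    names(landCoverClasses())))
  # parcels are contiguous: each parcel's pixel count matches its area
  expect_equal(tabulate(as.vector(lyr@parcelOf), nrow(parcels(lyr))) * 0.49,
               parcels(lyr)$area_ha)
})

test_that("identical config and seed reproduce bit-identical outputs", {
  a <- simulateLandcover(tinyConfig(seed = 1))
  b <- simulateLandcover(tinyConfig(seed = 1))
  c2 <- simulateLandcover(tinyConfig(seed = 2))
  expect_identical(classMap(a), classMap(b))
  expect_false(identical(classMap(a), classMap(c2)))

  s1 <- simulateScenes(tinyConfig(seed = 1), a, nights = 1:2)
  s2 <- simulateScenes(tinyConfig(seed = 1), a, nights = 1:2)
  expect_identical(lapply(s1, gridValues), lapply(s2, gridValues))

  # night slices reproduce the corresponding part of a full run
  n2only <- simulateScenes(tinyConfig(seed = 1), a, nights = 2)
  expect_identical(gridValues(n2only[[1]]),
                   gridValues(s1[[tinyConfig()@scansPerNight + 1L]]))
})

test_that("empirical presence rate matches the configured r without plume", {
  cfg <- tinyConfig(classWeights = c(grassland = 1), amplitude = 0,
                    detectionRate = 0.1, nNights = 6, scansPerNight = 25,
                    seed = 17)
  lyr <- simulateLandcover(cfg)
  act <- simulateActivity(cfg, lyr)
  n <- nScenes(act) * prod(dim(act))
  phat <- sum(gridValues(act)) / n
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(phat - 0.1), 3 * se)
})

test_that("r = 0 gives empty scenes", {
  cfg <- tinyConfig(detectionRate = 0)
  lyr <- simulateLandcover(cfg)
  sc <- simulateScenes(cfg, lyr, nights = 1)
  expect_true(all(vapply(sc, function(s) sum(gridValues(s)), numeric(1)) == 0))
})

test_that("class weights scale empirical presence rates proportionally", {
  cfg <- tinyConfig(classWeights = c(rice = 0.2, grassland = 0.1),
                    amplitude = 0, detectionRate = 1,
                    nNights = 8, scansPerNight = 25, nPatches = 30,
                    seed = 23)
  lyr <- simulateLandcover(cfg)
  act <- simulateActivity(cfg, lyr)
  cm <- classMap(lyr)
  pRice <- mean(gridValues(act)[cm == "rice"]) / nScenes(act)
  pGrass <- mean(gridValues(act)[cm == "grassland"]) / nScenes(act)
  expect_equal(pRice / pGrass, 2, tolerance = 0.1)
})

test_that("saturated probability regime triggers the degenerate warning", {
  cfg <- tinyConfig(classWeights = c(rice = 10), detectionRate = 1)
  lyr <- simulateLandcover(cfg)
  expect_warning(presenceProbability(cfg, lyr), "degenerate")
  p <- suppressWarnings(presenceProbability(cfg, lyr))
  expect_true(all(p <= 1))     # silently clipped
})

test_that("covariates honor geometry, bounds and class contrasts", {
  cfg <- tinyConfig(seed = 19)
  lyr <- simulateLandcover(cfg)
  cov <- simulateCovariates(cfg, lyr)
  expect_length(cov$temperature, cfg@nTimeSteps)
  for (tm in cov$temperature)
    expect_true(all(tm >= cfg@tLo & tm <= cfg@tHi))

  # constant-temperature option: no gradient, no season, no noise
  cfgC <- tinyConfig(seed = 19, tGradient = 0, tSeasonal = 0, tNoise = 0)
  covC <- simulateCovariates(cfgC, simulateLandcover(cfgC))
  expect_true(all(vapply(covC$temperature,
                         function(tm) diff(range(tm)) == 0, logical(1))))

  cm <- classMap(lyr)
  if (any(cm == "urban") && any(cm != "urban"))
    expect_gt(mean(gridValues(cov$lights)[cm == "urban"]),
              mean(gridValues(cov$lights)[cm != "urban"]))
  ag <- cm %in% c("rice", "row/field crops", "fruits/nuts/vineyards",
                  "miscellaneous")
  if (any(ag) && any(!ag))
    expect_gt(mean(gridValues(cov$irrigated)[ag]),
              mean(gridValues(cov$irrigated)[!ag]))
})

test_that("configs validate their invariants before any simulation", {
  expect_error(landscapeConfig(classWeights = c(rice = -1)), ">= 0")
  expect_error(landscapeConfig(classWeights = c(swamp_castle = 1)),
               "unknown class")
  expect_error(landscapeConfig(scale = -10), "> 0")
  expect_error(landscapeConfig(detectionRate = 1.5), "\\[0, 1\\]")
  expect_error(landscapeConfig(nNights = 0), ">= 1")
})

test_that("matched roost correction removes the simulated commute trend", {
  cfg <- tinyConfig(gridWidth = 50, gridHeight = 20,
                    classWeights = c(grassland = 1),
                    roosts = cbind(x = 100, y = 100),
                    amplitude = 1.5, scale = 1000,
                    detectionRate = 0.1, nNights = 15, scansPerNight = 40,
                    seed = 29)
  lyr <- simulateLandcover(cfg)
  act <- simulateActivity(cfg, lyr)
  rate <- toRate(act)
  d <- distanceToNearestRoost(20, 50, roostSet(cfg@roosts), 70)
  plume <- exp(-as.vector(d) / cfg@scale)

  # before correction the commute trend is strongly present
  tRaw <- summary(lm(as.vector(gridValues(rate)) ~ plume))$coefficients[2, 3]
  expect_gt(tRaw, 5)

  corr <- correctActivity(rate, roostSet(cfg@roosts),
                          decayParams(cfg@amplitude, cfg@scale))
  tCorr <- summary(lm(as.vector(gridValues(corr)) ~
                        plume))$coefficients[2, 3]
  expect_lt(abs(tCorr), 2)
})
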