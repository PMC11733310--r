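test_that("Briere curve has boundary zeros and the stated closed form", {
  expect_equal(briere(0, 1, 0, 4), 0)
  expect_equal(briere(4, 1, 0, 4), 0)
  expect_equal(briere(2, 1, 0, 4), 2 * 2 * sqrt(2))
  expect_equal(briere(c(-5, 50), 1, 0, 4), c(0, 0))   # outside support
  expect_true(all(briere(seq(-10, 50, 0.1), 0.02, 11, 39) >= 0))
})

test_that("Briere argmax on a fine grid matches the analytic derivative root", {
  c0 <- 7.86e-5; Tmin <- 11.4; Tmax <- 39.2
  grid <- seq(Tmin, Tmax, length.out = 200001)
  tGrid <- grid[which.max(briere(grid, c0, Tmin, Tmax))]
  # d/dT [T(T-Tmin)sqrt(Tmax-T)] = 0, solved independently
  dfun <- function(T)
    (2 * T - Tmin) * sqrt(Tmax - T) - T * (T - Tmin) / (2 * sqrt(Tmax - T))
  tRoot <- uniroot(dfun, c(Tmin + 1e-6, Tmax - 1e-6))$root
  expect_equal(tGrid, tRoot, tolerance = 1e-3)
})

test_that("quadratic curve is symmetric with a midpoint peak", {
  expect_equal(quadraticTPC(20, 1, 10, 30), 100)
  expect_equal(quadraticTPC(c(5, 35), 1, 10, 30), c(0, 0))
  delta <- seq(0.5, 9.5, by = 0.5)
  expect_equal(quadraticTPC(20 + delta, 2, 10, 30),
               quadraticTPC(20 - delta, 2, 10, 30))
})

test_that("relative abundance composes the traits as EFD*pEA*MDR/mu^2", {
  tr <- constantTraits(EFD = 8, pEA = 0.5, MDR = 0.1, mu = 0.2)
  expect_equal(relativeAbundance(15, tr), 8 * 0.5 * 0.1 / 0.04)  # = 10

  # zero outside every trait support
  real <- readTraitConfig()
  expect_equal(relativeAbundance(c(-20, 5, 45), real), c(0, 0, 0))

  # mortality floor caps the denominator
  trF <- constantTraits(mu = 1e-9, muFloor = 0.01)
  expect_equal(relativeAbundance(15, trF), 8 * 0.5 * 0.1 / 0.01^2)

  # missing trait is a construction error
  expect_error(abundanceParams(list(EFD = traitCurve("EFD", "constant", 1))),
               "missing trait")
})

test_that("default trait composition is unimodal over temperature", {
  params <- readTraitConfig()
  grid <- seq(0, 45, by = 0.01)
  m <- relativeAbundance(grid, params)
  expect_true(any(m > 0))
  interior <- which(diff(sign(diff(m))) == -2) + 1L
  expect_length(interior[m[interior] > 1e-12 * max(m)], 1L)
  # zero outside the intersection of trait supports
  lo <- max(vapply(params@curves, function(cu) cu@Tmin, numeric(1)))
  hi <- min(vapply(params@curves, function(cu) cu@Tmax, numeric(1)))
  expect_true(all(m[grid < lo | grid > hi] == 0))
})

test_that("the index is linear in each numerator trait's scale", {
  params <- readTraitConfig()
  doubled <- params
  doubled@curves$EFD@c <- 2 * params@curves$EFD@c
  grid <- seq(10, 40, by = 0.5)
  expect_equal(relativeAbundance(grid, doubled),
               2 * relativeAbundance(grid, params))
})

test_that("the abundance raster averages M(T) over the season", {
  params <- constantTraits()
  stack <- replicate(4, matrix(20, 3, 3), simplify = FALSE)
  r <- abundanceRaster(stack, params)
  expect_equal(gridValues(r), matrix(10, 3, 3))

  real <- readTraitConfig()
  grid <- seq(14, 34, length.out = 9)
  set.seed(8)
  stack <- replicate(5, matrix(sample(grid, 12, TRUE), 3, 4),
                     simplify = FALSE)
  r <- gridValues(abundanceRaster(stack, real))
  for (i in 1:3) for (j in 1:4) {
    vals <- vapply(stack, function(tm) relativeAbundance(tm[i, j], real),
                   numeric(1))
    expect_equal(r[i, j], mean(vals))
  }

  # always-cold pixel is zero; missing temperatures propagate
  stack2 <- replicate(3, matrix(c(25, 2, NA, 25), 2, 2), simplify = FALSE)
  r2 <- gridValues(abundanceRaster(stack2, real))
  expect_equal(r2[2, 1], 0)
  expect_true(is.na(r2[1, 2]))
  expect_error(abundanceRaster(list(), real), "empty")
})

test_that("seasonal averaging commutes with spatial masking", {
  real <- readTraitConfig()
  set.seed(12)
  stack <- replicate(4, matrix(runif(20, 12, 38), 4, 5), simplify = FALSE)
  mask <- matrix(rbinom(20, 1, 0.7), 4, 5)
  a <- applyMask(abundanceRaster(stack, real), mask)
  maskedStack <- lapply(stack, function(tm) { tm[mask == 0] <- NA; tm })
  b <- abundanceRaster(maskedStack, real)
  expect_equal(gridValues(a), gridValues(b))
})
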