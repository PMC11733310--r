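test_that("pixel table aggregation matches brute-force block averaging", {
  set.seed(41)
  nr <- 28; nc <- 42; blk <- 7
  act <- gridRaster(matrix(runif(nr * nc, 0, 30), nr, nc))
  act@values[sample(nr * nc, 60)] <- NA
  mos <- gridRaster(matrix(runif(nr * nc, 0, 5), nr, nc))
  lig <- gridRaster(matrix(rlnorm(nr * nc), nr, nc))
  irr <- gridRaster(matrix(runif(nr * nc, 0, 0.4), nr, nc))
  cfg <- tinyConfig(gridWidth = nc, gridHeight = nr, seed = 43,
                    nPatches = 30)
  lyr <- simulateLandcover(cfg)
  suppressMessages(
    tab <- buildPixelTable(act, mos, lig, irr, lyr, cellSizePx = blk,
                           minValidFrac = 0))
  expect_equal(nrow(tab), (nr / blk) * (nc / blk))
  for (k in sample(nrow(tab), 6)) {
    i <- ((tab$cell_id[k] - 1) %% (nr / blk))
    j <- ((tab$cell_id[k] - 1) %/% (nr / blk))
    rows <- (i * blk + 1):(i * blk + blk)
    cols <- (j * blk + 1):(j * blk + blk)
    expect_equal(tab$activity[k], mean(act@values[rows, cols], na.rm = TRUE))
    expect_equal(tab$mosquito[k], mean(mos@values[rows, cols]))
    expect_equal(tab$irrigated_ha[k], sum(irr@values[rows, cols]))
    blkCls <- table(classMap(lyr)[rows, cols])
    top <- sort(names(blkCls)[blkCls == max(blkCls)])[1]
    expect_equal(tab$class[k], top)
  }
})

test_that("uniform layers give identical records; low-coverage cells drop", {
  u <- gridRaster(matrix(2, 20, 20))
  cfgU <- tinyConfig(gridWidth = 20, gridHeight = 20,
                     classWeights = c(rice = 1))
  lyrU <- simulateLandcover(cfgU)
  tab <- buildPixelTable(u, u, u, u, lyrU, cellSizePx = 10)
  expect_equal(nrow(unique(tab[c("activity", "mosquito", "lights",
                                 "class")])), 1L)

  half <- u
  half@values[1:10, ] <- NA   # entire top half masked
  expect_message(
    tab2 <- buildPixelTable(half, u, u, u, lyrU, cellSizePx = 10,
                            minValidFrac = 0.5),
    "dropped")
  expect_equal(nrow(tab2), 2L)

  allNA <- u; allNA@values[] <- NA
  expect_error(suppressMessages(
    buildPixelTable(allNA, u, u, u, lyrU, cellSizePx = 10)), "no cell")
})

test_that("the GAM recovers a known monotone mosquito effect", {
  rec <- makeRecords(1200, seed = 51,
                     mosquitoEffect = function(m) 12 * plogis(m - 5),
                     lightsBeta = 2, noiseSd = 1)
  fit <- fitGam(rec, kSpace = 20)
  eff <- mosquitoEffect(fit, at = seq(0.2, 9.8, length.out = 100))
  truth <- 12 * plogis(eff$mosquito - 5)
  expect_gt(cor(eff$effect, truth), 0.9)
  expect_lt(modelSmooths(fit)$p[grep("mosquito",
                                     modelSmooths(fit)$term)], 0.001)

  # lights coefficient lands in its CI on this draw
  tt <- modelTerms(fit)
  li <- tt[tt$term == "lights", ]
  expect_true(li$ci_lo <= 2 && 2 <= li$ci_hi)
})

test_that("estimates are invariant to record order", {
  rec <- makeRecords(600, seed = 53, riceDelta = 4)
  f1 <- fitGam(rec, kSpace = 15)
  set.seed(1)
  f2 <- fitGam(rec[sample(nrow(rec)), ], kSpace = 15)
  expect_equal(modelTerms(f1)$estimate, modelTerms(f2)$estimate,
               tolerance = 1e-8)
  expect_equal(f1@r2, f2@r2, tolerance = 1e-8)
})

test_that("reference class is declared, absorbed, and configurable", {
  rec <- makeRecords(500, seed = 57, riceDelta = 5)
  fit <- fitGam(rec, referenceClass = "miscellaneous", kSpace = 15)
  expect_equal(fit@referenceClass, "miscellaneous")
  tt <- modelTerms(fit)
  expect_false(any(grepl("miscellaneous", tt$term)))
  rice <- tt[tt$term == "LULC: rice", ]
  expect_gt(rice$estimate, 0)   # simulated +5 offset has the right sign
  expect_equal(fit@n, 500L)

  fitG <- fitGam(rec, referenceClass = "grassland", kSpace = 15)
  expect_false(any(grepl("grassland", modelTerms(fitG)$term)))
})

test_that("thin classes are dropped with a warning, with bookkeeping", {
  rec <- makeRecords(300, seed = 59)
  rec$class[1] <- "desert"     # a 1-record class
  expect_warning(fit <- fitGam(rec, kSpace = 15), "desert")
  expect_equal(fit@n, 299L)
})

test_that("fit reports round-trip through the serialized forms", {
  rec <- makeRecords(400, seed = 61, riceDelta = 3)
  fit <- fitGam(rec, kSpace = 15)
  stem <- file.path(tempdir(), "gamfit")
  rows <- summarizeFit(fit, file = stem)
  expect_equal(rows$predictor[1], "(Intercept)")
  expect_true(any(grepl("^Smooth term", rows$predictor)))

  back <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(back$terms$estimate, modelTerms(fit)$estimate)
  expect_equal(back$r2, fit@r2)
  expect_equal(back$n, fit@n)
  expect_equal(back$reference_class, fit@referenceClass)
})
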