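test_that("harmonization applies crop precedence and the miscellaneous rule", {
  nat <- matrix("grassland", 4, 4)
  nat[1, ] <- "agriculture"          # generic agriculture in the old layer
  crop <- matrix(NA_character_, 4, 4)
  crop[2, 1:2] <- "rice"             # crop parcel over grassland
  crop[1, 1] <- "almonds"            # crop parcel over generic agriculture
  lyr <- harmonizeLandCover(nat, crop)
  cm <- classMap(lyr)
  expect_equal(cm[2, 1], "rice")                 # crop wins over natural
  expect_equal(cm[1, 1], "fruits/nuts/vineyards")
  expect_equal(cm[1, 2], "miscellaneous")        # ag without crop label
  expect_equal(cm[3, 3], "grassland")
  expect_equal(unique(parcels(lyr)$type[parcels(lyr)$class == "rice"]),
               "agricultural")
  # area conservation: parcel areas partition the grid
  expect_equal(sum(parcels(lyr)$area_ha), 16 * 0.49)
})

test_that("harmonization rejects unmapped raw labels, naming them", {
  nat <- matrix(c("grassland", "lunar regolith"), 2, 2)
  expect_error(harmonizeLandCover(nat), "lunar regolith")
})

test_that("crop parcel ids are preserved and split across classes", {
  nat <- matrix("grassland", 3, 6)
  crop <- matrix(NA_character_, 3, 6)
  ids <- matrix(NA_integer_, 3, 6)
  crop[, 1:2] <- "rice";   ids[, 1:2] <- 1L
  crop[, 4:5] <- "corn";   ids[, 4:5] <- 2L
  lyr <- harmonizeLandCover(nat, crop, cropParcelIds = ids)
  pt <- parcels(lyr)
  expect_setequal(pt$class, c("rice", "row/field crops", "grassland"))
  expect_equal(pt$area_ha[pt$class == "rice"], 6 * 0.49)
})

test_that("parcel extraction averages unmasked pixel rates per parcel", {
  cls <- matrix("grassland", 2, 4)
  cls[, 3:4] <- "rice"
  lyr <- harmonizeLandCover(cls)
  v <- matrix(c(1, 1, 3, 3, 5, NA, 7, 7), 2, 4)
  rate <- gridRaster(v)
  st <- extractParcelStats(rate, lyr)
  expect_equal(st$mean_rate[st$class == "grassland"], 2.0)
  expect_equal(st$mean_rate[st$class == "rice"], mean(c(5, 7, 7)))

  # fully masked parcel is missing, not zero
  v2 <- v; v2[, 3:4] <- NA
  st2 <- extractParcelStats(gridRaster(v2), lyr)
  expect_true(is.na(st2$mean_rate[st2$class == "rice"]))
})

test_that("zonal statistics match a per-pixel loop on a random landscape", {
  cfg <- tinyConfig(seed = 31)
  lyr <- simulateLandcover(cfg)
  set.seed(4)
  v <- matrix(runif(prod(dim(lyr)), 0, 30), dim(lyr)[1], dim(lyr)[2])
  v[sample(length(v), 40)] <- NA
  st <- extractParcelStats(gridRaster(v), lyr)
  pid <- lyr@parcelOf
  for (k in sample(nrow(st), 20)) {
    px <- v[pid == st$parcel_id[k]]
    if (all(is.na(px))) expect_true(is.na(st$mean_rate[k]))
    else expect_equal(st$mean_rate[k], mean(px, na.rm = TRUE))
  }
})

test_that("class summaries are area-weighted with percentile bootstrap CIs", {
  ps <- data.frame(parcel_id = 1:2, class = c("rice", "rice"),
                   type = "agricultural", area_ha = c(2, 2),
                   n_pixels = 4, n_unmasked = 4, mean_rate = c(10, 20))
  s <- classSummaries(ps, nBoot = 200, seed = 1)
  expect_equal(s$mean_rate[s$class == "rice"], 15)

  ps$area_ha <- c(1, 3)
  s <- classSummaries(ps, nBoot = 200, seed = 1)
  expect_equal(s$mean_rate[s$class == "rice"], 17.5)  # (1*10+3*20)/4
  expect_true(s$ci_lo[s$class == "rice"] <= 17.5 + 1e-9)
  expect_true(s$ci_hi[s$class == "rice"] >= 17.5 - 1e-9)

  # single-parcel class: mean reported, CI undefined
  ps1 <- rbind(ps, data.frame(parcel_id = 3, class = "urban",
                              type = "urban/other", area_ha = 5,
                              n_pixels = 4, n_unmasked = 4, mean_rate = 3))
  s1 <- classSummaries(ps1, nBoot = 100, seed = 2)
  expect_true(is.na(s1$ci_lo[s1$class == "urban"]))
  expect_equal(s1$mean_rate[s1$class == "urban"], 3)
})

test_that("study-wide mean agrees with total occurrences over total area", {
  cfg <- tinyConfig(seed = 13, amplitude = 0)
  lyr <- simulateLandcover(cfg)
  act <- simulateActivity(cfg, lyr)
  rate <- toRate(act)
  st <- extractParcelStats(rate, lyr, counts = act)
  s <- classSummaries(st, nBoot = 50, seed = 3)
  direct <- sum(gridValues(act)) /
    (sum(st$area_ha) * nNights(act))
  expect_equal(s$mean_rate[s$class == "(all)"], direct, tolerance = 1e-9)
})

test_that("ranking orders classes and reports unrounded ratios", {
  s <- data.frame(class = c("(all)", "rice", "barren/other"),
                  type = c("(all)", "agricultural", "urban/other"),
                  mean_rate = c(15.89, 28.56, 19.04),
                  ci_lo = NA, ci_hi = NA, area_ha = 1, n_parcels = 2)
  r <- rankAndRatios(s)
  expect_equal(r$class[1], "rice")
  expect_equal(r$ratio_to_next[1], 28.56 / 19.04)  # = 1.5
  expect_equal(round(r$ratio_to_next[1], 2), 1.5)
  expect_equal(r$ratio_to_overall[1], 28.56 / 15.89)

  one <- s[1:2, ]
  expect_equal(rankAndRatios(one)$ratio_to_next, 1)

  tie <- data.frame(class = c("(all)", "urban", "conifer", "rice"),
                    type = "x", mean_rate = 5, ci_lo = NA, ci_hi = NA,
                    area_ha = 1, n_parcels = 1)
  tie$type <- c("(all)", "urban/other", "natural", "agricultural")
  rt <- rankAndRatios(tie)
  expect_equal(rt$class, c("conifer", "rice", "urban"))  # alphabetical ties
  expect_true(all(rt$ratio_to_overall == 1))
})

test_that("the shipped class mapping is total over the 13-class vocabulary", {
  mp <- readClassMapping()
  expect_true(all(mp %in% names(landCoverClasses())))
  expect_setequal(unique(unname(landCoverClasses())),
                  c("agricultural", "natural", "urban/other", "water"))
  expect_length(landCoverClasses(), 13)
})
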