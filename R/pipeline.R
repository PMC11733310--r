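#' @include synthetic.R presence.R roost.R landcover.R mosquito.R association.R io.R
NULL

#' Run the full synthetic-landscape analysis pipeline
#'
#' Orchestrates simulate -> aggregate -> roost-correct -> land-cover
#' statistics -> mosquito abundance -> association GAM as one reproducible
#' run. Every stage output is written as plain text into `outDir`, the
#' configuration is serialized next to them, and a manifest records each
#' file with its MD5 checksum: re-running with an identical configuration
#' and seed reproduces identical checksums.
#'
#' @param config a [LandscapeConfig-class]; validated before any stage runs.
#' @param outDir output directory (created if needed).
#' @param decay a [DecayParams-class] for the roost correction; defaults to
#'   the configuration's own (amplitude, scale), i.e. the matched
#'   correction.
#' @param traits an [AbundanceParams-class]; default [readTraitConfig()].
#' @param nBoot bootstrap resamples for class CIs.
#' @param cellSizePx association-model cell edge in base pixels.
#' @param kMosquito,kSpace GAM basis dimensions (see [fitGam()]).
#' @param mask optional binary coverage mask matrix (1 = keep).
#' @param quiet suppress progress messages.
#' @return the manifest as a list (also written to `manifest.json`):
#'   per-stage files with checksums, the key headline numbers, and the
#'   parameters used.
#' @export
runPipeline <- function(config, outDir, decay = NULL, traits = NULL,
                        nBoot = 1000, cellSizePx = 14,
                        kMosquito = 10, kSpace = 50, mask = NULL,
                        quiet = FALSE) {
  stopifnot(is(config, "LandscapeConfig"))
  validObject(config)
  if (is.null(decay))
    decay <- decayParams(amplitude = config@amplitude, scale = config@scale)
  validObject(decay)
  if (is.null(traits)) traits <- readTraitConfig()
  validObject(traits)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  files <- character()
  stage <- function(name, fs) {
    files[fs] <<- name
    invisible(NULL)
  }

  cfgFile <- file.path(outDir, "config.json")
  jsonlite::write_json(configAsList(config), cfgFile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage("config", cfgFile)

  say("stage 1/6: land cover")
  lc <- simulateLandcover(config)
  stage("landcover", writeLandCover(lc, file.path(outDir, "landcover")))

  say("stage 2/6: scene simulation + aggregation (",
      config@nNights, " nights x ", config@scansPerNight, " scans)")
  act <- simulateActivity(config, lc)
  if (!is.null(mask)) act <- applyMask(act, mask)
  f <- file.path(outDir, "activity_counts.asc")
  writeAsciiGrid(act, f); stage("aggregate", f)
  rate <- toRate(act)
  f <- file.path(outDir, "activity_rate.asc")
  writeAsciiGrid(rate, f); stage("aggregate", f)

  say("stage 3/6: roost correction")
  roosts <- roostSet(config@roosts)
  f <- file.path(outDir, "roosts.csv")
  writeRoosts(roosts, f); stage("correct", f)
  corrected <- correctActivity(rate, roosts, decay)
  f <- file.path(outDir, "activity_rate_corrected.asc")
  writeAsciiGrid(corrected, f); stage("correct", f)

  say("stage 4/6: land-cover statistics")
  pstats <- extractParcelStats(corrected, lc, counts = act)
  f <- file.path(outDir, "parcel_stats.tsv")
  utils::write.table(pstats, f, sep = "\t", row.names = FALSE, quote = FALSE)
  stage("landcover_stats", f)
  summ <- classSummaries(pstats, nBoot = nBoot,
                         seed = subSeed(config@seed, 130003))
  f <- file.path(outDir, "class_summaries.tsv")
  utils::write.table(summ, f, sep = "\t", row.names = FALSE, quote = FALSE)
  stage("landcover_stats", f)
  ranks <- rankAndRatios(summ)
  f <- file.path(outDir, "class_ranks.tsv")
  utils::write.table(ranks, f, sep = "\t", row.names = FALSE, quote = FALSE)
  stage("landcover_stats", f)

  say("stage 5/6: mosquito abundance proxy")
  cov <- simulateCovariates(config, lc)
  mosq <- abundanceRaster(cov$temperature, traits,
                          pixelSize = config@pixelSize)
  f <- file.path(outDir, "mosquito_abundance.asc")
  writeAsciiGrid(mosq, f); stage("mosquito", f)
  f <- file.path(outDir, "lights.asc")
  writeAsciiGrid(cov$lights, f); stage("mosquito", f)
  f <- file.path(outDir, "irrigated.asc")
  writeAsciiGrid(cov$irrigated, f); stage("mosquito", f)

  say("stage 6/6: association model")
  records <- buildPixelTable(corrected, mosq, cov$lights, cov$irrigated,
                             lc, cellSizePx = cellSizePx)
  f <- file.path(outDir, "pixel_table.tsv")
  utils::write.table(records, f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  stage("gam", f)
  gres <- withCallingHandlers(
    fitGam(records, kMosquito = kMosquito, kSpace = kSpace),
    warning = function(w) {
      say("fitGam: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  summarizeFit(gres, file = file.path(outDir, "gam_summary"))
  stage("gam", file.path(outDir, c("gam_summary.tsv", "gam_summary.json")))

  vr <- gridValues(rate)
  headline <- list(
    n_scenes = act@nScenes,
    n_nights = act@nNights,
    scans_per_night_avg = round(act@nScenes / act@nNights),
    peak_rate_occ_ha_night = max(vr, na.rm = TRUE),
    mean_rate_occ_ha_night = mean(vr, na.rm = TRUE),
    fraction_area_detected = fractionAreaDetected(act),
    study_mean_corrected = summ$mean_rate[summ$class == "(all)"],
    top_class = ranks$class[1L],
    gam_r2 = gres@r2,
    gam_n = gres@n)

  manifest <- list(
    parameters = list(seed = config@seed,
                      decay_amplitude = decay@amplitude,
                      decay_scale_m = decay@scale,
                      n_boot = nBoot, cell_size_px = cellSizePx,
                      k_mosquito = kMosquito, k_space = kSpace),
    headline = headline,
    stages = lapply(split(names(files), unname(files)), function(fs)
      lapply(stats::setNames(fs, basename(fs)),
             function(p) unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", outDir)
  invisible(manifest)
}

## Serializable view of a configuration (round-trips through JSON/YAML).
configAsList <- function(config) {
  list(grid_width = config@gridWidth, grid_height = config@gridHeight,
       pixel_size_m = config@pixelSize,
       n_nights = config@nNights, scans_per_night = config@scansPerNight,
       class_weights = as.list(config@classWeights),
       n_patches = config@nPatches,
       roosts = apply(config@roosts, 1L,
                      function(r) list(x = r[[1]], y = r[[2]])),
       amplitude = config@amplitude, scale_m = config@scale,
       detection_rate = config@detectionRate, seed = config@seed,
       n_time_steps = config@nTimeSteps,
       t_base = config@tBase, t_gradient = config@tGradient,
       t_seasonal = config@tSeasonal, t_noise = config@tNoise,
       t_lo = config@tLo, t_hi = config@tHi)
}

#' Build a LandscapeConfig from a plain list (e.g. parsed YAML/JSON)
#'
#' Inverse of the serialization written by [runPipeline()]; unknown keys
#' are an error so typos never silently fall back to defaults.
#'
#' @param x named list using the serialized key names (see the written
#'   `config.json`); missing keys take the [landscapeConfig()] defaults.
#' @return a [LandscapeConfig-class].
#' @export
configFromList <- function(x) {
  known <- c("grid_width", "grid_height", "pixel_size_m", "n_nights",
             "scans_per_night", "class_weights", "n_patches", "roosts",
             "amplitude", "scale_m", "detection_rate", "seed",
             "n_time_steps", "t_base", "t_gradient", "t_seasonal",
             "t_noise", "t_lo", "t_hi")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- list()
  take <- function(key, arg) if (!is.null(x[[key]])) args[[arg]] <<- x[[key]]
  take("grid_width", "gridWidth"); take("grid_height", "gridHeight")
  take("pixel_size_m", "pixelSize"); take("n_nights", "nNights")
  take("scans_per_night", "scansPerNight"); take("n_patches", "nPatches")
  take("amplitude", "amplitude"); take("scale_m", "scale")
  take("detection_rate", "detectionRate"); take("seed", "seed")
  take("n_time_steps", "nTimeSteps"); take("t_base", "tBase")
  take("t_gradient", "tGradient"); take("t_seasonal", "tSeasonal")
  take("t_noise", "tNoise"); take("t_lo", "tLo"); take("t_hi", "tHi")
  if (!is.null(x$class_weights))
    args$classWeights <- unlist(x$class_weights)
  if (!is.null(x$roosts)) {
    args$roosts <- do.call(rbind, lapply(x$roosts, function(r)
      c(x = r$x, y = r$y)))
    rownames(args$roosts) <- NULL
  }
  do.call(landscapeConfig, args)
}
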