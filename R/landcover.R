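#' @include grid-utils.R
NULL

#' Read a raw-label to harmonized-class mapping table
#'
#' The mapping from raw source labels (vegetation raster categories and crop
#' parcel labels, 56 in the original sources) to the 13 harmonized classes
#' ships as an editable tab-separated table with columns `raw`, `class`.
#' Types are implied by the fixed class-to-type nesting
#' ([landCoverClasses()]).
#'
#' @param path TSV file; default is the table shipped with the package.
#' @return named character vector: raw label -> harmonized class.
#' @export
readClassMapping <- function(path = system.file("extdata",
                                                "class_mapping.tsv",
                                                package = "batscape")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("raw", "class") %in% names(tab)))
    stop("mapping table needs columns 'raw' and 'class'", call. = FALSE)
  bad <- setdiff(tab$class, names(landCoverClasses()))
  if (length(bad))
    stop("mapping maps to unknown class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  stats::setNames(tab$class, tab$raw)
}

## Build a LandCoverLayer from a per-pixel class matrix plus an optional
## per-pixel parcel-id matrix. Pixels without a parcel id are grouped into
## contiguous same-class patches.
layerFromMatrices <- function(classMat, parcelMat = NULL, pixelSize = 70,
                              xll = 0, yll = 0) {
  lev <- sort(unique(as.vector(classMat)))
  bad <- setdiff(lev, names(landCoverClasses()))
  if (length(bad))
    stop("unknown land-cover class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  idx <- matrix(match(classMat, lev), nrow = nrow(classMat))
  if (is.null(parcelMat)) {
    parcelMat <- labelPatches(idx)
  } else {
    # split any supplied parcel that spans several classes
    key <- paste(parcelMat, idx)
    parcelMat <- matrix(match(key, unique(key)), nrow = nrow(classMat))
  }
  pid <- sort(unique(as.vector(parcelMat)))
  npix <- tabulate(match(as.vector(parcelMat), pid), length(pid))
  clsIdx <- as.vector(idx)[match(pid, as.vector(parcelMat))]
  areaHa <- npix * (pixelSize / 100)^2
  cls <- lev[clsIdx]
  parcels <- data.frame(parcel_id = seq_along(pid),
                        class = cls,
                        type = unname(landCoverClasses()[cls]),
                        area_ha = areaHa,
                        stringsAsFactors = FALSE)
  dense <- matrix(match(as.vector(parcelMat), pid), nrow = nrow(classMat))
  new("LandCoverLayer", classOf = idx, parcelOf = dense, levels = lev,
      parcels = parcels, pixelSize = pixelSize, xll = xll, yll = yll)
}

#' Harmonize natural-vegetation and crop-parcel layers into one land cover
#'
#' Merges a natural-vegetation label raster with a crop-parcel layer into
#' the 13-class / 4-type scheme. Crop labels take precedence wherever a crop
#' parcel exists; natural-layer pixels labeled as generic agriculture with
#' no corresponding crop parcel become "miscellaneous" (field margins,
#' fallowed or otherwise unlabeled agricultural ground).
#'
#' @param naturalLabels character matrix of raw natural-layer labels.
#' @param cropLabels character matrix of raw crop labels, `NA` where no crop
#'   parcel exists; or `NULL` for none.
#' @param cropParcelIds optional integer matrix of crop parcel ids (NA where
#'   none); crop parcels keep their field boundaries, natural ground is
#'   split into contiguous patches.
#' @param mapping named character vector raw -> class
#'   (see [readClassMapping()]).
#' @param agricultureRawLabels raw natural-layer labels meaning "generic
#'   agriculture" that fall back to miscellaneous (default "agriculture").
#' @param pixelSize,xll,yll grid geometry.
#' @return a [LandCoverLayer-class].
#' @export
harmonizeLandCover <- function(naturalLabels, cropLabels = NULL,
                               cropParcelIds = NULL,
                               mapping = readClassMapping(),
                               agricultureRawLabels = "agriculture",
                               pixelSize = 70, xll = 0, yll = 0) {
  raw <- naturalLabels
  hasCrop <- if (is.null(cropLabels)) {
    matrix(FALSE, nrow(raw), ncol(raw))
  } else {
    checkSameGeometry(naturalLabels, cropLabels, "natural and crop layers")
    !is.na(cropLabels)
  }
  seen <- unique(c(as.vector(raw), as.vector(cropLabels[hasCrop])))
  seen <- setdiff(seen, c(NA, agricultureRawLabels))
  unmapped <- setdiff(seen, names(mapping))
  if (length(unmapped))
    stop("unmapped raw label(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  cls <- matrix(NA_character_, nrow(raw), ncol(raw))
  natIsAg <- raw %in% agricultureRawLabels
  cls[!natIsAg] <- mapping[raw[!natIsAg]]
  cls[natIsAg] <- "miscellaneous"   # agriculture with no 2019 crop label
  cls[hasCrop] <- mapping[cropLabels[hasCrop]]
  parcelMat <- NULL
  if (!is.null(cropParcelIds)) {
    # natural ground gets ids disjoint from crop ids via patch labeling
    natPatch <- labelPatches(matrix(match(cls, sort(unique(as.vector(cls)))),
                                    nrow = nrow(cls)))
    offset <- max(cropParcelIds, 0L, na.rm = TRUE)
    parcelMat <- ifelse(hasCrop & !is.na(cropParcelIds),
                        cropParcelIds, natPatch + offset)
  }
  layerFromMatrices(cls, parcelMat, pixelSize, xll, yll)
}

#' Per-parcel activity totals and mean rates
#'
#' Zonal statistics of a rate surface over parcels: pixels are assigned to
#' the parcel containing their center; each parcel's mean rate is the mean
#' over its unmasked pixels, and its total occurrences are reported when a
#' count raster is supplied. Parcels whose pixels are all masked are
#' recorded with `NA` mean and excluded from class summaries.
#'
#' @param rate a [GridRaster-class] of rates (occ ha^-1 night^-1).
#' @param layer a [LandCoverLayer-class] co-registered with `rate`.
#' @param counts optional co-registered [ActivityRaster-class] of raw counts.
#' @return data.frame: parcel_id, class, type, area_ha, n_pixels,
#'   n_unmasked, mean_rate, and total_occurrences if `counts` given.
#' @export
extractParcelStats <- function(rate, layer, counts = NULL) {
  checkSameGeometry(rate, layer, "rate surface and land-cover layer")
  v <- rate@values
  pid <- as.vector(layer@parcelOf)
  np <- nrow(layer@parcels)
  ok <- !is.na(v)
  nPix <- tabulate(pid, np)
  nOk <- tabulate(pid[ok], np)
  sums <- rep(0, np)
  s <- tapply(v[ok], pid[ok], sum)
  sums[as.integer(names(s))] <- s
  out <- layer@parcels
  out$n_pixels <- nPix
  out$n_unmasked <- nOk
  out$mean_rate <- ifelse(nOk > 0, sums / nOk, NA_real_)
  if (!is.null(counts)) {
    cv <- counts@values
    okc <- !is.na(cv)
    tot <- rep(0, np)
    tc <- tapply(cv[okc], pid[okc], sum)
    tot[as.integer(names(tc))] <- tc
    out$total_occurrences <- tot
  }
  out
}

#' Area-weighted class summaries with bootstrap confidence intervals
#'
#' For every land-cover class, the area-weighted mean rate over its parcels,
#' \eqn{\sum_i a_i \bar{r}_i / \sum_i a_i}, with a seeded parcel bootstrap
#' 95\% CI (parcels resampled with replacement; the area-weighted mean is
#' recomputed on each resample, since parcels -- not pixels -- are the
#' independent units). The default interval is the bootstrap standard error
#' with a Student-t quantile at the Kish effective sample size of the area
#' weights, \eqn{n_{eff} = (\sum a_i)^2 / \sum a_i^2}; skewed parcel areas
#' make \eqn{n_{eff}} much smaller than the parcel count, and the raw
#' percentile interval is then systematically narrow. `ciMethod =
#' "percentile"` gives the plain percentile interval. A study-wide row
#' ("(all)") is computed identically over all parcels. Classes with fewer
#' than two parcels get an `NA` CI.
#'
#' @param parcelStats output of [extractParcelStats()].
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param ciMethod "t" (bootstrap-SE Student-t at the effective sample
#'   size; default) or "percentile".
#' @return data.frame: class, type, mean_rate, ci_lo, ci_hi, area_ha,
#'   n_parcels; first row is the study-wide "(all)" summary.
#' @export
classSummaries <- function(parcelStats, nBoot = 1000, seed = 1,
                           conf = 0.95, ciMethod = c("t", "percentile")) {
  ciMethod <- match.arg(ciMethod)
  ps <- parcelStats[!is.na(parcelStats$mean_rate), , drop = FALSE]
  if (nrow(ps) == 0L)
    stop("no parcel has unmasked pixels; class summaries are undefined",
         call. = FALSE)
  alpha <- (1 - conf) / 2
  set.seed(seed)
  summarize <- function(sub, label, type) {
    a <- sub$area_ha; r <- sub$mean_rate
    m <- sum(a * r) / sum(a)
    if (nrow(sub) >= 2L) {
      idx <- matrix(sample.int(nrow(sub), nrow(sub) * nBoot, replace = TRUE),
                    nrow = nBoot)
      aw <- matrix(a[idx] * r[idx], nrow = nBoot)
      bm <- rowSums(aw) / rowSums(matrix(a[idx], nrow = nBoot))
      if (ciMethod == "percentile") {
        ci <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
      } else {
        nEff <- sum(a)^2 / sum(a^2)
        half <- stats::qt(1 - alpha, max(1, nEff - 1)) * stats::sd(bm)
        ci <- c(m - half, m + half)
      }
    } else ci <- c(NA_real_, NA_real_)
    data.frame(class = label, type = type, mean_rate = m,
               ci_lo = ci[1], ci_hi = ci[2], area_ha = sum(a),
               n_parcels = nrow(sub), stringsAsFactors = FALSE)
  }
  rows <- list(summarize(ps, "(all)", "(all)"))
  for (cl in sort(unique(ps$class))) {
    sub <- ps[ps$class == cl, , drop = FALSE]
    rows[[length(rows) + 1L]] <- summarize(sub, cl, sub$type[1])
  }
  do.call(rbind, rows)
}

#' Rank classes by activity and report ratios
#'
#' Orders the per-class summaries by descending mean rate (ties broken
#' alphabetically) and reports each class's ratio to the study-wide mean
#' and, for the top class, to the next-highest class -- the "rice is 1.5
#' times the next-highest class" style of statement. Ratios use unrounded
#' means.
#'
#' @param summaries output of [classSummaries()] (study-wide "(all)" row
#'   required for the ratio to the overall mean).
#' @return data.frame ordered by rank: class, mean_rate, ratio_to_overall,
#'   ratio_to_next.
#' @export
rankAndRatios <- function(summaries) {
  overall <- summaries$mean_rate[summaries$class == "(all)"]
  cls <- summaries[summaries$class != "(all)", , drop = FALSE]
  if (nrow(cls) < 1L) stop("no class rows to rank", call. = FALSE)
  ord <- order(-cls$mean_rate, cls$class)
  cls <- cls[ord, , drop = FALSE]
  nxt <- c(cls$mean_rate[-1L], NA_real_)
  data.frame(rank = seq_len(nrow(cls)),
             class = cls$class,
             mean_rate = cls$mean_rate,
             ratio_to_overall = if (length(overall))
               cls$mean_rate / overall else NA_real_,
             ratio_to_next = ifelse(is.na(nxt) | nxt == 0,
                                    ifelse(nrow(cls) == 1L, 1, NA_real_),
                                    cls$mean_rate / nxt),
             stringsAsFactors = FALSE)
}
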