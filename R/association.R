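#' @include grid-utils.R
NULL

#' Aggregate all layers to coarse cells and build the model table
#'
#' Averages bat activity, mosquito abundance, nighttime lights and
#' irrigated area over square blocks of base pixels (1 km cells for a 70 m
#' grid is a 14-pixel block, i.e. 980 m) and attaches the modal land-cover
#' class by area (ties broken alphabetically) and the cell centroid
#' coordinates. Cells with less than `minValidFrac` unmasked activity
#' pixels are dropped and counted in a message.
#'
#' @param activity [GridRaster-class] or [ActivityRaster-class]: bat
#'   activity at base resolution (rate or corrected rate surface).
#' @param mosquito [GridRaster-class]: relative mosquito abundance.
#' @param lights [GridRaster-class]: nighttime lights.
#' @param irrigated [GridRaster-class]: irrigated area, ha per pixel
#'   (summed to ha per cell).
#' @param landcover [LandCoverLayer-class].
#' @param cellSizePx block edge in base pixels (default 14, ~1 km at 70 m).
#' @param minValidFrac minimum fraction of unmasked base pixels to keep a
#'   cell (default 0.5).
#' @return data.frame with one row per retained cell: cell_id, x, y (m,
#'   cell centroids), activity, mosquito, lights, irrigated_ha, class.
#' @export
buildPixelTable <- function(activity, mosquito, lights, irrigated,
                            landcover, cellSizePx = 14,
                            minValidFrac = 0.5) {
  for (layer in list(mosquito, lights, irrigated, landcover))
    checkSameGeometry(activity, layer, "input layers")
  blk <- as.integer(cellSizePx)
  act <- blockAggregate(activity@values, blk)
  mos <- blockAggregate(mosquito@values, blk)
  lig <- blockAggregate(lights@values, blk)
  irr <- blockAggregate(irrigated@values, blk)
  cls <- blockModalClass(landcover@classOf, landcover@levels, blk)
  nrC <- nrow(act$mean); ncC <- ncol(act$mean)
  ps <- activity@pixelSize
  cx <- activity@xll + (rep(seq_len(ncC), each = nrC) - 0.5) * blk * ps
  cy <- activity@yll + (nrow(activity@values) -
          (rep(seq_len(nrC), times = ncC) - 0.5) * blk) * ps
  tab <- data.frame(cell_id = seq_len(nrC * ncC),
                    x = cx, y = cy,
                    activity = as.vector(act$mean),
                    mosquito = as.vector(mos$mean),
                    lights = as.vector(lig$mean),
                    irrigated_ha = as.vector(irr$mean) * blk^2,
                    class = as.vector(cls),
                    validFrac = as.vector(act$validFrac),
                    stringsAsFactors = FALSE)
  keep <- tab$validFrac >= minValidFrac &
    stats::complete.cases(tab[c("activity", "mosquito", "lights",
                                "irrigated_ha", "class")])
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(nDropped, " cell(s) dropped (<", round(100 * minValidFrac),
            "% unmasked area or missing covariates)")
  out <- tab[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no cell has enough unmasked area to model", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit the spatial GAM of bat activity on modeled prey density
#'
#' Gaussian generalized additive model:
#' activity ~ s(mosquito, bs = "cr", k = kMosquito) + lights +
#' irrigated_ha + class + s(x, y, bs = "gp", k = kSpace).
#' The mosquito term is a cubic regression spline allowing a nonlinear
#' activity-prey relationship; the isotropic Gaussian-process smooth over
#' the cell coordinates absorbs residual spatial autocorrelation. Land
#' cover enters as a factor with a declared reference class absorbed into
#' the intercept. Classes with fewer than `minPerClass` cells are dropped
#' with a warning (they would make the factor rank-deficient or its CI
#' meaningless).
#'
#' @param records data.frame from [buildPixelTable()].
#' @param referenceClass land-cover class used as baseline (default
#'   "miscellaneous"; falls back to the most frequent class if absent).
#' @param kMosquito basis dimension of the mosquito smooth (default 10).
#' @param kSpace basis dimension of the spatial smooth (default 50).
#' @param family model family (default [stats::gaussian()] with identity
#'   link; the activity response is a non-negative rate but is modeled on
#'   the raw scale).
#' @param minPerClass minimum cells per land-cover class (default 2).
#' @return a [GAMResult-class].
#' @export
fitGam <- function(records, referenceClass = "miscellaneous",
                   kMosquito = 10, kSpace = 50,
                   family = stats::gaussian(), minPerClass = 2) {
  need <- c("activity", "mosquito", "lights", "irrigated_ha", "class",
            "x", "y")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab <- table(records$class)
  thin <- names(tab)[tab < minPerClass]
  if (length(thin)) {
    warning("dropping class(es) with < ", minPerClass, " cells: ",
            paste(thin, collapse = ", "), call. = FALSE)
    records <- records[!records$class %in% thin, , drop = FALSE]
  }
  if (!referenceClass %in% records$class) {
    referenceClass <- names(sort(table(records$class),
                                 decreasing = TRUE))[1L]
  }
  lev <- c(referenceClass,
           sort(setdiff(unique(records$class), referenceClass)))
  records$class <- factor(records$class, levels = lev)
  # a single-class table degenerates the factor; drop the term then
  oneClass <- nlevels(records$class) == 1L
  kMosquito <- min(kMosquito,
                   max(3L, length(unique(records$mosquito)) - 1L))
  kSpace <- min(kSpace, nrow(unique(records[c("x", "y")])) - 1L)
  form <- if (oneClass)
    activity ~ s(mosquito, bs = "cr", k = kMosquito) + lights +
      irrigated_ha + s(x, y, bs = "gp", k = kSpace)
  else
    activity ~ s(mosquito, bs = "cr", k = kMosquito) + lights +
      irrigated_ha + class + s(x, y, bs = "gp", k = kSpace)
  fit <- mgcv::gam(form, data = records, family = family, method = "REML")
  sm <- summary(fit)
  pt <- sm$p.table
  est <- pt[, "Estimate"]
  se <- pt[, "Std. Error"]
  ci <- stats::qnorm(0.975) * se
  nice <- rownames(pt)
  nice <- sub("^class", "LULC: ", nice)
  terms <- data.frame(term = nice, estimate = unname(est),
                      ci_lo = unname(est - ci), ci_hi = unname(est + ci),
                      p = unname(pt[, 4]), stringsAsFactors = FALSE)
  st <- sm$s.table
  smooths <- data.frame(term = rownames(st), edf = unname(st[, "edf"]),
                        p = unname(st[, "p-value"]),
                        stringsAsFactors = FALSE)
  new("GAMResult", terms = terms, smooths = smooths,
      r2 = unname(sm$r.sq), n = as.integer(nrow(records)),
      referenceClass = referenceClass, fit = fit)
}

#' Partial effect of the mosquito smooth
#'
#' Evaluates the fitted smooth of mosquito abundance (centered, other
#' covariates held out) on a grid or at supplied values -- the curve used
#' to judge whether bat activity rises where modeled prey density is high.
#'
#' @param result a [GAMResult-class].
#' @param at mosquito-abundance values; default an even grid over the
#'   fitted range.
#' @param n grid size when `at` is NULL.
#' @return data.frame: mosquito, effect.
#' @export
mosquitoEffect <- function(result, at = NULL, n = 200) {
  fit <- result@fit
  mf <- fit$model
  if (is.null(at))
    at <- seq(min(mf$mosquito), max(mf$mosquito), length.out = n)
  base <- mf[1L, , drop = FALSE]
  nd <- base[rep(1L, length(at)), , drop = FALSE]
  nd$mosquito <- at
  pt <- stats::predict(fit, newdata = nd, type = "terms")
  col <- grep("s\\(mosquito\\)", colnames(pt))
  data.frame(mosquito = at, effect = as.numeric(pt[, col]))
}

#' Lay out a fitted model as a report table
#'
#' Orders the parametric rows (intercept, nighttime lights, irrigated area,
#' land-cover classes) followed by the smooth terms, with the observation
#' count, adjusted R-squared and reference class appended -- the
#' conventional presentation of this model family. Returns the table
#' invisibly and optionally writes TSV and JSON renderings.
#'
#' @param result a [GAMResult-class].
#' @param file optional path stem; writes `<file>.tsv` and `<file>.json`.
#' @return data.frame of the rendered rows (invisible).
#' @export
summarizeFit <- function(result, file = NULL) {
  tt <- result@terms
  ord <- c(grep("Intercept", tt$term),
           grep("^lights$", tt$term),
           grep("^irrigated_ha$", tt$term),
           sort(grep("^LULC: ", tt$term)))
  ord <- c(ord, setdiff(seq_len(nrow(tt)), ord))
  tt <- tt[ord, , drop = FALSE]
  rows <- data.frame(predictor = tt$term,
                     estimate = sprintf("%.2f", tt$estimate),
                     ci = sprintf("%.2f - %.2f", tt$ci_lo, tt$ci_hi),
                     p = ifelse(tt$p < 0.001, "<0.001",
                                sprintf("%.3f", tt$p)),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(result@smooths)))
    rows <- rbind(rows, data.frame(
      predictor = paste("Smooth term:", result@smooths$term[i]),
      estimate = "", ci = "",
      p = ifelse(result@smooths$p[i] < 0.001, "<0.001",
                 sprintf("%.3f", result@smooths$p[i]))))
  rows <- rbind(rows,
                data.frame(predictor = "Observations",
                           estimate = as.character(result@n), ci = "", p = ""),
                data.frame(predictor = "Adjusted R-squared",
                           estimate = sprintf("%.3f", result@r2),
                           ci = "", p = ""),
                data.frame(predictor = "Reference class",
                           estimate = result@referenceClass,
                           ci = "", p = ""))
  if (!is.null(file)) {
    utils::write.table(rows, paste0(file, ".tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    payload <- list(terms = result@terms, smooths = result@smooths,
                    n = result@n, r2 = result@r2,
                    reference_class = result@referenceClass)
    jsonlite::write_json(payload, paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(rows)
}
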