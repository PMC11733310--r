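#' @include grid-utils.R
NULL

#' Write a raster to an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values north to south. `NA` is written as the nodata value.
#'
#' @param raster a [GridRaster-class] (or subclass).
#' @param path output file path (conventionally `.asc`).
#' @param nodata nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(raster, path, nodata = -9999) {
  v <- raster@values
  hdr <- c(paste("ncols", ncol(v)),
           paste("nrows", nrow(v)),
           paste("xllcorner", format(raster@xll, scientific = FALSE)),
           paste("yllcorner", format(raster@yll, scientific = FALSE)),
           paste("cellsize", format(raster@pixelSize, scientific = FALSE)),
           paste("NODATA_value", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 10),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [writeAsciiGrid()] (or any conforming ASCII
#'   grid).
#' @return a [GridRaster-class]; nodata cells become `NA`.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("not an ASCII grid: missing header field(s)", call. = FALSE)
  body <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  m <- do.call(rbind, body)
  if (!identical(dim(m), c(as.integer(vals["nrows"]),
                           as.integer(vals["ncols"]))))
    stop("ASCII grid body does not match its header dimensions",
         call. = FALSE)
  m[m == vals["nodata_value"]] <- NA_real_
  gridRaster(m, pixelSize = unname(vals["cellsize"]),
             xll = unname(vals["xllcorner"]),
             yll = unname(vals["yllcorner"]))
}

#' Read roost locations from a CSV with x,y columns
#'
#' @param path CSV file with columns `x`, `y` (projected meters) and
#'   optionally `weight`.
#' @return a [RoostSet-class].
#' @export
readRoosts <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(tab)))
    stop("roost file needs columns 'x' and 'y'", call. = FALSE)
  roostSet(cbind(x = tab$x, y = tab$y),
           weights = if ("weight" %in% names(tab)) tab$weight else NULL)
}

#' Write roost locations to CSV
#'
#' @param roosts a [RoostSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRoosts <- function(roosts, path) {
  utils::write.csv(data.frame(x = roosts@coords[, 1],
                              y = roosts@coords[, 2],
                              weight = roosts@weights),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a land-cover layer as plain-text rasters plus a parcel table
#'
#' Writes `<stem>_class.asc` (class index grid), `<stem>_parcel.asc`
#' (parcel id grid), and `<stem>_parcels.tsv` (parcel attributes including
#' the class-index legend).
#'
#' @param layer a [LandCoverLayer-class].
#' @param stem path stem.
#' @return character vector of the files written, invisibly.
#' @export
writeLandCover <- function(layer, stem) {
  f1 <- paste0(stem, "_class.asc")
  f2 <- paste0(stem, "_parcel.asc")
  f3 <- paste0(stem, "_parcels.tsv")
  writeAsciiGrid(gridRaster(layer@classOf + 0, pixelSize = layer@pixelSize,
                            xll = layer@xll, yll = layer@yll), f1)
  writeAsciiGrid(gridRaster(layer@parcelOf + 0, pixelSize = layer@pixelSize,
                            xll = layer@xll, yll = layer@yll), f2)
  tab <- layer@parcels
  tab$class_index <- match(tab$class, layer@levels)
  utils::write.table(tab, f3, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2, f3))
}
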