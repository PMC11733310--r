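#' @include AllClasses.R grid-utils.R
NULL

#' Briere thermal performance curve
#'
#' \eqn{c\,T\,(T - Tmin)\sqrt{Tmax - T}} on \eqn{[Tmin, Tmax]}, exactly zero
#' outside; the asymmetric unimodal form typical of development-rate and
#' fecundity traits.
#'
#' @param temp temperature(s), degrees C (vectorized).
#' @param c scale constant, > 0.
#' @param Tmin,Tmax thermal limits, Tmin < Tmax.
#' @return trait value(s), >= 0.
#' @export
briere <- function(temp, c, Tmin, Tmax) {
  stopifnot(Tmin < Tmax)
  inside <- !is.na(temp) & temp > Tmin & temp < Tmax
  out <- numeric(length(temp))
  out[is.na(temp)] <- NA_real_
  tt <- temp[inside]
  out[inside] <- pmax(0, c * tt * (tt - Tmin) * sqrt(Tmax - tt))
  if (is.matrix(temp)) out <- matrix(out, nrow = nrow(temp))
  out
}

#' Quadratic thermal performance curve
#'
#' \eqn{c\,(T - Tmin)(Tmax - T)} on \eqn{[Tmin, Tmax]}, exactly zero
#' outside; symmetric with its peak at the midpoint of the thermal limits.
#'
#' @inheritParams briere
#' @return trait value(s), >= 0.
#' @export
quadraticTPC <- function(temp, c, Tmin, Tmax) {
  stopifnot(Tmin < Tmax)
  inside <- !is.na(temp) & temp > Tmin & temp < Tmax
  out <- numeric(length(temp))
  out[is.na(temp)] <- NA_real_
  tt <- temp[inside]
  out[inside] <- pmax(0, c * (tt - Tmin) * (Tmax - tt))
  if (is.matrix(temp)) out <- matrix(out, nrow = nrow(temp))
  out
}

#' Construct a TraitCurve
#'
#' @param trait trait name ("EFD", "pEA", "MDR", "lf" or "mu").
#' @param form "briere", "quadratic" or "constant".
#' @param c scale constant (> 0); for the constant form this is the value.
#' @param Tmin,Tmax thermal limits, degrees C (ignored for constant form).
#' @return a [TraitCurve-class].
#' @export
traitCurve <- function(trait, form, c, Tmin = 0, Tmax = 1) {
  new("TraitCurve", trait = trait, form = form, c = c,
      Tmin = Tmin, Tmax = Tmax)
}

#' @rdname evalCurve
#' @aliases evalCurve,TraitCurve-method
setMethod("evalCurve", "TraitCurve", function(curve, temp) {
  switch(curve@form,
         briere = briere(temp, curve@c, curve@Tmin, curve@Tmax),
         quadratic = quadraticTPC(temp, curve@c, curve@Tmin, curve@Tmax),
         constant = {
           out <- rep(curve@c, length(temp))
           out[is.na(temp)] <- NA_real_
           if (is.matrix(temp)) out <- matrix(out, nrow = nrow(temp))
           out
         })
})

#' Construct AbundanceParams
#'
#' @param curves named list of [TraitCurve-class]; must contain EFD, pEA,
#'   MDR and either mu (adult mortality, day^-1) or lf (adult lifespan,
#'   days, inverted internally).
#' @param muFloor mortality-rate floor, day^-1 (default 0.01) keeping the
#'   index finite where the lifespan curve approaches its thermal limits.
#' @return an [AbundanceParams-class].
#' @export
abundanceParams <- function(curves, muFloor = 0.01) {
  new("AbundanceParams", curves = curves, muFloor = muFloor)
}

#' Read trait-curve parameters from a TSV configuration
#'
#' The trait configuration is an editable tab-separated table with columns
#' `trait`, `form`, `c`, `Tmin`, `Tmax`. The shipped default
#' (`culex_tarsalis_traits.tsv`) carries Briere/quadratic parameters in the
#' style of published *Culex tarsalis* trait fits.
#'
#' @param path TSV file; default is the shipped table.
#' @param muFloor mortality floor passed to [abundanceParams()].
#' @return an [AbundanceParams-class].
#' @export
readTraitConfig <- function(path = system.file("extdata",
                                               "culex_tarsalis_traits.tsv",
                                               package = "batscape"),
                            muFloor = 0.01) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("trait", "form", "c", "Tmin", "Tmax")
  if (!all(need %in% names(tab)))
    stop("trait table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  curves <- lapply(seq_len(nrow(tab)), function(i)
    traitCurve(tab$trait[i], tab$form[i], tab$c[i], tab$Tmin[i], tab$Tmax[i]))
  names(curves) <- tab$trait
  abundanceParams(curves, muFloor = muFloor)
}

#' Relative mosquito abundance index M(T)
#'
#' Composition of temperature-dependent life-history traits used as a
#' relative (unitless) abundance proxy:
#' \deqn{M(T) = \frac{EFD(T)\,pEA(T)\,MDR(T)}{\max(\mu(T), floor)^2}}
#' where EFD is eggs per female per day, pEA egg-to-adult survival, MDR the
#' development rate and \eqn{\mu} adult mortality (day^-1, taken as
#' 1/lifespan when an "lf" curve is supplied; infinite -- hence M = 0 in the
#' numerator-positive case never arises -- outside the lifespan support).
#' M is zero wherever any numerator trait is zero, so it vanishes outside
#' the intersection of the trait thermal supports. Being relative, it is
#' only defined up to a monotone rescaling; downstream smooth-term use is
#' invariant to that.
#'
#' @param temp temperature(s), degrees C (vectorized; matrix in, matrix out).
#' @param params an [AbundanceParams-class].
#' @return index value(s), >= 0.
#' @export
relativeAbundance <- function(temp, params) {
  stopifnot(is(params, "AbundanceParams"))
  num <- evalCurve(params@curves[["EFD"]], temp) *
         evalCurve(params@curves[["pEA"]], temp) *
         evalCurve(params@curves[["MDR"]], temp)
  if ("mu" %in% names(params@curves)) {
    mu <- evalCurve(params@curves[["mu"]], temp)
  } else {
    lf <- evalCurve(params@curves[["lf"]], temp)
    mu <- ifelse(!is.na(lf) & lf > 0, 1 / lf, Inf)
  }
  mu <- pmax(mu, params@muFloor)
  out <- num / mu^2
  out[!is.na(num) & num == 0] <- 0   # mu = Inf outside lf support
  if (is.matrix(temp)) out <- matrix(out, nrow = nrow(temp))
  out
}

#' Seasonal mean abundance surface from a temperature stack
#'
#' Evaluates M(T) per pixel per time step and averages over the season.
#' Missing temperatures propagate as missing.
#'
#' @param tempStack list of co-registered temperature matrices (degrees C),
#'   or a 3-d array with time as the third dimension.
#' @param params an [AbundanceParams-class].
#' @param pixelSize,xll,yll grid geometry for the output raster.
#' @return a [GridRaster-class]: seasonal mean of M(T).
#' @export
abundanceRaster <- function(tempStack, params, pixelSize = 70,
                            xll = 0, yll = 0) {
  if (is.array(tempStack) && length(dim(tempStack)) == 3L)
    tempStack <- lapply(seq_len(dim(tempStack)[3]),
                        function(k) tempStack[, , k])
  if (length(tempStack) == 0L)
    stop("temperature stack is empty", call. = FALSE)
  acc <- 0
  for (tm in tempStack) {
    if (!identical(dim(tm), dim(tempStack[[1L]])))
      stop("temperature stack layers differ in shape", call. = FALSE)
    acc <- acc + relativeAbundance(tm, params)
  }
  gridRaster(acc / length(tempStack), pixelSize = pixelSize,
             xll = xll, yll = yll)
}
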