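#' Accessors for pixel maps and related containers
#'
#' `mapValues()` returns the matrix of per-pixel values, `mapValid()` the
#' logical validity mask, and `pixelLength()` the pixel edge length in
#' micrometres. These are the supported way to read the pipeline's map
#' objects; slots are internal.
#'
#' @param x a [PixelMap-class] derivative, [HyperspectralStack-class] or
#'   [SceneTruth-class].
#' @return `mapValues()`: numeric matrix; `mapValid()`: logical matrix;
#'   `pixelLength()`: numeric scalar (um) or `NA`.
#' @aliases mapValues mapValid pixelLength
#' @name map-accessors
#' @examples
#' h <- HueMap(matrix(0.3, 2, 2))
#' mapValues(h)
#' mapValid(h)
#' @export mapValues
#' @export mapValid
#' @export pixelLength
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname map-accessors
setGeneric("mapValid", function(x) standardGeneric("mapValid"))

#' @rdname map-accessors
setGeneric("pixelLength", function(x) standardGeneric("pixelLength"))

setMethod("mapValues", "PixelMap", function(x) x@values)
setMethod("mapValid", "PixelMap", function(x) x@valid)
setMethod("pixelLength", "PixelMap", function(x) x@pixelLength)
setMethod("pixelLength", "HyperspectralStack", function(x) x@pixelLength)
setMethod("pixelLength", "SceneTruth", function(x) x@pixelLength)
setMethod("mapValues", "SceneTruth", function(x) x@displacement)

#' Wavelength axis of spectral containers
#'
#' @param x a [HyperspectralStack-class] or [CameraModel-class].
#' @return numeric vector of wavelengths in nm, strictly increasing.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

setMethod("wavelengths", "HyperspectralStack", function(x) x@wavelengths)
setMethod("wavelengths", "CameraModel", function(x) x@wavelengths)

#' @describeIn ForceTrace-class sample times (s)
#' @param x a `ForceTrace`.
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
setMethod("traceTimes", "ForceTrace", function(x) x@times)

#' @describeIn ForceTrace-class force values (nN)
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
setMethod("traceValues", "ForceTrace", function(x) x@values)

#' @describeIn ForceTrace-class per-beat annotations (data.frame)
#' @export
setGeneric("traceBeats", function(x) standardGeneric("traceBeats"))
setMethod("traceBeats", "ForceTrace", function(x) x@beats)

#' @describeIn ForceTrace-class per-beat phase durations (data.frame)
#' @export
setGeneric("tracePhases", function(x) standardGeneric("tracePhases"))
setMethod("tracePhases", "ForceTrace", function(x) x@phases)

#' @describeIn CalibrationCurve-class knots as a two-column data.frame
#'   (`hue`, `wavelength_nm`)
#' @param x a `CalibrationCurve`.
#' @export
setGeneric("calibrationKnots", function(x) standardGeneric("calibrationKnots"))
setMethod("calibrationKnots", "CalibrationCurve", function(x)
  data.frame(hue = x@hue, wavelength_nm = x@wavelength))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SubstrateSpec", function(object) {
  cat("SubstrateSpec\n")
  cat(sprintf("  D      : %g um\n", object@restD))
  cat(sprintf("  E      : %g Pa\n", object@youngsE))
  cat(sprintf("  nu     : %g\n", object@poissonNu))
  cat(sprintf("  lambda0: %g nm\n", object@lambda0))
  if (is.finite(object@d111))
    cat(sprintf("  d111   : %g nm, n_avg %g, theta %g rad\n",
                object@d111, object@nAverage, object@theta))
  invisible(NULL)
})

setMethod("show", "CameraModel", function(object) {
  w <- object@wavelengths
  cat(sprintf("CameraModel: %d-bit, axis %g-%g nm (%d samples)\n",
              object@bitDepth, min(w), max(w), length(w)))
  cat(sprintf("  read noise %g of full scale, exposure %g, WB [%s]\n",
              object@readNoiseSigma, object@exposure,
              paste(signif(object@whiteBalance, 3), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "PixelMap", function(object) {
  v <- object@values[object@valid]
  cat(sprintf("%s: %d x %d pixels, %d valid (%.1f%%)\n",
              class(object), nrow(object@values), ncol(object@values),
              sum(object@valid),
              100 * mean(object@valid)))
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g]", min(v), max(v)))
  if (!is.na(object@pixelLength))
    cat(sprintf("  pixel %.3g um", object@pixelLength))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "HyperspectralStack", function(object) {
  d <- dim(object@cube)
  cat(sprintf("HyperspectralStack: %d x %d pixels, %d wavelengths (%g-%g nm)\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
  invisible(NULL)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: %d knots, hue [%.4f, %.4f] -> %s in wavelength (%g-%g nm)\n",
              length(object@hue), min(object@hue), max(object@hue),
              if (object@wavelength[length(object@wavelength)] >
                  object@wavelength[1]) "increasing" else "decreasing",
              min(object@wavelength), max(object@wavelength)))
  invisible(NULL)
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d x %d pixels, dD range [%.3f, %.3f] um, seed %d\n",
              nrow(object@displacement), ncol(object@displacement),
              min(object@displacement), max(object@displacement),
              object@seed))
  invisible(NULL)
})

setMethod("show", "ForceTrace", function(object) {
  cat(sprintf("ForceTrace: %d frames at %.4g s, force range [%.3g, %.3g] nN",
              length(object@values), object@frameInterval,
              min(object@values), max(object@values)))
  if (nrow(object@beats))
    cat(sprintf(", %d beats", nrow(object@beats)))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "TensorField", function(object) {
  cat(sprintf("%s: %d x %d grid, spacing %g um\n", class(object),
              nrow(object@xx), ncol(object@xx), object@spacing))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## constructors
## ---------------------------------------------------------------------------

#' Construct a substrate specification
#'
#' Defaults match a polyacrylamide photonic-crystal film: 24 um thick,
#' E = 20 kPa, nu = 0.49, unstrained green reflection peak at 550 nm.
#'
#' @param restD unstrained thickness D, um.
#' @param youngsE Young's modulus E, Pa.
#' @param poissonNu Poisson ratio nu in `[0, 0.5)`.
#' @param lambda0 unstrained reflection peak wavelength, nm.
#' @param d111 optional (111) interplanar distance, nm.
#' @param nAverage optional average refractive index.
#' @param theta incidence angle, rad (default 0, normal incidence).
#' @return a validated [SubstrateSpec-class].
#' @examples
#' SubstrateSpec()                        # the default 24 um / 20 kPa film
#' SubstrateSpec(lambda0 = 549.92, d111 = 196.4, nAverage = 1.40)
#' @export
SubstrateSpec <- function(restD = 24, youngsE = 20e3, poissonNu = 0.49,
                          lambda0 = 550, d111 = NA_real_,
                          nAverage = NA_real_, theta = 0) {
  new("SubstrateSpec", restD = as.numeric(restD),
      youngsE = as.numeric(youngsE), poissonNu = as.numeric(poissonNu),
      lambda0 = as.numeric(lambda0), d111 = as.numeric(d111),
      nAverage = as.numeric(nAverage), theta = as.numeric(theta))
}

.mkMap <- function(class, values, valid = NULL, pixelLength = NA_real_) {
  values <- as.matrix(values)
  if (is.null(valid)) valid <- !is.na(values)
  storage.mode(values) <- "double"
  new(class, values = values, valid = valid,
      pixelLength = as.numeric(pixelLength))
}

#' Construct pixel map objects
#'
#' Thin constructors for the concrete [PixelMap-class] types. `valid`
#' defaults to `!is.na(values)`.
#'
#' @param values numeric matrix.
#' @param valid logical matrix of the same shape, or `NULL`.
#' @param pixelLength pixel edge length, um, or `NA`.
#' @return a validated map object of the corresponding class.
#' @name map-constructors
#' @examples
#' WavelengthMap(matrix(550, 4, 4), pixelLength = 0.18)
#' @export
HueMap <- function(values, valid = NULL, pixelLength = NA_real_)
  .mkMap("HueMap", values, valid, pixelLength)

#' @rdname map-constructors
#' @export
WavelengthMap <- function(values, valid = NULL, pixelLength = NA_real_)
  .mkMap("WavelengthMap", values, valid, pixelLength)

#' @rdname map-constructors
#' @export
DisplacementMap <- function(values, valid = NULL, pixelLength = NA_real_)
  .mkMap("DisplacementMap", values, valid, pixelLength)

#' @rdname map-constructors
#' @export
StressMap <- function(values, valid = NULL, pixelLength = NA_real_)
  .mkMap("StressMap", values, valid, pixelLength)

#' @rdname map-constructors
#' @export
VelocityMap <- function(values, valid = NULL, pixelLength = NA_real_)
  .mkMap("VelocityMap", values, valid, pixelLength)

#' Construct a hyperspectral stack
#'
#' @param cube numeric array `(rows, cols, n_wavelengths)`.
#' @param wavelengths strictly increasing wavelength axis, nm.
#' @param background background spectrum (length `n_wavelengths`) or
#'   per-pixel background array shaped like `cube`.
#' @param pixelLength pixel edge length, um, or `NA`.
#' @return a validated [HyperspectralStack-class].
#' @export
HyperspectralStack <- function(cube, wavelengths, background,
                               pixelLength = NA_real_) {
  new("HyperspectralStack", cube = cube,
      wavelengths = as.numeric(wavelengths),
      background = as.numeric(background),
      pixelLength = as.numeric(pixelLength))
}

#' Construct a force trace
#'
#' @param values force per frame, nN.
#' @param frameInterval spacing between frames, s.
#' @param times optional explicit times; default `(0:(n-1)) * frameInterval`.
#' @return a [ForceTrace-class] without beat annotations.
#' @export
ForceTrace <- function(values, frameInterval, times = NULL) {
  values <- as.numeric(values)
  if (is.null(times))
    times <- (seq_along(values) - 1) * frameInterval
  new("ForceTrace", times = as.numeric(times), values = values,
      frameInterval = as.numeric(frameInterval))
}
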