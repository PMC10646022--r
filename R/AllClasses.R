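#' @import methods
NULL

## ---------------------------------------------------------------------------
## SubstrateSpec
## ---------------------------------------------------------------------------

#' Physical and optical description of a photonic-crystal substrate
#'
#' Ties the structural color of the substrate to its mechanics: the film
#' thickness \eqn{D}, the elastic constants \eqn{E} and \eqn{\nu}, and the
#' unstrained reflection peak wavelength \eqn{\lambda_0}. Optionally carries
#' the Bragg parameters (interplanar spacing of the (111) planes, average
#' refractive index, incidence angle); when both `d111` and `nAverage` are
#' set, \eqn{\lambda_0} must agree with the Bragg condition
#' \eqn{\lambda = 2 d_{111}\sqrt{n^2 - \sin^2\theta}} within 1 nm.
#'
#' @slot restD unstrained film thickness, micrometres.
#' @slot youngsE Young's modulus, pascals.
#' @slot poissonNu Poisson ratio, dimensionless, in `[0, 0.5)`.
#' @slot lambda0 unstrained reflection peak wavelength, nanometres.
#' @slot d111 interplanar distance of the (111) diffraction planes,
#'   nanometres, or `NA` when unknown.
#' @slot nAverage average refractive index of the photonic crystal, or `NA`.
#' @slot theta angle between incident light and the surface normal, radians.
#'
#' @seealso [SubstrateSpec()] for the user-facing constructor,
#'   [braggPeakWavelength()], [displacementMap()], [verticalStressMap()].
#' @exportClass SubstrateSpec
setClass("SubstrateSpec",
  representation(
    restD     = "numeric",
    youngsE   = "numeric",
    poissonNu = "numeric",
    lambda0   = "numeric",
    d111      = "numeric",
    nAverage  = "numeric",
    theta     = "numeric"
  ),
  prototype(
    restD = 24, youngsE = 20e3, poissonNu = 0.49, lambda0 = 550,
    d111 = NA_real_, nAverage = NA_real_, theta = 0
  )
)

setValidity("SubstrateSpec", function(object) {
  msg <- character()
  if (length(object@restD) != 1L || !is.finite(object@restD) ||
      object@restD <= 0)
    msg <- c(msg, "restD must be a single positive number (um)")
  if (length(object@youngsE) != 1L || !is.finite(object@youngsE) ||
      object@youngsE <= 0)
    msg <- c(msg, "youngsE must be a single positive number (Pa)")
  if (length(object@poissonNu) != 1L || !is.finite(object@poissonNu) ||
      object@poissonNu < 0 || object@poissonNu >= 0.5)
    msg <- c(msg, "poissonNu must lie in [0, 0.5)")
  if (length(object@lambda0) != 1L || !is.finite(object@lambda0) ||
      object@lambda0 < 400 || object@lambda0 > 700)
    msg <- c(msg, "lambda0 must lie in [400, 700] nm")
  if (length(object@theta) != 1L || object@theta < 0 ||
      object@theta >= pi / 2)
    msg <- c(msg, "theta must lie in [0, pi/2)")
  if (is.finite(object@d111) && is.finite(object@nAverage)) {
    lam <- 2 * object@d111 *
      sqrt(object@nAverage^2 - sin(object@theta)^2)
    if (abs(lam - object@lambda0) > 1)
      msg <- c(msg, sprintf(
        "lambda0 (%.2f nm) disagrees with the Bragg condition (%.2f nm) by more than 1 nm",
        object@lambda0, lam))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CameraModel
## ---------------------------------------------------------------------------

#' Spectral model of the color camera
#'
#' Holds the three channel spectral sensitivity curves (R, G, B) and the
#' illuminant spectral power on a shared, strictly increasing wavelength
#' axis, together with bit depth, read noise, white-balance gains and an
#' exposure scale. Hue-based wavelength readout requires spectral crosstalk:
#' the sensitivity curves must pairwise overlap on the working band
#' (510--570 nm), which the validity method enforces.
#'
#' @slot wavelengths shared wavelength axis, nm, strictly increasing.
#' @slot sensitivities numeric matrix, `length(wavelengths)` rows by 3
#'   columns (R, G, B), nonnegative.
#' @slot illuminant relative spectral power of the light source on the same
#'   axis, nonnegative.
#' @slot bitDepth 8 or 16.
#' @slot readNoiseSigma additive Gaussian read noise, as a fraction of full
#'   scale (0 disables noise).
#' @slot whiteBalance three positive channel gains.
#' @slot exposure scalar gain applied to linear intensities before
#'   quantization.
#'
#' @seealso [defaultCameraModel()], [renderRGB()].
#' @exportClass CameraModel
setClass("CameraModel",
  representation(
    wavelengths    = "numeric",
    sensitivities  = "matrix",
    illuminant     = "numeric",
    bitDepth       = "integer",
    readNoiseSigma = "numeric",
    whiteBalance   = "numeric",
    exposure       = "numeric"
  )
)

setValidity("CameraModel", function(object) {
  msg <- character()
  w <- object@wavelengths
  if (length(w) < 2L || any(diff(w) <= 0))
    msg <- c(msg, "wavelength axis must be strictly increasing")
  s <- object@sensitivities
  if (!is.numeric(s) || nrow(s) != length(w) || ncol(s) != 3L)
    msg <- c(msg, "sensitivities must be a length(wavelengths) x 3 matrix")
  else {
    if (any(s < 0)) msg <- c(msg, "sensitivities must be nonnegative")
    band <- w >= 510 & w <= 570
    if (any(band)) {
      for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
        ov <- sum(s[band, pair[1]] * s[band, pair[2]])
        if (!is.na(ov) && ov <= 0)
          msg <- c(msg, sprintf(
            "channels %d and %d have no spectral overlap on 510-570 nm (crosstalk required)",
            pair[1], pair[2]))
      }
    }
  }
  if (length(object@illuminant) != length(w) || any(object@illuminant < 0))
    msg <- c(msg, "illuminant must be nonnegative on the wavelength axis")
  if (!object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (object@readNoiseSigma < 0)
    msg <- c(msg, "readNoiseSigma must be >= 0")
  if (length(object@whiteBalance) != 3L || any(object@whiteBalance <= 0))
    msg <- c(msg, "whiteBalance must be three positive gains")
  if (length(object@exposure) != 1L || object@exposure <= 0)
    msg <- c(msg, "exposure must be a positive scalar")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Pixel maps
## ---------------------------------------------------------------------------

#' Per-pixel scalar fields with validity masks
#'
#' `PixelMap` is the virtual parent of the pipeline's scalar fields:
#' [HueMap-class] (HSV hue in `[0,1)`), [WavelengthMap-class] (reflection
#' peak wavelength, nm), [DisplacementMap-class] (vertical substrate
#' deformation \eqn{\Delta D}, micrometres, positive = upward pull) and
#' [StressMap-class] (vertical traction \eqn{T_z}, pascals, positive =
#' upward). Each carries a matrix of values, a logical validity mask of the
#' same shape, and the physical pixel edge length in micrometres (`NA` when
#' not calibrated).
#'
#' @slot values numeric matrix of per-pixel values.
#' @slot valid logical matrix marking pixels that carry meaningful values.
#' @slot pixelLength pixel edge length, micrometres (`NA_real_` if unknown).
#'
#' @aliases HueMap-class WavelengthMap-class DisplacementMap-class
#'   StressMap-class VelocityMap-class
#' @seealso [mapValues()], [mapValid()], [pixelLength()].
#' @exportClass PixelMap
#' @exportClass HueMap
#' @exportClass WavelengthMap
#' @exportClass DisplacementMap
#' @exportClass StressMap
#' @exportClass VelocityMap
setClass("PixelMap",
  representation(
    values      = "matrix",
    valid       = "matrix",
    pixelLength = "numeric",
    "VIRTUAL"
  ),
  prototype(pixelLength = NA_real_)
)

setValidity("PixelMap", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (!is.logical(object@valid))
    msg <- c(msg, "valid must be a logical matrix")
  if (!identical(dim(object@values), dim(object@valid)))
    msg <- c(msg, "values and valid must have identical dimensions")
  if (length(object@pixelLength) != 1L ||
      (!is.na(object@pixelLength) && object@pixelLength <= 0))
    msg <- c(msg, "pixelLength must be a single positive number or NA")
  if (length(msg)) msg else TRUE
})

setClass("HueMap", contains = "PixelMap")
setValidity("HueMap", function(object) {
  v <- object@values[object@valid]
  if (any(v < 0 | v >= 1, na.rm = TRUE))
    "valid hue values must lie in [0, 1)" else TRUE
})

setClass("WavelengthMap", contains = "PixelMap")
setClass("DisplacementMap", contains = "PixelMap")
setClass("StressMap", contains = "PixelMap")
setClass("VelocityMap", contains = "PixelMap")

## ---------------------------------------------------------------------------
## HyperspectralStack
## ---------------------------------------------------------------------------

#' Wavelength-indexed intensity cube with background spectrum
#'
#' Stores a hyperspectral acquisition \eqn{I(\lambda, x, y)} as an array with
#' dimensions `(rows, cols, wavelengths)`, the strictly increasing wavelength
#' axis, and the background spectrum \eqn{I_{bg}(\lambda)} used to derive
#' reflection spectra \eqn{R = I/I_{bg} - 1} (either one spectrum for the
#' whole field, or a per-pixel background array of the same shape as the
#' cube).
#'
#' @slot wavelengths wavelength axis, nm, strictly increasing.
#' @slot cube numeric array `(rows, cols, n_wavelengths)`.
#' @slot background numeric vector of length `n_wavelengths`, or an array
#'   shaped like `cube`.
#' @slot pixelLength pixel edge length, micrometres, or `NA`.
#'
#' @seealso [makeHyperspectralStack()], [reflectionSpectra()],
#'   [peakWavelengthMap()].
#' @exportClass HyperspectralStack
setClass("HyperspectralStack",
  representation(
    wavelengths = "numeric",
    cube        = "array",
    background  = "numeric",
    pixelLength = "numeric"
  ),
  prototype(pixelLength = NA_real_)
)

setValidity("HyperspectralStack", function(object) {
  msg <- character()
  w <- object@wavelengths
  if (length(w) < 1L || any(diff(w) <= 0))
    msg <- c(msg, "wavelength axis must be strictly increasing")
  d <- dim(object@cube)
  if (length(d) != 3L)
    msg <- c(msg, "cube must be a 3-d array (rows, cols, wavelengths)")
  else if (d[3] != length(w))
    msg <- c(msg, "third cube dimension must match the wavelength axis")
  bg <- object@background
  if (!(length(bg) == length(w) || identical(dim(bg), d)))
    msg <- c(msg, "background must be one spectrum or a per-pixel array")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CalibrationCurve
## ---------------------------------------------------------------------------

#' Monotone hue-to-wavelength lookup table
#'
#' The bridge from camera color to physics: an ordered set of
#' `(hue, wavelength)` knots, strictly monotone in hue and strictly monotone
#' (increasing or decreasing, consistently) in wavelength, built from paired
#' hue and reference peak-wavelength maps of a gradient-deformed substrate.
#' For green-to-yellow substrates the curve decreases: longer wavelengths
#' map to smaller hue.
#'
#' @slot hue knot hue values, strictly increasing, in `[0, 1)`.
#' @slot wavelength knot wavelengths, nm, strictly monotone.
#' @slot provenance list of free-form provenance fields (source, date,
#'   bin width, number of pairs, ...).
#'
#' @seealso [buildCalibration()], [lookupWavelength()],
#'   [writeCalibration()], [readCalibration()].
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(
    hue        = "numeric",
    wavelength = "numeric",
    provenance = "list"
  ),
  prototype(provenance = list())
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  h <- object@hue; w <- object@wavelength
  if (length(h) < 2L)
    msg <- c(msg, "calibration needs at least 2 knots")
  if (length(h) != length(w))
    msg <- c(msg, "hue and wavelength knot vectors must have equal length")
  if (any(h < 0 | h >= 1))
    msg <- c(msg, "hue knots must lie in [0, 1)")
  if (length(h) >= 2L) {
    if (any(diff(h) <= 0))
      msg <- c(msg, "hue knots must be strictly increasing")
    dw <- diff(w)
    if (!(all(dw > 0) || all(dw < 0)))
      msg <- c(msg, "wavelength knots must be strictly monotone in one direction")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SceneTruth
## ---------------------------------------------------------------------------

#' Ground-truth deformation scene from the synthetic generator
#'
#' A known vertical displacement field \eqn{\Delta D(x,y)} (micrometres,
#' signed, positive = pull) with the substrate description, pixel size, the
#' seed and the generator parameters needed to reproduce it bit-for-bit.
#'
#' @slot displacement numeric matrix of \eqn{\Delta D} per pixel, um.
#' @slot pixelLength pixel edge length, um.
#' @slot substrate the [SubstrateSpec-class] the scene was built for.
#' @slot seed integer seed used by the generator.
#' @slot params list of the generator parameters.
#'
#' @seealso [makeCellScene()], [makeAggregateScene()].
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(
    displacement = "matrix",
    pixelLength  = "numeric",
    substrate    = "SubstrateSpec",
    seed         = "integer",
    params       = "list"
  )
)

setValidity("SceneTruth", function(object) {
  msg <- character()
  if (any(abs(object@displacement) >= object@substrate@restD))
    msg <- c(msg, "|displacement| must stay below the rest thickness D")
  if (length(object@pixelLength) != 1L || object@pixelLength <= 0)
    msg <- c(msg, "pixelLength must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ForceTrace
## ---------------------------------------------------------------------------

#' Time series of integrated vertical force with beat annotations
#'
#' Total vertically directed force in a field of view (or ROI) sampled at a
#' constant frame interval, optionally annotated with detected beats (onset,
#' peak, end) and per-beat systolic/diastolic/static phase durations.
#'
#' @slot times sample times, seconds, strictly increasing, constant spacing.
#' @slot values force at each sample, nanonewtons.
#' @slot frameInterval spacing between samples, seconds.
#' @slot beats data.frame with one row per detected beat: `beat`, `onset_s`,
#'   `peak_s`, `end_s`, `peak_nN`, `prominence_nN` (empty before
#'   [detectBeats()]).
#' @slot phases data.frame with one row per beat: `beat`, `systolic_s`,
#'   `diastolic_s`, `static_s`.
#'
#' @seealso [totalForceTrace()], [detectBeats()], [lowerEnvelope()].
#' @exportClass ForceTrace
setClass("ForceTrace",
  representation(
    times         = "numeric",
    values        = "numeric",
    frameInterval = "numeric",
    beats         = "data.frame",
    phases        = "data.frame"
  ),
  prototype(beats = data.frame(), phases = data.frame())
)

setValidity("ForceTrace", function(object) {
  msg <- character()
  t <- object@times
  if (length(t) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(t) >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (max(abs(dt - object@frameInterval)) > 1e-6 * object@frameInterval)
      msg <- c(msg, "times must be evenly spaced at frameInterval")
  }
  if (nrow(object@beats) &&
      (any(object@beats$peak_s < min(t)) || any(object@beats$peak_s > max(t))))
    msg <- c(msg, "beat annotations must lie within the time range")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Strain / stress tensor fields
## ---------------------------------------------------------------------------

#' Symmetric strain and stress tensor fields on a pixel grid
#'
#' `TensorField` stores the six independent components of a symmetric rank-2
#' tensor per pixel (`xx`, `yy`, `zz`, `xy`, `xz`, `yz`), each a matrix on
#' the image grid. `StrainField` components are dimensionless; `StressField`
#' components are pascals.
#'
#' @slot xx,yy,zz,xy,xz,yz numeric matrices of tensor components.
#' @slot spacing grid spacing, micrometres.
#'
#' @aliases StrainField-class StressField-class
#' @seealso [strainTensor()], [stressTensor()].
#' @exportClass TensorField
#' @exportClass StrainField
#' @exportClass StressField
setClass("TensorField",
  representation(
    xx = "matrix", yy = "matrix", zz = "matrix",
    xy = "matrix", xz = "matrix", yz = "matrix",
    spacing = "numeric",
    "VIRTUAL"
  )
)

setValidity("TensorField", function(object) {
  d <- dim(object@xx)
  for (comp in c("yy", "zz", "xy", "xz", "yz"))
    if (!identical(dim(slot(object, comp)), d))
      return("all tensor component matrices must share one shape")
  TRUE
})

setClass("StrainField", contains = "TensorField")
setClass("StressField", contains = "TensorField")
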