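## High-level pipeline wrappers binding the modules together: one color
## micrograph (or a stack of them) in, wavelength / displacement / stress
## maps and region forces out.

#' Analyze one color micrograph
#'
#' Runs the full inverse chain: per-pixel hue, hue-to-wavelength lookup
#' through the calibration curve, vertical displacement via the fractional
#' peak shift, vertical stress via incompressible elasticity, region
#' segmentation on the displacement magnitude, and region-wise force
#' integration. When the substrate's unstrained peak `lambda0` is `NA`, it
#' is estimated from the wavelength-map histogram mode
#' ([estimateLambda0()]); without enough valid background this fails with
#' an explicit error.
#'
#' @param image RGB array `(rows, cols, 3)` in `[0, 1]`.
#' @param curve a [CalibrationCurve-class].
#' @param spec a [SubstrateSpec-class]; set `lambda0 = NA` to estimate it
#'   from the image background.
#' @param pixelLength pixel edge length, um.
#' @param saturationFloor chroma validity floor for the hue extraction.
#' @param outOfRange lookup policy, see [lookupWavelength()].
#' @param threshold segmentation threshold, um.
#' @param minArea minimum region area, pixels.
#' @return list with `hue`, `wavelength`, `displacement`, `stress` maps,
#'   `labels` (integer matrix) and `regions` (data.frame from
#'   [regionForces()]).
#' @examples
#' wedge <- makeCalibrationWedge(shape = c(16, 64))
#' hw <- computeHueMap(wedge$image)
#' curve <- buildCalibration(pairHueWavelength(hw, wedge$truth))
#' sc <- makeCellScene(nCells = 1, shape = c(64, 64), seed = 3)
#' img <- renderRGB(wavelengthFromDisplacement(mapValues(sc),
#'                                             SubstrateSpec()),
#'                  defaultCameraModel())
#' res <- analyzeImage(img, curve, SubstrateSpec(), pixelLength = 0.18)
#' res$regions
#' @export
analyzeImage <- function(image, curve, spec, pixelLength = 0.18,
                         saturationFloor = 0.02,
                         outOfRange = "clamp", threshold = 0.05,
                         minArea = 20L) {
  hue <- computeHueMap(image, saturationFloor, pixelLength)
  wl <- lookupWavelength(hue, curve, outOfRange)
  if (!is.finite(spec@lambda0)) {
    lam0 <- tryCatch(estimateLambda0(wl), error = function(e)
      stop("lambda0 is not set and cannot be estimated from the image ",
           "background: ", conditionMessage(e)))
    spec@lambda0 <- lam0
    validObject(spec)
  }
  disp <- displacementMap(wl, spec)
  stress <- verticalStressMap(disp, spec)
  labels <- segmentRegions(disp, threshold, minArea)
  regions <- regionForces(stress, labels)
  list(hue = hue, wavelength = wl, displacement = disp, stress = stress,
       labels = labels, regions = regions)
}

#' Analyze a time-lapse stack of color micrographs
#'
#' Applies [analyzeImage()] per frame (segmentation off by default; pass an
#' `roi` label map for fixed-region bookkeeping) and assembles displacement
#' and stress stacks plus the total-force trace.
#'
#' @param frames list of RGB arrays.
#' @param curve a [CalibrationCurve-class].
#' @param spec a [SubstrateSpec-class].
#' @param frameInterval time between frames, s.
#' @param pixelLength pixel edge length, um.
#' @param mode force trace mode, `"magnitude"` or `"signed"`.
#' @param roi optional logical matrix restricting the trace.
#' @param ... passed to [computeHueMap()] / [lookupWavelength()].
#' @return list with `displacement` (list of maps), `stress` (list of
#'   maps), `velocity` (list of maps, one fewer frame) and `trace`
#'   (a [ForceTrace-class]).
#' @export
analyzeStack <- function(frames, curve, spec, frameInterval,
                         pixelLength = 0.18, mode = "magnitude",
                         roi = NULL, ...) {
  stopifnot(length(frames) >= 1L)
  disp <- vector("list", length(frames))
  stress <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    hue <- computeHueMap(frames[[i]], pixelLength = pixelLength, ...)
    wl <- lookupWavelength(hue, curve)
    disp[[i]] <- displacementMap(wl, spec)
    stress[[i]] <- verticalStressMap(disp[[i]], spec)
  }
  vel <- if (length(frames) >= 2L) velocityMaps(disp, frameInterval)
         else list()
  trace <- totalForceTrace(stress, frameInterval, mode = mode, roi = roi,
                           pixelLength = pixelLength)
  list(displacement = disp, stress = stress, velocity = vel, trace = trace)
}
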