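## Seeded generators of ground-truth deformation scenes, calibration wedges,
## hyperspectral cubes and beating time-lapse sequences. Every generator is a
## pure function of (parameters, seed) so downstream stages can be tested
## bit-for-bit without microscope data.

## radial cell footprint: central Gaussian depression plus an annular rim of
## elevation (focal-adhesion-like ring). The raw sum of the two Gaussians is
## rescaled so the extremes equal the configured push depth / pull height
## exactly.
.cellFootprint <- function(rGrid, pushDepth, pullHeight, radiusPx) {
  sigmaCore <- radiusPx / 2
  rimR <- radiusPx
  sigmaRim <- radiusPx / 4
  f <- -exp(-rGrid^2 / (2 * sigmaCore^2)) * pushDepth +
    exp(-(rGrid - rimR)^2 / (2 * sigmaRim^2)) * pullHeight
  lo <- min(f); hi <- max(f)
  if (pushDepth > 0 && lo < 0) f[f < 0] <- f[f < 0] * (pushDepth / -lo)
  if (pullHeight > 0 && hi > 0) f[f > 0] <- f[f > 0] * (pullHeight / hi)
  f
}

#' Synthetic cell deformation scene
#'
#' Generates a ground-truth vertical displacement field in which each cell is
#' a central depression (the cell body pushing the film down) surrounded by
#' an annular ring of elevation (pulling at the focal-adhesion rim). Cell
#' centers are drawn uniformly at random, rejecting placements whose
#' footprints would overlap or leave the frame. When cells do not overlap,
#' the field minimum equals `-pushDepth` and the maximum `+pullHeight`
#' exactly. Default depths mirror a typical epithelial cell on a 20 kPa
#' film: 1.52 um push, 1.19 um pull.
#'
#' @param nCells number of cells.
#' @param pushDepth central push depth, um, `>= 0`.
#' @param pullHeight rim pull height, um, `>= 0`.
#' @param cellRadius footprint radius, um.
#' @param shape frame size, pixels, `c(rows, cols)`.
#' @param pixelLength pixel edge length, um (0.18 um for a x10 objective).
#' @param substrate a [SubstrateSpec-class].
#' @param seed integer seed.
#' @return a [SceneTruth-class].
#' @examples
#' sc <- makeCellScene(nCells = 2, shape = c(96, 96), seed = 7)
#' range(mapValues(sc))
#' @export
makeCellScene <- function(nCells = 3, pushDepth = 1.52, pullHeight = 1.19,
                          cellRadius = 3.5, shape = c(192, 192),
                          pixelLength = 0.18, substrate = SubstrateSpec(),
                          seed = 1L) {
  stopifnot(pushDepth >= 0, pullHeight >= 0, nCells >= 0)
  radiusPx <- cellRadius / pixelLength
  pad <- 1.6 * radiusPx            # rim + tail must fit inside the frame
  field <- matrix(0, shape[1], shape[2])
  if (nCells > 0) {
    if (2 * pad >= min(shape))
      stop("cellRadius too large for the frame")
    centers <- .withSeed(seed, {
      acc <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(acc) < nCells && tries < 10000L) {
        cand <- c(stats::runif(1, pad, shape[1] - pad),
                  stats::runif(1, pad, shape[2] - pad))
        ok <- !nrow(acc) ||
          all(sqrt(rowSums(sweep(acc, 2, cand)^2)) > 3.2 * radiusPx)
        if (ok) acc <- rbind(acc, cand)
        tries <- tries + 1L
      }
      if (nrow(acc) < nCells)
        stop("could not place ", nCells, " non-overlapping cells in the frame")
      acc
    })
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      r <- sqrt((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2)
      field <- field + .cellFootprint(r, pushDepth, pullHeight, radiusPx)
    }
  }
  new("SceneTruth", displacement = field, pixelLength = pixelLength,
      substrate = substrate, seed = as.integer(seed),
      params = list(generator = "cell", nCells = nCells,
                    pushDepth = pushDepth, pullHeight = pullHeight,
                    cellRadius = cellRadius, shape = shape))
}

#' Synthetic cell-aggregate compression scene
#'
#' A wide, shallow V-shaped depression with a rim of elevation, emulating a
#' three-dimensional cell aggregate compressing the film: displacement falls
#' linearly from the rim to the apex of the V at the aggregate center, and
#' the rim pulls up slightly.
#'
#' @param pushDepth apex depth of the V, um.
#' @param pullHeight rim elevation, um.
#' @param radius aggregate footprint radius, um.
#' @param shape frame size, pixels.
#' @param pixelLength pixel edge length, um.
#' @param center aggregate center `c(row, col)` in pixels; default frame
#'   center.
#' @param substrate a [SubstrateSpec-class].
#' @param seed integer seed (recorded; this generator is deterministic).
#' @return a [SceneTruth-class].
#' @export
makeAggregateScene <- function(pushDepth = 0.66, pullHeight = 0.19,
                               radius = 8, shape = c(128, 128),
                               pixelLength = 0.18,
                               center = (shape + 1) / 2,
                               substrate = SubstrateSpec(), seed = 1L) {
  stopifnot(pushDepth >= 0, pullHeight >= 0)
  radiusPx <- radius / pixelLength
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  r <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  field <- matrix(0, shape[1], shape[2])
  inside <- r < radiusPx
  field[inside] <- -pushDepth * (1 - r[inside] / radiusPx)   # V profile
  sigmaRim <- radiusPx / 6
  rim <- exp(-(r - 1.1 * radiusPx)^2 / (2 * sigmaRim^2)) * pullHeight
  rim[inside & r < 0.9 * radiusPx] <- 0
  field <- field + rim
  new("SceneTruth", displacement = field, pixelLength = pixelLength,
      substrate = substrate, seed = as.integer(seed),
      params = list(generator = "aggregate", pushDepth = pushDepth,
                    pullHeight = pullHeight, radius = radius, shape = shape))
}

#' Calibration wedge: gradient-squeezed substrate
#'
#' Emulates the gradient-squeezing procedure used to build the
#' hue-to-wavelength mapping: the reflection peak wavelength ramps linearly
#' along the column axis from `lambdaMin` to `lambdaMax` (endpoints attained
#' exactly), and both a camera RGB render and a hyperspectral cube are
#' produced from the same truth.
#'
#' @param lambdaMin,lambdaMax wavelength ramp endpoints, nm,
#'   `lambdaMin < lambdaMax`, within the visible range.
#' @param shape frame size, pixels, `c(rows, cols)`.
#' @param camera a [CameraModel-class].
#' @param peakHeight,fwhm,background stop-band parameters
#'   (see [reflectanceSpectrum()]).
#' @param pixelLength pixel edge length, um.
#' @param seed integer seed (read noise in the render).
#' @return list with elements `truth` (a [WavelengthMap-class]), `image`
#'   (RGB array) and `stack` (a [HyperspectralStack-class]).
#' @examples
#' w <- makeCalibrationWedge(shape = c(8, 32))
#' range(mapValues(w$truth))
#' @export
makeCalibrationWedge <- function(lambdaMin = 510, lambdaMax = 570,
                                 shape = c(32, 128),
                                 camera = defaultCameraModel(),
                                 peakHeight = 1, fwhm = 30,
                                 background = 0.05, pixelLength = 0.18,
                                 seed = 1L) {
  stopifnot(lambdaMin < lambdaMax, lambdaMin >= 400, lambdaMax <= 700)
  ramp <- seq(lambdaMin, lambdaMax, length.out = shape[2])
  lam <- matrix(ramp, shape[1], shape[2], byrow = TRUE)
  truth <- WavelengthMap(lam, pixelLength = pixelLength)
  image <- renderRGB(lam, camera, peakHeight = peakHeight, fwhm = fwhm,
                     background = background, seed = seed)
  stack <- makeHyperspectralStack(lam, peakHeight = peakHeight, fwhm = fwhm,
                                  background = background,
                                  pixelLength = pixelLength, seed = seed)
  list(truth = truth, image = image, stack = stack)
}

#' Synthetic hyperspectral cube for a wavelength map
#'
#' Renders the hyperspectral acquisition a tunable-filter scan would record
#' for a substrate whose per-pixel reflection peak is `wavelengthMap`:
#' the sample intensity is \eqn{I = I_{bg} (1 + R)} where \eqn{R} is the
#' Gaussian stop-band reflectance and \eqn{I_{bg}} the background spectrum
#' (default: a scaled tungsten-halogen spectrum). Optional Gaussian noise is
#' seeded.
#'
#' @param wavelengthMap matrix or [WavelengthMap-class] of peak wavelengths,
#'   nm, within the axis range.
#' @param axis wavelength axis, nm (default 420--730 nm, 1 nm step, 311
#'   samples).
#' @param peakHeight,fwhm,background stop-band parameters.
#' @param backgroundSpectrum \eqn{I_{bg}} on `axis`; default
#'   `0.3 * planckSpectrum(axis) + 0.02`, strictly positive.
#' @param noiseSigma Gaussian noise SD on intensities (0 = noiseless).
#' @param pixelLength pixel edge length, um.
#' @param seed integer seed.
#' @return a [HyperspectralStack-class].
#' @export
makeHyperspectralStack <- function(wavelengthMap, axis = 420:730,
                                   peakHeight = 1, fwhm = 30,
                                   background = 0.05,
                                   backgroundSpectrum =
                                     0.3 * planckSpectrum(axis) + 0.02,
                                   noiseSigma = 0, pixelLength = 0.18,
                                   seed = 1L) {
  lam <- if (is(wavelengthMap, "WavelengthMap")) wavelengthMap@values
         else as.matrix(wavelengthMap)
  if (any(lam < min(axis) | lam > max(axis)))
    stop("wavelength map leaves the axis range")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  nr <- nrow(lam); nc <- ncol(lam); nw <- length(axis)
  refl <- background +
    peakHeight * exp(-outer(as.vector(lam), axis, "-")^2 / (2 * sigma^2))
  cube <- sweep(1 + refl, 2, backgroundSpectrum, "*")
  if (noiseSigma > 0)
    cube <- cube + .withSeed(seed,
      matrix(stats::rnorm(length(cube), sd = noiseSigma), nrow(cube), nw))
  HyperspectralStack(array(cube, c(nr, nc, nw)), axis, backgroundSpectrum,
                     pixelLength)
}

#' Synthetic beating time-lapse sequence
#'
#' Emulates a cardiomyocyte monolayer: the displacement at time \eqn{t} is
#' \eqn{\Delta D(x,y,t) = b t + A(x,y) \max(0, \sin(2\pi f t))^p}, a
#' baseline drift plus pulse-like rectified-sine half-waves of the amplitude
#' field \eqn{A}. Frames can be rendered through the camera model or
#' returned as truth only.
#'
#' @param amplitudeField matrix of per-pixel beat amplitudes, um.
#' @param freq beating frequency, Hz; must satisfy `fps > 2 * freq`.
#' @param fps frame rate, Hz (19.06 fps is typical of the camera used for
#'   monolayer recordings).
#' @param duration recording length, s.
#' @param baselineDrift linear drift of the static baseline, um/s.
#' @param pulsePower sharpening exponent `p` of the rectified sine.
#' @param substrate a [SubstrateSpec-class].
#' @param camera a [CameraModel-class], used when `render = TRUE`.
#' @param render render camera frames (`TRUE`) or return truth only.
#' @param pixelLength pixel edge length, um.
#' @param seed integer seed.
#' @return list with `times` (s), `truth` (list of displacement matrices,
#'   um), `frames` (list of RGB arrays, or `NULL`), `frameInterval` (s, =
#'   `1/fps`), and the generator parameters.
#' @examples
#' seqc <- makeBeatingSequence(matrix(0.4, 8, 8), freq = 1, fps = 10,
#'                             duration = 2, render = FALSE)
#' length(seqc$truth)
#' @export
makeBeatingSequence <- function(amplitudeField, freq = 1.65, fps = 19.06,
                                duration = 20, baselineDrift = 0,
                                pulsePower = 2,
                                substrate = SubstrateSpec(),
                                camera = defaultCameraModel(),
                                render = TRUE, pixelLength = 0.18,
                                seed = 1L) {
  if (freq > 0 && fps <= 2 * freq)
    stop("fps must exceed twice the beating frequency to resolve beats")
  amplitudeField <- as.matrix(amplitudeField)
  n <- floor(duration * fps)
  times <- (seq_len(n) - 1) / fps
  pulse <- pmax(0, sin(2 * pi * freq * times))^pulsePower
  truth <- lapply(seq_len(n), function(i)
    baselineDrift * times[i] + amplitudeField * pulse[i])
  frames <- NULL
  if (render) {
    frames <- lapply(seq_len(n), function(i) {
      lam <- wavelengthFromDisplacement(truth[[i]], substrate)
      renderRGB(lam, camera, seed = seed + i)
    })
  }
  list(times = times, truth = truth, frames = frames,
       frameInterval = 1 / fps,
       params = list(freq = freq, fps = fps, duration = duration,
                     baselineDrift = baselineDrift,
                     pulsePower = pulsePower, seed = as.integer(seed)))
}
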