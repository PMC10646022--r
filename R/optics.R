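## Forward optical physics: substrate geometry/deformation -> reflection peak
## -> spectrum -> camera RGB -> hue. Shared by the synthetic generator and,
## in reverse, by the analysis chain.

#' Reflection peak wavelength from the Bragg condition
#'
#' The photonic stop band of the substrate reflects at
#' \eqn{\lambda = 2 d_{111} \sqrt{n_{avg}^2 - \sin^2\theta}}, where
#' \eqn{d_{111}} is the interplanar distance of the (111) diffraction planes,
#' \eqn{n_{avg}} the average refractive index and \eqn{\theta} the incidence
#' angle relative to the surface normal.
#'
#' @param d111 interplanar distance, nm, positive.
#' @param nAverage average refractive index, positive (below 1 the
#'   evanescent domain check can trigger at oblique incidence).
#' @param theta incidence angle, rad, in `[0, pi/2)`.
#' @return peak wavelength in nm.
#' @examples
#' braggPeakWavelength(196.4, 1.40)   # 549.92 nm
#' @export
braggPeakWavelength <- function(d111, nAverage, theta = 0) {
  stopifnot(d111 > 0, nAverage > 0, theta >= 0, theta < pi / 2)
  disc <- nAverage^2 - sin(theta)^2
  if (any(disc <= 0))
    stop("evanescent condition: nAverage^2 <= sin^2(theta)")
  2 * d111 * sqrt(disc)
}

#' Peak wavelength after a vertical thickness change
#'
#' The fractional shift of the reflection peak equals the fractional change
#' of film thickness, \eqn{\Delta\lambda / \lambda_0 = \Delta D / D}, so a
#' deformed substrate reflects at \eqn{\lambda_0 (1 + \Delta D / D)}.
#' Sign convention (project-wide): \eqn{\Delta D > 0} is a thickness increase
#' (cell pulls upward, red shift), \eqn{\Delta D < 0} a compression (push,
#' blue shift).
#'
#' @param deltaD vertical deformation, um (scalar, vector or matrix).
#' @param spec a [SubstrateSpec-class] supplying D and lambda0.
#' @return wavelength(s), nm, same shape as `deltaD`.
#' @examples
#' s <- SubstrateSpec()
#' wavelengthFromDisplacement(0.24, s)    # 1% thickness increase -> 555.5 nm
#' @export
wavelengthFromDisplacement <- function(deltaD, spec) {
  stopifnot(is(spec, "SubstrateSpec"))
  if (any(deltaD <= -spec@restD))
    stop("deltaD must exceed -D: the film cannot compress past zero thickness")
  spec@lambda0 * (1 + deltaD / spec@restD)
}

#' Model reflectance spectrum of the photonic stop band
#'
#' A Gaussian peak of the given height and full width at half maximum on a
#' flat background, sampled on a wavelength axis. The lineshape is a modeling
#' convenience: only the peak position carries mechanical information.
#'
#' @param peakLambda peak center, nm.
#' @param axis wavelength grid, nm.
#' @param peakHeight peak reflectance above background, positive.
#' @param fwhm full width at half maximum, nm, positive.
#' @param background flat background reflectance, `>= 0`.
#' @return numeric vector on `axis` with attribute `outOfRange = TRUE` when
#'   the peak center lies outside the axis (a warning is raised, the
#'   spectrum is still returned).
#' @examples
#' s <- reflectanceSpectrum(550, axis = 420:730)
#' axis <- 420:730; axis[which.max(s)]    # 550
#' @export
reflectanceSpectrum <- function(peakLambda, axis = 420:730, peakHeight = 1,
                                fwhm = 30, background = 0.05) {
  stopifnot(fwhm > 0, peakHeight > 0, background >= 0)
  out <- peakLambda < min(axis) || peakLambda > max(axis)
  if (out)
    warning(sprintf("peak %.1f nm lies outside the axis [%g, %g] nm",
                    peakLambda, min(axis), max(axis)))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  spec <- background + peakHeight * exp(-(axis - peakLambda)^2 / (2 * sigma^2))
  if (out) attr(spec, "outOfRange") <- TRUE
  spec
}

#' Planck blackbody relative spectral power
#'
#' @param axis wavelengths, nm.
#' @param temperature color temperature, K (default 3200, tungsten-halogen).
#' @return spectral power normalized to a maximum of 1 on `axis`.
#' @export
planckSpectrum <- function(axis, temperature = 3200) {
  lm <- axis * 1e-9
  p <- lm^-5 / (exp(1.4388e-2 / (lm * temperature)) - 1)
  p / max(p)
}

#' Default camera model
#'
#' Three Gaussian channel sensitivities centered at 600 (R), 540 (G) and
#' 460 nm (B) with a common sigma of 55 nm — wide enough to guarantee the
#' spectral crosstalk that makes hue a one-to-one function of the narrow
#' reflection peak over the working band — under a tungsten-halogen
#' (Planck 3200 K) illuminant, on the 420--730 nm, 1 nm axis.
#'
#' @param axis wavelength axis, nm.
#' @param centers channel centers (R, G, B), nm.
#' @param sigma common Gaussian width, nm.
#' @param bitDepth 8 or 16.
#' @param readNoiseSigma Gaussian read noise as a fraction of full scale
#'   (default 0: noiseless).
#' @param whiteBalance three channel gains.
#' @param exposure linear gain before quantization.
#' @param illuminant relative spectral power on `axis`; default Planck
#'   3200 K.
#' @return a validated [CameraModel-class].
#' @examples
#' cam <- defaultCameraModel()
#' cam
#' @export
defaultCameraModel <- function(axis = 420:730,
                               centers = c(600, 540, 460), sigma = 55,
                               bitDepth = 16L, readNoiseSigma = 0,
                               whiteBalance = c(1, 1, 1), exposure = 1.8,
                               illuminant = planckSpectrum(axis)) {
  sens <- vapply(centers,
                 function(mu) exp(-(axis - mu)^2 / (2 * sigma^2)),
                 numeric(length(axis)))
  new("CameraModel", wavelengths = as.numeric(axis), sensitivities = sens,
      illuminant = as.numeric(illuminant), bitDepth = as.integer(bitDepth),
      readNoiseSigma = as.numeric(readNoiseSigma),
      whiteBalance = as.numeric(whiteBalance),
      exposure = as.numeric(exposure))
}

## run expr with a local, seeded RNG; caller's RNG state is untouched
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## trapezoidal quadrature weights for a (possibly non-uniform) axis
.trapWeights <- function(axis) {
  n <- length(axis)
  w <- numeric(n)
  d <- diff(axis)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

## camera channel integration weights: trapezoid x illuminant x sensitivity,
## normalized per channel by the white reference integral(illum x sens)
.channelWeights <- function(camera) {
  tw <- .trapWeights(camera@wavelengths)
  w <- camera@sensitivities * (camera@illuminant * tw)
  sweep(w, 2, colSums(w), "/")
}

## linear RGB (n_pix x 3) from a spectra matrix (n_pix x n_wavelengths)
.spectraToLinearRGB <- function(spectra, camera) {
  spectra %*% .channelWeights(camera)
}

#' Render a camera RGB image of the substrate
#'
#' Forms the linear channel values
#' \eqn{c = \int L(\lambda) R(\lambda) S_c(\lambda) d\lambda /
#'          \int L(\lambda) S_c(\lambda) d\lambda}
#' by trapezoidal quadrature (illuminant \eqn{L}, reflectance \eqn{R},
#' channel sensitivity \eqn{S_c}), applies white-balance gains and the
#' exposure factor, adds seeded Gaussian read noise, clamps to `[0, 1]` and
#' quantizes to the camera bit depth. Deterministic given `seed`; with zero
#' read noise the result is seed-invariant.
#'
#' The reflectance can be given either as explicit per-pixel spectra (a
#' [HyperspectralStack-class] of reflectance values, sharing an axis with the
#' camera) or, more commonly, as a peak-wavelength map plus the Gaussian
#' stop-band parameters of [reflectanceSpectrum()].
#'
#' @param x a [WavelengthMap-class] (or plain matrix of peak wavelengths,
#'   nm), or a [HyperspectralStack-class] holding per-pixel reflectance.
#' @param camera a [CameraModel-class].
#' @param peakHeight,fwhm,background stop-band parameters used when `x` is a
#'   wavelength map (see [reflectanceSpectrum()]).
#' @param seed integer seed for the read noise.
#' @return numeric array `(rows, cols, 3)` of quantized channel values in
#'   `[0, 1]` (multiples of `1/(2^bitDepth - 1)`).
#' @examples
#' cam <- defaultCameraModel()
#' img <- renderRGB(matrix(c(520, 550), 1, 2), cam)
#' dim(img)
#' @export
renderRGB <- function(x, camera, peakHeight = 1, fwhm = 30,
                      background = 0.05, seed = 1L) {
  stopifnot(is(camera, "CameraModel"))
  axis <- camera@wavelengths
  if (is(x, "HyperspectralStack")) {
    if (length(x@wavelengths) != length(axis) ||
        max(abs(x@wavelengths - axis)) > 1e-9) {
      if (max(x@wavelengths) < min(axis) || min(x@wavelengths) > max(axis))
        stop("spectra and camera wavelength axes are disjoint")
      ## resample camera curves onto the spectra axis
      camera@sensitivities <- apply(camera@sensitivities, 2, function(s)
        stats::approx(axis, s, xout = x@wavelengths, rule = 2)$y)
      camera@illuminant <- stats::approx(axis, camera@illuminant,
                                         xout = x@wavelengths, rule = 2)$y
      camera@wavelengths <- x@wavelengths
      axis <- x@wavelengths
    }
    d <- dim(x@cube)
    spectra <- matrix(x@cube, d[1] * d[2], d[3])
    shape <- d[1:2]
  } else {
    lam <- if (is(x, "WavelengthMap")) x@values else as.matrix(x)
    shape <- dim(lam)
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    ## chunked outer product keeps memory bounded for large fields
    npix <- length(lam)
    rgbLin <- matrix(0, npix, 3)
    cw <- .channelWeights(camera)
    chunk <- 8192L
    lamv <- as.vector(lam)
    for (i0 in seq(1L, npix, by = chunk)) {
      i1 <- min(i0 + chunk - 1L, npix)
      sp <- background +
        peakHeight * exp(-outer(lamv[i0:i1], axis, "-")^2 / (2 * sigma^2))
      rgbLin[i0:i1, ] <- sp %*% cw
    }
    return(.finishRender(rgbLin, shape, camera, seed))
  }
  rgbLin <- .spectraToLinearRGB(spectra, camera)
  .finishRender(rgbLin, shape, camera, seed)
}

.finishRender <- function(rgbLin, shape, camera, seed) {
  rgbLin <- sweep(rgbLin, 2, camera@whiteBalance, "*") * camera@exposure
  if (camera@readNoiseSigma > 0)
    rgbLin <- rgbLin + .withSeed(seed,
      matrix(stats::rnorm(length(rgbLin), sd = camera@readNoiseSigma),
             nrow(rgbLin), 3))
  levels <- 2^camera@bitDepth - 1
  q <- round(pmin(pmax(rgbLin, 0), 1) * levels) / levels
  array(q, dim = c(shape, 3L))
}

#' Per-pixel hue with a saturation validity floor
#'
#' Extracts the standard hexagonal HSV hue, scaled to `[0, 1)` with red at
#' 0, from a 3-channel image. Pixels whose chroma (max minus min channel
#' value) falls below `saturationFloor` of full scale have no well-defined
#' hue and are marked invalid.
#'
#' @param image numeric array `(rows, cols, 3)` with values in `[0, 1]`.
#' @param saturationFloor chroma floor as a fraction of full scale.
#' @param pixelLength pixel edge length, um, carried into the result.
#' @return a [HueMap-class].
#' @examples
#' img <- array(0, c(1, 1, 3)); img[1, 1, ] <- c(0, 1, 0)   # pure green
#' mapValues(computeHueMap(img))                            # 1/3
#' @export
computeHueMap <- function(image, saturationFloor = 0.02,
                          pixelLength = NA_real_) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be a (rows, cols, 3) array")
  r <- matrix(image[, , 1], d[1], d[2])
  g <- matrix(image[, , 2], d[1], d[2])
  b <- matrix(image[, , 3], d[1], d[2])
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  chroma <- mx - mn
  valid <- chroma >= saturationFloor & chroma > 0
  h <- matrix(0, d[1], d[2])
  safe <- ifelse(chroma > 0, chroma, 1)
  iR <- mx == r
  iG <- !iR & mx == g
  iB <- !iR & !iG
  h[iR] <- (((g - b) / safe)[iR] / 6) %% 1
  h[iG] <- ((b - r) / safe)[iG] / 6 + 1 / 3
  h[iB] <- ((r - g) / safe)[iB] / 6 + 2 / 3
  h[!valid] <- NA_real_
  HueMap(h, valid, pixelLength)
}
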