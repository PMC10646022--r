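## Reference branch: reflection spectra and per-pixel reflection peak
## wavelength maps from hyperspectral cubes. Used to build calibration
## ground truth and to validate the hue-based readout.

#' Reflection spectra from a hyperspectral cube
#'
#' Elementwise \eqn{R(\lambda, x, y) = I(\lambda, x, y) / I_{bg}(\lambda) - 1}.
#' Pixels touching a zero or negative background sample are invalidated with
#' a warning rather than producing infinities.
#'
#' @param stack a [HyperspectralStack-class].
#' @return list with `reflectance` (array shaped like the cube) and `valid`
#'   (logical matrix of pixels whose background was strictly positive at
#'   every wavelength).
#' @export
reflectionSpectra <- function(stack) {
  stopifnot(is(stack, "HyperspectralStack"))
  d <- dim(stack@cube)
  bg <- stack@background
  if (length(bg) == d[3]) {
    bad <- bg <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive background sample(s); affected ",
              "wavelengths invalidate all pixels")
      valid <- matrix(FALSE, d[1], d[2])
    } else valid <- matrix(TRUE, d[1], d[2])
    safeBg <- ifelse(bad, 1, bg)
    refl <- sweep(stack@cube, 3, safeBg, "/") - 1
    refl[, , bad] <- NA_real_
  } else {
    bad <- bg <= 0
    valid <- !apply(bad, c(1, 2), any)
    if (any(!valid))
      warning(sum(!valid), " pixel(s) invalidated by non-positive background")
    safeBg <- ifelse(bad, 1, bg)
    refl <- stack@cube / safeBg - 1
    refl[array(rep(!valid, d[3]), d)] <- NA_real_
  }
  list(reflectance = refl, valid = valid)
}

## 3-point parabolic (quadratic vertex) sub-sample refinement around an
## interior argmax; returns the fractional offset in grid steps, in
## [-0.5, 0.5]
.parabolicOffset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  off <- ifelse(abs(denom) > .Machine$double.eps,
                0.5 * (ym1 - yp1) / denom, 0)
  pmin(pmax(off, -0.5), 0.5)
}

#' Per-pixel reflection peak wavelength map
#'
#' For every pixel, the wavelength of the maximum reflectance over the axis;
#' with `refine = TRUE` (default) a 3-point parabolic interpolation around
#' the argmax gives sub-sample precision (well under half the grid step for
#' a smooth stop-band peak). Pixels whose peak prominence — the excursion
#' `max - min` relative to the maximum — falls below `minProminence`, and
#' flat-spectrum pixels, are marked invalid.
#'
#' @param reflectance array `(rows, cols, n_wavelengths)` of reflectance
#'   (from [reflectionSpectra()]), or a [HyperspectralStack-class] (the
#'   reflectance is derived first).
#' @param axis wavelength axis, nm; taken from the stack when `reflectance`
#'   is a [HyperspectralStack-class].
#' @param refine use parabolic sub-sample refinement.
#' @param minProminence minimum `(max - min)/max` to accept a peak.
#' @param smooth optional odd window length for a running-mean spectral
#'   smoothing before peak finding (`0` = off, the default).
#' @param pixelLength pixel edge length, um, carried into the result.
#' @return a [WavelengthMap-class].
#' @export
peakWavelengthMap <- function(reflectance, axis = NULL, refine = TRUE,
                              minProminence = 0.05, smooth = 0,
                              pixelLength = NA_real_) {
  valid0 <- NULL
  if (is(reflectance, "HyperspectralStack")) {
    if (is.null(axis)) axis <- reflectance@wavelengths
    if (is.na(pixelLength)) pixelLength <- reflectance@pixelLength
    rs <- reflectionSpectra(reflectance)
    valid0 <- rs$valid
    reflectance <- rs$reflectance
  }
  d <- dim(reflectance)
  stopifnot(length(d) == 3L, !is.null(axis), length(axis) == d[3])
  if (d[3] < 3L) stop("need at least 3 wavelength samples")
  m <- matrix(reflectance, d[1] * d[2], d[3])
  if (smooth > 0) {
    if (smooth %% 2 == 0) stop("smooth window must be odd")
    k <- rep(1 / smooth, smooth)
    m <- t(apply(m, 1, function(r)
      stats::filter(r, k, sides = 2) |> as.numeric() |>
        (\(x) { x[is.na(x)] <- r[is.na(x)]; x })()))
  }
  idx <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), idx)]
  mn <- apply(m, 1, min)
  flat <- !is.finite(mx) | !is.finite(mn) | (mx - mn) == 0
  prom <- ifelse(flat | mx == 0, 0, (mx - mn) / abs(mx))
  ok <- !flat & prom >= minProminence & mx > 0
  lam <- axis[idx]
  if (refine) {
    interior <- idx > 1L & idx < d[3]
    i <- which(interior & ok)
    if (length(i)) {
      ym1 <- m[cbind(i, idx[i] - 1L)]
      yp1 <- m[cbind(i, idx[i] + 1L)]
      step <- (axis[idx[i] + 1L] - axis[idx[i] - 1L]) / 2
      lam[i] <- lam[i] + .parabolicOffset(ym1, mx[i], yp1) * step
    }
  }
  lam[!ok] <- NA_real_
  valid <- matrix(ok, d[1], d[2])
  if (!is.null(valid0)) valid <- valid & valid0
  vals <- matrix(lam, d[1], d[2])
  vals[!valid] <- NA_real_
  WavelengthMap(vals, valid, pixelLength)
}

#' Write / read a hyperspectral cube as multi-page TIFF + JSON sidecar
#'
#' Each TIFF page is one wavelength plane (32-bit float samples; cube
#' intensities are camera-normalized to `[0, 1]`). The JSON sidecar
#' (`<path>.json`) carries the wavelength axis, the background spectrum and
#' the pixel length; reading without it is an error.
#'
#' @param stack a [HyperspectralStack-class].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `writeHyperspectralStack()`: `path` invisibly;
#'   `readHyperspectralStack()`: a [HyperspectralStack-class].
#' @export
writeHyperspectralStack <- function(stack, path) {
  stopifnot(is(stack, "HyperspectralStack"))
  d <- dim(stack@cube)
  pages <- lapply(seq_len(d[3]), function(k) stack@cube[, , k])
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  meta <- list(wavelengths_nm = stack@wavelengths,
               background = stack@background,
               pixel_length_um = stack@pixelLength)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeHyperspectralStack
#' @export
readHyperspectralStack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for cube: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  cube <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  pl <- meta$pixel_length_um
  if (is.null(pl) || !length(pl)) pl <- NA_real_
  HyperspectralStack(cube, meta$wavelengths_nm, meta$background,
                     pixelLength = pl)
}
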