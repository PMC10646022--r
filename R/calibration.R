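## Hue -> wavelength calibration: pairing hue and reference wavelength maps
## of a gradient-deformed substrate, binning to monotone knots, and applying
## the resulting lookup table. This replaces a hyperspectral scan for every
## subsequent acquisition.

#' Pair co-valid hue and wavelength values position by position
#'
#' Collects all pixels where both the hue map and the reference wavelength
#' map are valid (optionally restricted to a mask) into a two-column
#' data.frame of `(hue, wavelength)` samples, the raw material for
#' [buildCalibration()].
#'
#' @param hue a [HueMap-class].
#' @param wl a [WavelengthMap-class] of the same shape (typically from
#'   [peakWavelengthMap()] on a hyperspectral scan of the same field).
#' @param mask optional logical matrix restricting the pairing.
#' @return data.frame with columns `hue` and `wavelength_nm`.
#' @export
pairHueWavelength <- function(hue, wl, mask = NULL) {
  stopifnot(is(hue, "HueMap"), is(wl, "WavelengthMap"))
  if (!identical(dim(hue@values), dim(wl@values)))
    stop("hue and wavelength maps must share one shape")
  keep <- hue@valid & wl@valid
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep))
    stop("no co-valid pixels to pair")
  data.frame(hue = hue@values[keep], wavelength_nm = wl@values[keep])
}

#' Build a monotone hue-to-wavelength calibration curve
#'
#' Bins the paired samples by hue (default bin width 0.002 hue units,
#' comparable to the substrate's intrinsic hue standard deviation of
#' 0.0025), takes the median hue and median wavelength per bin for
#' robustness (so exactly linear pairs yield knots exactly on that line),
#' and enforces strict monotonicity with isotonic regression in the
#' dominant direction.
#' The direction (increasing or decreasing wavelength with hue) is decided
#' by the sign of the Spearman correlation of the raw pairs, never
#' hard-coded: for green-to-yellow substrates the curve is decreasing
#' (yellow hue is smaller than green hue at longer wavelength).
#'
#' @param pairs data.frame from [pairHueWavelength()] (columns `hue`,
#'   `wavelength_nm`).
#' @param binWidth hue bin width.
#' @param provenance optional list merged into the curve's provenance.
#' @return a [CalibrationCurve-class] with one knot per populated hue bin.
#' @export
buildCalibration <- function(pairs, binWidth = 0.002, provenance = list()) {
  stopifnot(all(c("hue", "wavelength_nm") %in% names(pairs)),
            binWidth > 0)
  h <- pairs$hue; w <- pairs$wavelength_nm
  bins <- floor(h / binWidth)
  if (length(unique(bins)) < 2L)
    stop("pairs must span at least 2 hue bins")
  med <- tapply(w, bins, stats::median)
  medH <- tapply(h, bins, stats::median)
  ord <- order(as.numeric(medH))
  centers <- as.numeric(medH)[ord]; med <- as.numeric(med)[ord]
  rho <- suppressWarnings(
    stats::cor(h, w, method = "spearman"))
  if (!is.finite(rho) || rho == 0)
    stop("cannot determine the calibration direction (flat or ambiguous pairs)")
  ## isotonic repair in the dominant direction
  iso <- if (rho > 0) stats::isoreg(centers, med)$yf
         else -stats::isoreg(centers, -med)$yf
  ## isoreg leaves flat runs; break only ties, by the smallest
  ## representable-at-scale step, so strictly monotone input is untouched
  eps <- 1e-10 * max(abs(iso), 1)
  if (rho > 0) {
    for (i in seq_along(iso)[-1])
      if (iso[i] <= iso[i - 1]) iso[i] <- iso[i - 1] + eps
  } else {
    for (i in seq_along(iso)[-1])
      if (iso[i] >= iso[i - 1]) iso[i] <- iso[i - 1] - eps
  }
  curve <- new("CalibrationCurve", hue = centers, wavelength = iso,
               provenance = c(list(binWidth = binWidth,
                                   nPairs = length(h),
                                   direction = if (rho > 0) "increasing"
                                               else "decreasing",
                                   date = format(Sys.Date())),
                              provenance))
  validObject(curve)
  curve
}

#' Wavelength map from a hue map via a calibration curve
#'
#' Linear interpolation between the calibration knots. Hue values outside
#' the calibrated range are handled per `outOfRange`: `"clamp"` (default)
#' assigns the boundary wavelength and leaves the pixel valid but flags it
#' in the `clamped` attribute of the returned map; `"invalidate"` marks the
#' pixel invalid. Invalid hue pixels always propagate as invalid.
#'
#' @param hue a [HueMap-class].
#' @param curve a [CalibrationCurve-class].
#' @param outOfRange `"clamp"` or `"invalidate"`.
#' @return a [WavelengthMap-class]; attribute `clamped` on the result is a
#'   logical matrix marking out-of-range pixels under the clamp policy.
#' @export
lookupWavelength <- function(hue, curve, outOfRange = c("clamp",
                                                        "invalidate")) {
  stopifnot(is(hue, "HueMap"), is(curve, "CalibrationCurve"))
  outOfRange <- match.arg(outOfRange)
  h <- hue@values
  lo <- min(curve@hue); hi <- max(curve@hue)
  out <- (h < lo | h > hi) & hue@valid
  out[is.na(out)] <- FALSE
  w <- matrix(stats::approx(curve@hue, curve@wavelength,
                            xout = pmin(pmax(as.vector(h), lo), hi))$y,
              nrow(h), ncol(h))
  valid <- hue@valid
  if (outOfRange == "invalidate") valid <- valid & !out
  w[!valid] <- NA_real_
  res <- WavelengthMap(w, valid, hue@pixelLength)
  attr(res, "clamped") <- out & (outOfRange == "clamp")
  res
}

#' Write / read a calibration curve as CSV
#'
#' Two numeric columns (`hue`, `wavelength_nm`) preceded by `#`-commented
#' header lines carrying the provenance. Knot values are written with full
#' double precision (17 significant digits) so that write-then-read
#' round-trips bit-exactly.
#'
#' @param curve a [CalibrationCurve-class].
#' @param path file path.
#' @return `writeCalibration()`: `path`, invisibly; `readCalibration()`: a
#'   [CalibrationCurve-class].
#' @export
writeCalibration <- function(curve, path) {
  stopifnot(is(curve, "CalibrationCurve"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(curve@provenance))
    writeLines(sprintf("# %s: %s", key,
                       paste(curve@provenance[[key]], collapse = " ")), con)
  writeLines("hue,wavelength_nm", con)
  writeLines(sprintf("%.17g,%.17g", curve@hue, curve@wavelength), con)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  prov <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^# *([^:]+): *(.*)$", ln))[[1]]
    if (length(m) == 3) prov[[m[2]]] <- m[3]
  }
  tab <- utils::read.csv(text = lines[!hdr])
  new("CalibrationCurve", hue = tab$hue, wavelength = tab$wavelength_nm,
      provenance = prov)
}
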