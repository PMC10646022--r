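## Time-lapse analytics: velocity maps, total-force traces, beat detection
## with phase decomposition, static-stress baselines, drug-response
## classification and force-area regression.

.stackValues <- function(x) {
  if (is(x, "PixelMap")) x@values else as.matrix(x)
}

.stackValid <- function(x) {
  if (is(x, "PixelMap")) x@valid else !is.na(as.matrix(x))
}

#' Vertical velocity maps from a displacement stack
#'
#' Frame-to-frame difference divided by the frame interval:
#' \eqn{v_t = (\Delta D_{t+1} - \Delta D_t) / \Delta t}. The output has one
#' fewer frame than the input; cumulative re-integration telescopes back to
#' the displacement difference between the last and first frame exactly.
#'
#' @param stack list of [DisplacementMap-class] objects (or plain matrices,
#'   um), at least 2 frames.
#' @param frameInterval time between frames, s, positive.
#' @return list of [VelocityMap-class] (um/s), length `length(stack) - 1`.
#' @export
velocityMaps <- function(stack, frameInterval) {
  if (length(stack) < 2L) stop("need at least 2 frames for velocities")
  stopifnot(frameInterval > 0)
  pl <- if (is(stack[[1]], "PixelMap")) stack[[1]]@pixelLength else NA_real_
  lapply(seq_len(length(stack) - 1L), function(i) {
    a <- .stackValues(stack[[i]]); b <- .stackValues(stack[[i + 1L]])
    va <- .stackValid(stack[[i]]); vb <- .stackValid(stack[[i + 1L]])
    v <- (b - a) / frameInterval
    ok <- va & vb
    v[!ok] <- NA_real_
    VelocityMap(v, ok, pl)
  })
}

#' Total vertical force trace over a time-lapse stress stack
#'
#' Integrates the vertical stress over the field of view (or an ROI) frame
#' by frame: magnitude mode sums \eqn{|T_z| \ell^2} (total vertically
#' directed force), signed mode sums \eqn{T_z \ell^2} (net up minus down).
#'
#' @param stack list of [StressMap-class] objects.
#' @param frameInterval time between frames, s.
#' @param mode `"magnitude"` (default) or `"signed"`.
#' @param roi optional logical matrix selecting the region of interest.
#' @param pixelLength pixel edge length, um; defaults to the maps'.
#' @return a [ForceTrace-class] (nN).
#' @export
totalForceTrace <- function(stack, frameInterval, mode = c("magnitude",
                                                           "signed"),
                            roi = NULL, pixelLength = NULL) {
  if (!length(stack)) stop("empty stress stack")
  mode <- match.arg(mode)
  if (is.null(pixelLength)) pixelLength <- stack[[1]]@pixelLength
  if (is.na(pixelLength)) stop("pixelLength is required")
  if (!is.null(roi) && !any(roi)) stop("empty ROI")
  aPix <- (pixelLength * 1e-6)^2 * 1e9
  vals <- vapply(stack, function(s) {
    tz <- s@values
    tz[!s@valid] <- NA_real_
    if (!is.null(roi)) tz <- tz[roi]
    v <- tz[!is.na(tz)]
    if (mode == "magnitude") sum(abs(v)) * aPix else sum(v) * aPix
  }, numeric(1))
  ForceTrace(vals, frameInterval)
}

## prominence of a local maximum: height above the higher of the two lowest
## valleys separating it from higher ground (classic topographic definition)
.peakProminence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p)]
    hiL <- which(left > y[p])
    baseL <- if (length(hiL)) min(left[max(hiL):p]) else min(left)
    right <- y[p:length(y)]
    hiR <- which(right > y[p])
    baseR <- if (length(hiR)) min(right[1:min(hiR)]) else min(right)
    y[p] - max(baseL, baseR)
  }, numeric(1))
}

#' Detect beats in a force trace
#'
#' Finds local maxima with at least the requested prominence and temporal
#' separation; each maximum is one beat. The beat rate is
#' `beats * 60 / duration` (bpm). Per beat, the phase boundaries are the
#' crossings of `baseline + 10%` of the beat amplitude: systole runs from
#' onset to peak, diastole from peak back to baseline, and the remainder of
#' the inter-beat interval is static.
#'
#' @param trace a [ForceTrace-class].
#' @param prominence minimum peak prominence, nN; default 20% of the trace
#'   dynamic range.
#' @param minSeparation minimum time between beats, s.
#' @param phaseFraction fraction of beat amplitude defining the onset/end
#'   threshold crossing.
#' @return the trace with `beats` and `phases` slots filled, and attribute
#'   `rate_bpm`; `beatRate()` reads the rate back.
#' @export
detectBeats <- function(trace, prominence = NULL, minSeparation = 0.25,
                        phaseFraction = 0.10) {
  stopifnot(is(trace, "ForceTrace"))
  y <- trace@values
  t <- trace@times
  n <- length(y)
  if (n < 3L) stop("trace must have at least 3 samples")
  rng <- diff(range(y))
  if (is.null(prominence)) prominence <- 0.2 * rng
  ## candidate local maxima (plateau-aware: strictly above one neighbor,
  ## not below the other)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (rng > 0 && length(cand)) {
    prom <- .peakProminence(y, cand)
    keep <- prom >= prominence
    cand <- cand[keep]; prom <- prom[keep]
    ## enforce separation, keeping the more prominent peak
    if (length(cand) > 1L) {
      ord <- order(prom, decreasing = TRUE)
      sel <- logical(0)
      chosen <- integer(0)
      for (i in ord) {
        if (!length(chosen) ||
            all(abs(t[cand[i]] - t[chosen]) >= minSeparation))
          chosen <- c(chosen, cand[i])
      }
      cand <- sort(chosen)
      prom <- .peakProminence(y, cand)
    }
  } else {
    cand <- integer(0); prom <- numeric(0)
  }
  duration <- n * trace@frameInterval
  rate <- length(cand) * 60 / duration
  beats <- data.frame(beat = integer(0), onset_s = numeric(0),
                      peak_s = numeric(0), end_s = numeric(0),
                      peak_nN = numeric(0), prominence_nN = numeric(0))
  phases <- data.frame(beat = integer(0), systolic_s = numeric(0),
                       diastolic_s = numeric(0), static_s = numeric(0))
  if (length(cand)) {
    bounds <- c(1L, floor((cand[-length(cand)] + cand[-1]) / 2), n)
    for (k in seq_along(cand)) {
      p <- cand[k]
      lo <- bounds[k]; hi <- bounds[k + 1]
      base <- min(y[lo:hi])
      thr <- base + phaseFraction * (y[p] - base)
      below <- which(y[lo:p] <= thr)
      onset <- if (length(below)) lo + max(below) - 1L else lo
      after <- which(y[p:hi] <= thr)
      endi <- if (length(after)) p + min(after) - 1L else hi
      beats <- rbind(beats, data.frame(
        beat = k, onset_s = t[onset], peak_s = t[p], end_s = t[endi],
        peak_nN = y[p], prominence_nN = prom[k]))
      interval <- t[hi] - t[lo]
      sys <- t[p] - t[onset]
      dia <- t[endi] - t[p]
      phases <- rbind(phases, data.frame(
        beat = k, systolic_s = sys, diastolic_s = dia,
        static_s = max(interval - sys - dia, 0)))
    }
  }
  out <- new("ForceTrace", times = t, values = y,
             frameInterval = trace@frameInterval, beats = beats,
             phases = phases)
  attr(out, "rate_bpm") <- rate
  out
}

#' @rdname detectBeats
#' @param x an annotated trace from `detectBeats()`.
#' @export
beatRate <- function(x) {
  r <- attr(x, "rate_bpm")
  if (is.null(r))
    r <- nrow(x@beats) * 60 / (length(x@values) * x@frameInterval)
  r
}

#' Lower envelope of a force trace (static-stress baseline)
#'
#' Running minimum over a centered time window; the positions where the
#' trace attains the running minimum are kept as anchors and the baseline is
#' the linear interpolation between them, clipped by the running minimum so
#' it never exceeds the trace. In a beating recording this tracks the
#' static (non-contractile) stress under the waveform.
#'
#' @param trace a [ForceTrace-class].
#' @param window window length, s, at least two frame intervals.
#' @return numeric baseline, same length as the trace, `<=` trace pointwise.
#' @export
lowerEnvelope <- function(trace, window) {
  stopifnot(is(trace, "ForceTrace"))
  if (window < 2 * trace@frameInterval)
    stop("window must be at least two frame intervals")
  y <- trace@values
  k <- max(3L, round(window / trace@frameInterval))
  if (k %% 2 == 0) k <- k + 1L
  rmin <- zoo::rollapply(y, k, min, partial = TRUE, align = "center")
  anchors <- which(y <= rmin + .Machine$double.eps * pmax(abs(y), 1))
  if (!1L %in% anchors) anchors <- c(1L, anchors)
  if (!length(y) %in% anchors) anchors <- c(anchors, length(y))
  interp <- stats::approx(trace@times[anchors], y[anchors],
                          xout = trace@times, rule = 2)$y
  pmin(interp, rmin)
}

#' Static stress difference between two frames
#'
#' Elementwise `frameB - frameA`, valid where both maps are valid. Used to
#' compare the static-period baselines before and after an intervention.
#'
#' @param frameA,frameB [StressMap-class] objects of one shape.
#' @return a [StressMap-class].
#' @export
staticStressDifference <- function(frameA, frameB) {
  stopifnot(is(frameA, "StressMap"), is(frameB, "StressMap"))
  if (!identical(dim(frameA@values), dim(frameB@values)))
    stop("frames must share one shape")
  v <- frameB@values - frameA@values
  ok <- frameA@valid & frameB@valid
  v[!ok] <- NA_real_
  StressMap(v, ok, frameA@pixelLength)
}

#' Amplitude-velocity regression
#'
#' Ordinary least squares of peak vertical velocity on beat amplitude across
#' cells or pixels, with intercept. A mature, synchronously beating
#' monolayer shows a tight linear relation (the slope has units 1/s).
#'
#' @param amplitudes beat amplitudes, um.
#' @param velocities peak velocities, um/s.
#' @return list with `slope` (1/s), `intercept` (um/s), `correlation`
#'   (Pearson R; `NA` with a flag when the response is constant) and
#'   `degenerate` (logical).
#' @export
amplitudeVelocityRegression <- function(amplitudes, velocities) {
  if (length(amplitudes) < 3L || length(amplitudes) != length(velocities))
    stop("need at least 3 paired samples")
  if (stats::var(amplitudes) == 0)
    stop("zero variance in amplitudes")
  fit <- stats::lm(velocities ~ amplitudes)
  degenerate <- stats::var(velocities) == 0
  r <- if (degenerate) NA_real_ else stats::cor(amplitudes, velocities)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = r, degenerate = degenerate)
}

#' Classify a per-cell drug-response series
#'
#' Input is a force series normalized to its first time point. The series is
#' `"non_monotonic"` when any value exceeds the running minimum so far by
#' more than `riseTolerance` (a transient rise before the decline);
#' otherwise `"monotonic_decline"`.
#'
#' @param series normalized force values over time, length `>= 2`.
#' @param riseTolerance allowed rise above the running minimum, as a
#'   fraction of the normalized force.
#' @return `"monotonic_decline"` or `"non_monotonic"`.
#' @examples
#' classifyResponse(c(1, 0.8, 0.6))          # monotonic_decline
#' classifyResponse(c(1, 1.3, 0.9, 0.5))     # non_monotonic
#' @export
classifyResponse <- function(series, riseTolerance = 0.05) {
  if (length(series) < 2L) stop("series must have at least 2 time points")
  runmin <- cummin(series)
  rises <- series[-1] > runmin[-length(series)] + riseTolerance
  if (any(rises)) "non_monotonic" else "monotonic_decline"
}

#' Force-area regression across regions, per timepoint
#'
#' At each timepoint, ordinary least squares of total region force on region
#' area across all regions; the slope (nN/um^2) tracks how compression
#' outpaces spreading over time.
#'
#' @param tables list of region tables (data.frames with `force_nN` and
#'   `area_um2`, e.g. from [regionForces()] with the whole-field row
#'   dropped), one per timepoint, each with `>= 3` regions.
#' @return data.frame with `timepoint`, `slope_nN_um2`, `intercept_nN`,
#'   `correlation`.
#' @export
forceAreaRegression <- function(tables) {
  stopifnot(length(tables) >= 1L)
  out <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    if (nrow(tab) < 3L)
      stop("timepoint ", i, ": need at least 3 regions")
    if (stats::var(tab$area_um2) == 0)
      stop("timepoint ", i, ": degenerate (all region areas equal)")
    fit <- stats::lm(force_nN ~ area_um2, data = tab)
    data.frame(timepoint = i,
               slope_nN_um2 = unname(stats::coef(fit)[2]),
               intercept_nN = unname(stats::coef(fit)[1]),
               correlation = stats::cor(tab$area_um2, tab$force_nN))
  })
  do.call(rbind, out)
}
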