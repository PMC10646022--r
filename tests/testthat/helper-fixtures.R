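## Shared fixtures, built in code once per test run. Everything is seeded so
## the suite is deterministic.

fixSpec <- SubstrateSpec()            # 24 um, 20 kPa, nu 0.49, 550 nm
fixCam <- defaultCameraModel()        # noiseless 16-bit

## a wedge wide enough to cover the default cell scene's wavelength range
## (515-577 nm), and the calibration curve built from it
fixWedge <- makeCalibrationWedge(505, 585, shape = c(16, 300),
                                 camera = fixCam, seed = 1)
fixCurve <- buildCalibration(
  pairHueWavelength(computeHueMap(fixWedge$image), fixWedge$truth))

## independent truth stress from a scene's displacement field (the oracle
## side of recovery comparisons: plain arithmetic, no pipeline code)
truthStress <- function(scene) {
  s <- scene@substrate
  StressMap(s@youngsE / (1 + s@poissonNu) * scene@displacement / s@restD,
            pixelLength = scene@pixelLength)
}

## brute-force centered running minimum (oracle for lowerEnvelope)
bruteRunMin <- function(y, k) {
  h <- (k - 1) %/% 2
  vapply(seq_along(y), function(i)
    min(y[max(1, i - h):min(length(y), i + h)]), numeric(1))
}
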