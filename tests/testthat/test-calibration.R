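test_that("pairing collects exactly the co-valid pixels", {
  h <- HueMap(matrix(c(0.2, 0.3, NA, 0.4), 2, 2))
  w <- WavelengthMap(matrix(c(550, NA, 540, 560), 2, 2))
  p <- pairHueWavelength(h, w)
  expect_equal(nrow(p), 2)
  expect_setequal(p$wavelength_nm, c(550, 560))
  # disjoint validity is an error
  h2 <- HueMap(matrix(c(0.2, NA), 1, 2))
  w2 <- WavelengthMap(matrix(c(NA, 550), 1, 2))
  expect_error(pairHueWavelength(h2, w2), "co-valid")
  # constant maps collapse to one repeated pair value
  h3 <- HueMap(matrix(0.25, 2, 2)); w3 <- WavelengthMap(matrix(551, 2, 2))
  expect_equal(unique(pairHueWavelength(h3, w3)),
               data.frame(hue = 0.25, wavelength_nm = 551))
})

test_that("exactly linear pairs give knots on the line", {
  hue <- seq(0.20, 0.35, length.out = 400)
  wl <- 600 - 300 * hue
  curve <- buildCalibration(data.frame(hue = hue, wavelength_nm = wl))
  k <- calibrationKnots(curve)
  expect_lt(max(abs(k$wavelength_nm - (600 - 300 * k$hue))), 1e-6)
  expect_gt(nrow(k), 50)
})

test_that("binned medians resist symmetric noise and stay monotone", {
  set.seed(42)
  hue <- runif(6000, 0.20, 0.35)
  noiseSD <- 0.4
  wl <- 600 - 300 * hue + rnorm(6000, sd = noiseSD)
  curve <- buildCalibration(data.frame(hue = hue, wavelength_nm = wl))
  k <- calibrationKnots(curve)
  expect_true(all(diff(k$hue) > 0))
  expect_true(all(diff(k$wavelength_nm) < 0))
  expect_lt(max(abs(k$wavelength_nm - (600 - 300 * k$hue))), 2 * noiseSD)
})

test_that("wedge calibration reproduces the truth mapping within 2 nm", {
  hw <- computeHueMap(fixWedge$image)
  wl <- lookupWavelength(hw, fixCurve)
  err <- mapValues(wl) - mapValues(fixWedge$truth)
  expect_lt(sqrt(mean(err^2)), 2)
  # and the pairs themselves lie on a single monotone curve
  p <- pairHueWavelength(hw, fixWedge$truth)
  agg <- tapply(p$wavelength_nm, round(p$hue, 4), mean)
  expect_true(all(diff(as.numeric(agg)) < 0))
})

test_that("lookup interpolates linearly and honors range policies", {
  curve <- buildCalibration(data.frame(
    hue = rep(c(0.1, 0.2, 0.3, 0.4), each = 3),
    wavelength_nm = rep(c(580, 560, 540, 520), each = 3)), binWidth = 0.05)
  k <- calibrationKnots(curve)
  atKnot <- HueMap(matrix(k$hue[2], 1, 1))
  expect_equal(mapValues(lookupWavelength(atKnot, curve))[1, 1],
               k$wavelength_nm[2])
  mid <- HueMap(matrix(mean(k$hue[2:3]), 1, 1))
  expect_equal(mapValues(lookupWavelength(mid, curve))[1, 1],
               mean(k$wavelength_nm[2:3]))
  # out-of-range hue: clamped and flagged, or invalidated
  oor <- HueMap(matrix(0.9, 1, 1))
  cl <- lookupWavelength(oor, curve, "clamp")
  expect_equal(mapValues(cl)[1, 1], min(k$wavelength_nm))
  expect_true(attr(cl, "clamped")[1, 1])
  inv <- lookupWavelength(oor, curve, "invalidate")
  expect_false(mapValid(inv)[1, 1])
  # lookup is injective over the calibrated range (strict monotonicity)
  hs <- HueMap(matrix(seq(min(k$hue), max(k$hue), length.out = 50), 1))
  ws <- mapValues(lookupWavelength(hs, curve))
  expect_equal(length(unique(as.vector(ws))), 50)
})

test_that("curves round-trip through CSV bit-exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeCalibration(fixCurve, path)
  back <- readCalibration(path)
  expect_identical(back@hue, fixCurve@hue)
  expect_identical(back@wavelength, fixCurve@wavelength)
  expect_true("binWidth" %in% names(back@provenance))
})

test_that("degenerate pair sets are rejected", {
  expect_error(buildCalibration(
    data.frame(hue = rep(0.25, 10), wavelength_nm = 1:10)), "2 hue bins")
  expect_error(buildCalibration(
    data.frame(hue = seq(0.1, 0.4, length.out = 20),
               wavelength_nm = rep(550, 20))), "direction")
})
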