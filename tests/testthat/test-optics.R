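test_that("Bragg peak wavelength follows the stop-band condition", {
  expect_equal(braggPeakWavelength(196.4, 1.40, 0), 2 * 196.4 * 1.40)
  expect_equal(braggPeakWavelength(196.4, 1.40, 0), 549.92)
  # n = 1, normal incidence reduces to twice the interplanar distance
  expect_equal(braggPeakWavelength(275, 1, 0), 550)
  # oblique incidence always blue-shifts the peak
  for (th in c(0.1, 0.4, 1.0))
    expect_lt(braggPeakWavelength(200, 1.40, th),
              braggPeakWavelength(200, 1.40, 0))
  expect_error(braggPeakWavelength(200, 0.5, pi / 3), "evanescent")
})

test_that("peak wavelength shifts in proportion to thickness change", {
  s <- fixSpec
  expect_equal(wavelengthFromDisplacement(0, s), s@lambda0)
  # 1% thickness increase gives a 1% red shift
  expect_equal(wavelengthFromDisplacement(0.24, s), 555.5)
  expect_equal(wavelengthFromDisplacement(-1.524, s), 550 * (1 - 1.524 / 24))
  expect_error(wavelengthFromDisplacement(-24, s), "zero thickness")
  # round trip through the mechanics inversion is exact
  for (dd in c(-5, -1.524, -0.01, 0.3, 1.19, 10)) {
    wl <- WavelengthMap(matrix(wavelengthFromDisplacement(dd, s), 1, 1))
    expect_equal(mapValues(displacementMap(wl, s))[1, 1], dd,
                 tolerance = 1e-12)
  }
})

test_that("model reflectance spectrum peaks at the right grid sample", {
  axis <- 420:730
  sp <- reflectanceSpectrum(550, axis, peakHeight = 1, background = 0.05)
  expect_equal(sp[axis == 550], 1.05)
  # symmetry about the peak on a symmetric grid
  expect_equal(sp[axis == 540], sp[axis == 560])
  # argmax lands on the grid point nearest the true center, across offsets
  for (center in seq(540.1, 541.9, by = 0.2)) {
    sp <- reflectanceSpectrum(center, axis)
    expect_equal(axis[which.max(sp)], axis[which.min(abs(axis - center))])
  }
  expect_warning(reflectanceSpectrum(900, axis), "outside the axis")
})

test_that("rendering is deterministic and black for zero reflectance", {
  cam <- fixCam
  zero <- makeHyperspectralStack(matrix(550, 2, 2), background = 0,
                                 peakHeight = 1e-12)
  zero@cube[] <- 0
  img <- renderRGB(zero, cam)
  expect_true(all(img == 0))
  # identical spectra give identical RGB; zero noise ignores the seed
  lam <- matrix(c(530, 530, 551, 551), 2, 2)
  expect_identical(renderRGB(lam, cam, seed = 1), renderRGB(lam, cam, seed = 99))
  img <- renderRGB(lam, cam)
  expect_identical(img[1, 1, ], img[2, 1, ])
})

test_that("rendered hue is strictly monotone in peak wavelength over the band", {
  lam <- matrix(seq(505, 575, by = 1), 1)
  hue <- mapValues(computeHueMap(renderRGB(lam, fixCam)))
  expect_true(all(is.finite(hue)))
  expect_true(all(diff(as.vector(hue)) < 0))   # green hue > yellow hue
})

test_that("hue extraction matches the HSV definition and flags gray pixels", {
  img <- array(0, c(1, 4, 3))
  img[1, 1, ] <- c(1, 0, 0)      # red
  img[1, 2, ] <- c(0, 1, 0)      # green
  img[1, 3, ] <- c(1, 1, 0)      # yellow
  img[1, 4, ] <- c(0.5, 0.5, 0.5) # gray: undefined hue
  h <- computeHueMap(img)
  expect_equal(mapValues(h)[1, 1:3], c(0, 1 / 3, 1 / 6))
  expect_false(mapValid(h)[1, 4])
  expect_error(computeHueMap(matrix(0, 2, 2)), "3")
})

test_that("read noise is seeded and bounded by the camera model", {
  cam <- defaultCameraModel(readNoiseSigma = 0.005)
  lam <- matrix(550, 8, 8)
  a <- renderRGB(lam, cam, seed = 7)
  b <- renderRGB(lam, cam, seed = 7)
  c <- renderRGB(lam, cam, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
  clean <- renderRGB(lam, fixCam)
  expect_lt(max(abs(a - clean)), 6 * 0.005)
})

test_that("substrate and camera validity catch inconsistent physics", {
  expect_error(SubstrateSpec(poissonNu = 0.5), "0.5")
  expect_error(SubstrateSpec(lambda0 = 300), "400")
  # Bragg consistency between lambda0 and (d111, n) is enforced at 1 nm
  expect_error(SubstrateSpec(lambda0 = 560, d111 = 196.4, nAverage = 1.40),
               "Bragg")
  expect_s4_class(SubstrateSpec(lambda0 = 549.92, d111 = 196.4,
                                nAverage = 1.40), "SubstrateSpec")
  expect_error(defaultCameraModel(bitDepth = 12), "8 or 16")
})
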