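test_that("cell scenes hit the configured push and pull extremes", {
  sc <- makeCellScene(nCells = 1, pushDepth = 1.52, pullHeight = 1.19,
                      shape = c(96, 96), seed = 4)
  expect_equal(min(mapValues(sc)), -1.52)
  expect_equal(max(mapValues(sc)), 1.19)
  flat <- makeCellScene(nCells = 0, shape = c(32, 32), seed = 1)
  expect_true(all(mapValues(flat) == 0))
  expect_error(makeCellScene(cellRadius = 50, shape = c(64, 64)),
               "too large")
})

test_that("generators are pure functions of parameters and seed", {
  a <- makeCellScene(nCells = 3, seed = 21)
  b <- makeCellScene(nCells = 3, seed = 21)
  expect_identical(mapValues(a), mapValues(b))
  c <- makeCellScene(nCells = 3, seed = 22)
  expect_false(identical(mapValues(a), mapValues(c)))
  # generators restore the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(makeCellScene(nCells = 2, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("calibration wedge spans its endpoints and matches its cube", {
  w <- makeCalibrationWedge(510, 570, shape = c(8, 61), camera = fixCam)
  ramp <- mapValues(w$truth)[1, ]
  expect_equal(ramp[1], 510)
  expect_equal(ramp[61], 570)
  expect_equal(length(wavelengths(w$stack)), 311)   # 420-730 nm at 1 nm
  # cube argmax per column reproduces the ramp within one grid step
  pk <- peakWavelengthMap(w$stack, refine = FALSE)
  expect_lt(max(abs(mapValues(pk) - mapValues(w$truth))), 1 + 1e-9)
})

test_that("hyperspectral generation inverts exactly at zero noise", {
  lam <- matrix(c(520, 555), 1, 2)
  st <- makeHyperspectralStack(lam, peakHeight = 0.9, fwhm = 25,
                               background = 0.04)
  rs <- reflectionSpectra(st)
  sigma <- 25 / (2 * sqrt(2 * log(2)))
  axis <- wavelengths(st)
  for (j in 1:2) {
    injected <- 0.04 + 0.9 * exp(-(axis - lam[1, j])^2 / (2 * sigma^2))
    expect_equal(rs$reflectance[1, j, ], injected, tolerance = 1e-12)
  }
  # a flat wavelength map gives identical spectra everywhere
  stFlat <- makeHyperspectralStack(matrix(540, 2, 3))
  expect_equal(stFlat@cube[1, 1, ], stFlat@cube[2, 3, ])
})

test_that("beating sequences pulse at the requested frequency", {
  amp <- matrix(0.4, 4, 4)
  bs <- makeBeatingSequence(amp, freq = 1.65, fps = 19.06, duration = 20,
                            render = FALSE)
  peakVal <- vapply(bs$truth, max, numeric(1))
  # count half-wave pulse maxima in the truth: 1.65 Hz over 20 s -> 33
  pulses <- sum(diff(sign(diff(peakVal))) < 0 &
                  peakVal[2:(length(peakVal) - 1)] > 0.2)
  expect_equal(pulses, 33)
  # freq 0 and zero amplitude both give constant stacks
  still <- makeBeatingSequence(amp, freq = 0, fps = 10, duration = 1,
                               render = FALSE)
  expect_true(all(vapply(still$truth,
                         function(m) identical(m, still$truth[[1]]),
                         logical(1))))
  expect_error(makeBeatingSequence(amp, freq = 3, fps = 5), "fps")
})

test_that("aggregate scenes form a V-shaped push with a raised rim", {
  ag <- makeAggregateScene(pushDepth = 0.66, pullHeight = 0.19,
                           radius = 6, shape = c(96, 96),
                           center = c(48, 48))
  v <- mapValues(ag)
  center <- v[48, 48]
  expect_equal(min(v), -0.66, tolerance = 0.02)
  expect_gt(max(v), 0.1)
  # profile through the center falls monotonically to the apex
  profile <- v[48, 48:63]
  expect_true(all(diff(profile) > 0))
  expect_lt(center, -0.6)
})
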