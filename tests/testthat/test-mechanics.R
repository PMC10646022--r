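test_that("displacement inversion matches the fractional peak shift", {
  s <- fixSpec
  expect_equal(mapValues(displacementMap(
    WavelengthMap(matrix(550, 1, 1)), s))[1, 1], 0)
  expect_equal(mapValues(displacementMap(
    WavelengthMap(matrix(555.5, 1, 1)), s))[1, 1], 0.24)
  expect_equal(mapValues(displacementMap(
    WavelengthMap(matrix(515.07, 1, 1)), s))[1, 1], -1.524,
    tolerance = 1e-3)
  # invalid pixels propagate
  wl <- WavelengthMap(matrix(c(555, NA), 1, 2))
  d <- displacementMap(wl, s)
  expect_false(mapValid(d)[1, 2])
})

test_that("vertical stress reproduces the printed worked examples", {
  s <- fixSpec
  tz <- function(dd) mapValues(verticalStressMap(
    DisplacementMap(matrix(dd, 1, 1)), s))[1, 1]
  expect_equal(round(abs(tz(-1.524))), 852)
  expect_equal(round(tz(0.27)), 151)
  expect_equal(round(tz(0.8)), 447)
  expect_equal(round(tz(1.19)), 666)
  expect_equal(tz(0), 0)
  # chain consistency: stress(displacement(wl)) = E/(1+nu) (lambda-l0)/l0
  wl <- WavelengthMap(matrix(seq(515, 577, length.out = 12), 3, 4))
  chain <- verticalStressMap(displacementMap(wl, s), s)
  direct <- s@youngsE / (1 + s@poissonNu) *
    (mapValues(wl) - s@lambda0) / s@lambda0
  expect_equal(mapValues(chain), direct, tolerance = 1e-14)
})

test_that("strain tensor is the symmetric gradient of the field", {
  # uniform translation has zero strain
  z <- strainTensor(ux = matrix(3, 5, 5), uy = matrix(-2, 5, 5), spacing = 1)
  expect_true(all(z@xx == 0) && all(z@yy == 0) && all(z@xy == 0))
  # u_x = a x is exact under central differences
  a <- 0.07
  ux <- outer(rep(1, 6), seq_len(8)) * a
  e <- strainTensor(ux = ux, spacing = 1)
  expect_equal(e@xx, matrix(a, 6, 8), tolerance = 1e-12)
  # pure shear u_x = a y gives e_xy = a / 2
  uxs <- outer(seq_len(6), rep(1, 8)) * a
  es <- strainTensor(ux = uxs, spacing = 1)
  expect_equal(es@xy, matrix(a / 2, 6, 8), tolerance = 1e-12)
  # supplied out-of-plane strain passes through
  ez <- strainTensor(ezz = matrix(0.01, 4, 4))
  expect_equal(ez@zz, matrix(0.01, 4, 4))
})

test_that("constitutive law matches hand algebra in both forms", {
  z <- matrix(0, 3, 3)
  e0 <- strainTensor(ux = z, uy = z, spacing = 1)
  s0 <- stressTensor(e0, E = 2e4, nu = 0.49)
  expect_true(all(s0@xx == 0) && all(s0@zz == 0))
  # incompressible with e_zz = dD/D alone reproduces the vertical traction
  ezz <- -1.524 / 24
  e <- strainTensor(ezz = matrix(ezz, 2, 2))
  s <- stressTensor(e, E = 2e4, nu = 0.49, incompressible = TRUE)
  expect_equal(s@zz[1, 1], 2e4 / 1.49 * ezz)
  # full law, pure volumetric strain: sigma_ii = E eps (1 + 3nu/(1-2nu))/(1+nu)
  eps <- 0.01; nu <- 0.3; E <- 5e4
  ev <- new("StrainField", xx = matrix(eps, 2, 2), yy = matrix(eps, 2, 2),
            zz = matrix(eps, 2, 2), xy = matrix(0, 2, 2),
            xz = matrix(0, 2, 2), yz = matrix(0, 2, 2), spacing = 1)
  sv <- stressTensor(ev, E = E, nu = nu, incompressible = FALSE)
  expect_equal(sv@xx[1, 1], E * eps * (1 + 3 * nu / (1 - 2 * nu)) / (1 + nu),
               tolerance = 1e-12)
  expect_error(stressTensor(ev, E = E, nu = 0.5, incompressible = FALSE),
               "singular")
})

test_that("segmentation finds 8-connected regions above threshold", {
  f <- matrix(0, 20, 20)
  f[3:6, 3:6] <- 0.5
  f[12:16, 12:16] <- -0.8
  labs <- segmentRegions(f, threshold = 0.1, minArea = 4)
  expect_equal(max(labs), 2)
  # diagonal contact merges under 8-connectivity
  g <- matrix(0, 10, 10)
  g[2:4, 2:4] <- 1; g[5:7, 5:7] <- 1      # touch at (4,4)-(5,5) corner
  expect_equal(max(segmentRegions(g, 0.5, minArea = 1)), 1)
  # flat field and sub-minArea blobs give zero labels
  expect_equal(max(segmentRegions(matrix(0, 5, 5), 0.1)), 0)
  small <- matrix(0, 10, 10); small[5, 5] <- 1
  expect_equal(max(segmentRegions(small, 0.5, minArea = 20)), 0)
})

test_that("region forces integrate stress over pixel area", {
  # uniform 852 Pa over 100 px at 0.18 um -> 2.76 nN
  s <- StressMap(matrix(852, 10, 10), pixelLength = 0.18)
  rt <- regionForces(s, matrix(1L, 10, 10))
  expect_equal(signif(rt$force_nN[rt$label == 1], 3), 2.76)
  expect_equal(rt$area_um2[rt$label == 1], 100 * 0.18^2)
  # zero stress, zero forces
  z <- regionForces(StressMap(matrix(0, 4, 4), pixelLength = 0.18))
  expect_true(all(z$force_nN == 0))
  # additivity over disjoint labels
  tz <- matrix(rnorm(400, sd = 300), 20, 20)
  labs <- matrix(0L, 20, 20); labs[1:10, ] <- 1L; labs[11:20, ] <- 2L
  rt2 <- regionForces(StressMap(tz, pixelLength = 0.18), labs)
  whole <- rt2$force_nN[rt2$label == 0]
  expect_equal(rt2$force_nN[rt2$label == 1] + rt2$force_nN[rt2$label == 2],
               whole, tolerance = 1e-12)
  # signed components split the magnitude sum
  expect_equal(rt2$force_up_nN - rt2$force_down_nN, rt2$force_nN,
               tolerance = 1e-12)
})

test_that("linearity: scaling displacement scales stress and forces", {
  sc <- makeCellScene(nCells = 2, cellRadius = 2, shape = c(96, 96), seed = 9)
  s1 <- truthStress(sc)
  sc2 <- sc; sc2@displacement <- sc@displacement * 2.5
  s2 <- truthStress(sc2)
  expect_equal(mapValues(s2), 2.5 * mapValues(s1), tolerance = 1e-12)
  labs <- segmentRegions(sc@displacement, 0.05, 10)
  f1 <- regionForces(s1, labs); f2 <- regionForces(s2, labs)
  expect_equal(f2$force_nN, 2.5 * f1$force_nN, tolerance = 1e-12)
})

test_that("scalar summaries match their definitions", {
  expect_equal(round(foldIncrease(159.63, 953.30), 2), 4.97)
  expect_equal(foldIncrease(10, 10), 0)
  expect_equal(foldIncrease(5, 10), 1)
  expect_error(foldIncrease(0, 10), "positive")
  expect_equal(round(relativeError(514.0, 511.0), 1), 0.6)
  expect_equal(relativeError(42, 42), 0)
  expect_equal(round(relativeError(577.2, 570.0), 2), 1.26)
  expect_error(relativeError(1, 0), "positive")
})

test_that("lambda0 is recoverable from the background mode", {
  sc <- makeCellScene(nCells = 1, shape = c(96, 96), seed = 2)
  lam <- wavelengthFromDisplacement(mapValues(sc), fixSpec)
  est <- estimateLambda0(WavelengthMap(lam))
  expect_lt(abs(est - fixSpec@lambda0), 0.5)
})
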