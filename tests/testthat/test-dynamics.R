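test_that("velocity maps difference adjacent frames and telescope exactly", {
  set.seed(31)
  stack <- lapply(1:6, function(i) matrix(rnorm(64), 8, 8))
  dt <- 0.051
  vel <- velocityMaps(stack, dt)
  expect_length(vel, 5)
  # dH = 0.051 um over 0.051 s is 1 um/s
  two <- velocityMaps(list(matrix(0, 2, 2), matrix(0.051, 2, 2)), 0.051)
  expect_equal(mapValues(two[[1]]), matrix(1, 2, 2))
  # identical frames give zero velocity
  expect_true(all(mapValues(velocityMaps(stack[c(1, 1)], dt)[[1]]) == 0))
  # telescoping: sum v dt = last - first, to machine precision
  total <- Reduce(`+`, lapply(vel, mapValues)) * dt
  expect_equal(total, stack[[6]] - stack[[1]], tolerance = 1e-14)
  expect_error(velocityMaps(stack[1], dt), "2 frames")
})

test_that("total force trace integrates each frame like regionForces", {
  s <- StressMap(matrix(852, 10, 10), pixelLength = 0.18)
  tr <- totalForceTrace(list(s), frameInterval = 0.051)
  expect_equal(signif(traceValues(tr)[1], 3), 2.76)
  zero <- totalForceTrace(list(StressMap(matrix(0, 4, 4),
                                         pixelLength = 0.18)), 0.1)
  expect_equal(traceValues(zero), 0)
  # magnitude mode dominates signed mode pointwise
  set.seed(5)
  stack <- lapply(1:4, function(i)
    StressMap(matrix(rnorm(100, sd = 200), 10, 10), pixelLength = 0.18))
  m <- traceValues(totalForceTrace(stack, 0.05, mode = "magnitude"))
  g <- traceValues(totalForceTrace(stack, 0.05, mode = "signed"))
  expect_true(all(m >= abs(g)))
  expect_error(totalForceTrace(stack, 0.05, roi = matrix(FALSE, 10, 10)),
               "ROI")
})

test_that("beat detection recovers synthetic rates and phase partitions", {
  # a flat trace has no beats
  flat <- ForceTrace(rep(2, 50), 0.05)
  expect_equal(nrow(traceBeats(detectBeats(flat))), 0)
  expect_equal(beatRate(detectBeats(flat)), 0)
  # 1.65 Hz rectified sine sampled at 19.06 fps over ~20 s -> 99 bpm
  fps <- 19.06
  t <- (0:380) / fps
  y <- pmax(0, sin(2 * pi * 1.65 * t))^2 * 10
  tr <- detectBeats(ForceTrace(y, 1 / fps))
  expect_equal(nrow(traceBeats(tr)), 33)
  expect_equal(round(beatRate(tr)), 99)
  # rate recovery across physiological frequencies and frame rates
  for (freq in c(0.5, 1.0, 2.0, 3.0)) {
    for (fps in c(19.06, 30)) {
      tt <- (0:floor(10 * fps)) / fps
      yy <- pmax(0, sin(2 * pi * freq * tt))^2
      got <- nrow(traceBeats(detectBeats(ForceTrace(yy, 1 / fps))))
      expect_lt(abs(got - freq * 10), 1 + 1e-9)
    }
  }
  # one isolated pulse partitions its interval into the three phases
  t1 <- seq(0, 2, by = 0.02)
  y1 <- exp(-(t1 - 1)^2 / (2 * 0.05^2))
  tr1 <- detectBeats(ForceTrace(y1, 0.02))
  expect_equal(nrow(traceBeats(tr1)), 1)
  ph <- tracePhases(tr1)
  expect_equal(ph$systolic_s + ph$diastolic_s + ph$static_s, 2,
               tolerance = 1e-9)
})

test_that("lower envelope tracks the running minimum baseline", {
  # constant trace: envelope equals the constant
  cst <- ForceTrace(rep(3, 40), 0.1)
  expect_equal(lowerEnvelope(cst, 0.5), rep(3, 40))
  # monotone increasing trace: envelope equals the brute-force running min
  inc <- ForceTrace(seq(1, 30, length.out = 60), 0.1)
  env <- lowerEnvelope(inc, 0.7)
  k <- 7
  expect_equal(env, bruteRunMin(traceValues(inc), k))
  # envelope never exceeds the trace
  set.seed(8)
  y <- pmax(0, sin(2 * pi * 1.5 * seq(0, 10, by = 0.05)))^2 +
    seq(0, 1, length.out = 201)
  tr <- ForceTrace(y, 0.05)
  expect_true(all(lowerEnvelope(tr, 1) <= traceValues(tr) + 1e-12))
  expect_error(lowerEnvelope(tr, 0.01), "window")
})

test_that("static stress difference is elementwise and antisymmetric", {
  a <- StressMap(matrix(rnorm(16), 4, 4))
  b <- StressMap(matrix(rnorm(16), 4, 4))
  expect_true(all(mapValues(staticStressDifference(a, a)) == 0))
  d1 <- staticStressDifference(a, b); d2 <- staticStressDifference(b, a)
  expect_equal(mapValues(d1), -mapValues(d2))
  cshift <- StressMap(mapValues(a) + 5)
  expect_equal(mapValues(staticStressDifference(a, cshift)),
               matrix(5, 4, 4))
  expect_error(staticStressDifference(a, StressMap(matrix(0, 2, 2))),
               "shape")
})

test_that("amplitude-velocity regression recovers a known slope", {
  x <- seq(0.1, 1, length.out = 10)
  exact <- amplitudeVelocityRegression(x, 2 * x)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$correlation, 1, tolerance = 1e-12)
  # constant response flags a degenerate correlation
  flat <- amplitudeVelocityRegression(x, rep(1, 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$correlation))
  # noisy simulation: slope within 3 SE of the generating 14 /s
  set.seed(77)
  a <- runif(200, 0, 1)
  v <- 14 * a + rnorm(200, sd = 0.5)
  fit <- amplitudeVelocityRegression(a, v)
  se <- summary(lm(v ~ a))$coefficients[2, 2]
  expect_lt(abs(fit$slope - 14), 3 * se)
  expect_error(amplitudeVelocityRegression(rep(1, 5), rnorm(5)), "variance")
})

test_that("drug-response classification follows the running-minimum rule", {
  expect_equal(classifyResponse(c(1, 0.8, 0.6, 0.4)), "monotonic_decline")
  expect_equal(classifyResponse(c(1, 1.3, 0.9, 0.5)), "non_monotonic")
  expect_equal(classifyResponse(c(1, 1.02, 0.9)), "monotonic_decline")
  # a rise late in the series also counts
  expect_equal(classifyResponse(c(1, 0.5, 0.8, 0.4)), "non_monotonic")
  expect_error(classifyResponse(1), "2 time points")
})

test_that("force-area regression recovers per-timepoint slopes", {
  mk <- function(slope) data.frame(area_um2 = c(100, 200, 300, 400),
                                   force_nN = slope * c(100, 200, 300, 400))
  res <- forceAreaRegression(lapply(c(0.1, 0.1), mk))
  expect_equal(res$slope_nN_um2, c(0.1, 0.1), tolerance = 1e-12)
  # ramped slopes (with noise) are recovered in order
  set.seed(12)
  slopes <- c(0.05, 0.10, 0.15, 0.20)
  tabs <- lapply(slopes, function(s) {
    areas <- runif(30, 500, 4000)
    data.frame(area_um2 = areas,
               force_nN = s * areas + rnorm(30, sd = 10))
  })
  res2 <- forceAreaRegression(tabs)
  expect_equal(res2$slope_nN_um2, slopes, tolerance = 0.05)
  expect_true(all(diff(res2$slope_nN_um2) > 0))
  expect_error(forceAreaRegression(list(data.frame(
    area_um2 = c(1, 1, 1), force_nN = 1:3))), "degenerate")
  expect_error(forceAreaRegression(list(mk(0.1)[1:2, ])), "3 regions")
})
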