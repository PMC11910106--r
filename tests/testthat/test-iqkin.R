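test_that("simulated progress curves obey the kinetic limits", {
  # S0 << Km: early slope = (kcat E / Km) S0 fluorCoeff
  s <- simulateProgressCurves(kcat = 0.02, Km = 60,
                              substrateConcs = c(0.01, 6000),
                              noiseSigma = 0, drift = 0)
  net <- blankSubtract(s)
  slopeLow <- (net@rfu[2, 1] - net@rfu[1, 1]) / 3
  expect_equal(slopeLow, 0.02 * 0.8 / 60 * 0.01 * 12, tolerance = 0.01)
  # S0 >> Km: early slope = kcat E fluorCoeff
  slopeHigh <- (net@rfu[2, 2] - net@rfu[1, 2]) / 3
  expect_equal(slopeHigh, 0.02 * 0.8 * 12, tolerance = 0.01)
  expect_error(simulateProgressCurves(kcat = -1, Km = 5), "kcat")
  expect_error(simulateProgressCurves(kcat = 1, Km = 0), "Km")
})

test_that("the integrator matches the implicit closed-form solution", {
  kcat <- 0.05; Km <- 5; E <- 0.8
  Vmax <- kcat * E
  s0 <- c(0.1, 1, 10, 100)
  times <- seq(0, 150, by = 3)
  got <- mitopink:::.integrateMM(Vmax, Km, s0, times, step = 0.01)
  # the integrated rate law Km ln(S0/S) + (S0 - S) = Vmax t defines S(t)
  # implicitly; solve it by bisection, independently of the integrator
  for (j in seq_along(s0)) {
    ref <- vapply(times, function(t) {
      f <- function(S) Km * log(s0[j] / S) + s0[j] - S - Vmax * t
      uniroot(f, c(s0[j] * 1e-9, s0[j]), tol = 1e-12)$root
    }, numeric(1))
    expect_lt(max(abs(got[, j] - ref) / pmax(ref, 1e-12)), 1e-4)
  }
})

test_that("blank subtraction is elementwise", {
  s <- simulateProgressCurves(kcat = 0.02, Km = 60, noiseSigma = 2,
                              seed = 3)
  net <- blankSubtract(s)
  oracle <- s@rfu
  for (i in seq_len(nrow(oracle))) for (j in seq_len(ncol(oracle)))
    oracle[i, j] <- s@rfu[i, j] - s@blankRfu[i, j]
  expect_equal(net@rfu, oracle)
  # blank == signal -> all zero
  z <- s; z@blankRfu <- s@rfu
  expect_true(all(blankSubtract(z)@rfu == 0))
  # constant blank b reduces every value by b
  cb <- s; cb@blankRfu <- matrix(7, nrow(s@rfu), ncol(s@rfu))
  expect_equal(blankSubtract(cb)@rfu, s@rfu - 7)
})

test_that("the calibration slope converts fluorescence to concentration", {
  expect_equal(as.numeric(calibrationSlope(c(50, 100), c(10, 20))), 5)
  expect_error(calibrationSlope(50, 10), "at least 2")
  s <- simulateProgressCurves(kcat = 0.02, Km = 60, fluorCoeff = 12,
                              noiseSigma = 0)
  expect_equal(as.numeric(calibrationSlope(s@fullDigestDelta,
                                           s@substrateConcs)), 12,
               tolerance = 1e-9)
  # noisy: estimate within 3 SE of truth in almost all replicates. with 7
  # calibration points the pivot is t with 5 df, so the 3-SE coverage is
  # ~97 percent, not the Gaussian 99.7
  hits <- 0L
  set.seed(17)
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 100)
  for (i in 1:100) {
    fd <- 12 * concs + rnorm(7, 0, 3)
    sl <- calibrationSlope(fd, concs)
    if (abs(as.numeric(sl) - 12) <= 3 * attr(sl, "se")) hits <- hits + 1L
  }
  expect_gte(hits, 92L)
})

test_that("initial velocities use a bounded-conversion early window", {
  t <- seq(0, 60, by = 3)
  expect_equal(as.numeric(initialVelocity(t, 10 * t, slopeCal = 5,
                                          s0 = 1000)), 2)
  expect_error(initialVelocity(t[1:3], (10 * t)[1:3], 5, 10),
               "insufficient")
  # noiseless zero-order curve: velocity within 2 percent of kcat E
  s <- simulateProgressCurves(kcat = 0.02, Km = 1,
                              substrateConcs = 100, noiseSigma = 0,
                              drift = 0)
  net <- blankSubtract(s)
  v <- initialVelocity(net@times, net@rfu[, 1], slopeCal = 12, s0 = 100)
  expect_equal(as.numeric(v), 0.02 * 0.8, tolerance = 0.02)
  # fast saturation at low S0: minimum window enforced and flagged
  rfu <- c(0, 40, 48, 50, 50, 50, 50)
  v2 <- initialVelocity(seq(0, 18, by = 3), rfu, slopeCal = 1, s0 = 50)
  expect_true(attr(v2, "high_conversion"))
  expect_equal(attr(v2, "window"), 5L)
})

test_that("the Michaelis-Menten fit recovers exact and noisy parameters", {
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 100)
  v <- mmVelocities(2, 5, concs)
  fit <- fitMM(concs, v, enzymeConc = 0.8)
  expect_equal(Vmax(fit), 2, tolerance = 1e-6)
  expect_equal(Km(fit), 5, tolerance = 1e-6)
  expect_equal(kcat(fit), 2 / 0.8, tolerance = 1e-6)
  expect_equal(catalyticEfficiency(fit), kcat(fit) / Km(fit),
               tolerance = 1e-9)
  # kcat is Vmax over enzyme concentration, exactly
  fit2 <- fitMM(concs, mmVelocities(0.8, 5, concs), enzymeConc = 0.8)
  expect_equal(kcat(fit2), 1, tolerance = 1e-6)
  expect_error(fitMM(c(1, 2, 3), c(1, 2, 3), 0.8), "4 distinct")
  # Monte-Carlo recovery at 5 percent velocity noise
  set.seed(31)
  relErr <- replicate(100, {
    vn <- v * (1 + rnorm(length(v), 0, 0.05))
    abs(Km(fitMM(concs, vn, 0.8)) - 5) / 5
  })
  expect_lte(median(relErr), 0.10)
})

test_that("catalytic efficiency ratios follow from the fits", {
  concs <- c(0.1, 0.3, 1, 3, 10, 30, 100)
  fa <- fitMM(concs, mmVelocities(2, 5, concs), 0.8)
  expect_equal(efficiencyRatio(fa, fa), 1)
  fb <- fitMM(concs, mmVelocities(4, 2.5, concs), 0.8)  # kcat x2, Km /2
  expect_equal(efficiencyRatio(fb, fa), 4, tolerance = 1e-6)
})

test_that("rescaling the fluorescence coefficient cancels out of all fitted quantities", {
  args <- list(kcat = 0.05, Km = 5, noiseSigma = 0)
  a <- analyzeCurveSet(do.call(simulateProgressCurves,
                               c(args, fluorCoeff = 12)))
  b <- analyzeCurveSet(do.call(simulateProgressCurves,
                               c(args, fluorCoeff = 60)))
  expect_equal(kcat(a$fit), kcat(b$fit), tolerance = 1e-9)
  expect_equal(Km(a$fit), Km(b$fit), tolerance = 1e-9)
  expect_equal(a$velocities$v, b$velocities$v, tolerance = 1e-9)
})

test_that("velocities increase with substrate and approach Vmax", {
  a <- analyzeCurveSet(simulateProgressCurves(kcat = 0.05, Km = 5,
                                              noiseSigma = 0))
  expect_true(all(diff(a$velocities$v) > 0))
  expect_lt(max(a$velocities$v), 0.05 * 0.8)
  expect_gt(max(a$velocities$v), 0.9 * 0.05 * 0.8)
})

test_that("plate CSVs round-trip the full curve set", {
  s <- simulateProgressCurves(kcat = 0.05, Km = 5, noiseSigma = 1,
                              seed = 8)
  path <- tempfile(fileext = ".csv")
  writePlateCsv(s, path, replicate = "repA")
  back <- readPlateCsv(path, enzymeConc = 0.8)
  expect_named(back, "repA")
  expect_equal(back$repA@rfu, s@rfu, tolerance = 1e-6)
  expect_equal(back$repA@blankRfu, s@blankRfu, tolerance = 1e-6)
  expect_equal(back$repA@fullDigestDelta, s@fullDigestDelta,
               tolerance = 1e-6)
  f1 <- analyzeCurveSet(s)$fit
  f2 <- analyzeCurveSet(back$repA)$fit
  expect_equal(Km(f1), Km(f2), tolerance = 1e-6)
})
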