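test_that("step response evaluates the multi-exponential decay", {
  ## a unit fast component decays to about 4% within one 1 ms switching interval
  expect_equal(stepResponse(data.frame(amplitude = 1, tau_ms = 0.3), 1.0),
               exp(-1 / 0.3), tolerance = 1e-12)
  expect_lt(abs(stepResponse(data.frame(amplitude = 1, tau_ms = 0.3), 1.0) - 0.0357),
            5e-4)
  ## empty model: no eddy
  expect_identical(stepResponse(data.frame(amplitude = numeric(0), tau_ms = numeric(0)), 2.5), 0)
  ## t = 0 returns the summed amplitudes
  expect_equal(stepResponse(table1Gx, 0), 0.0982 + 0.0788)
  ## vectorized and causal-only
  expect_length(stepResponse(table1Gx, c(0, 1, 2)), 3L)
  expect_error(stepResponse(table1Gx, -0.1), "causal")
})

test_that("coil presets hold the measured component tables exactly", {
  m <- eddyPreset("table1_standard_coil", b0 = FALSE)
  expect_equal(eddyComponents(m, "x"), table1Gx)
  expect_equal(eddyComponents(m, "y"), table1Gy)
  expect_equal(eddyComponents(m, "z"), table1Gz)
  m2 <- eddyPreset("table2_large_coil")
  expect_equal(100 * eddyComponents(m2, "x")$amplitude, c(20.1, 14.6))
  expect_equal(eddyComponents(m2, "x")$tau_ms, c(2.12, 12.7))
  expect_equal(100 * eddyComponents(m2, "z")$amplitude, c(20.4, 19.7))
  expect_equal(eddyComponents(m2, "z")$tau_ms, c(1.48, 9.70))
  expect_equal(nrow(eddyComponents(m2, "y")), 0L)
  expect_equal(presetLabel(eddyPreset("none")), "none")
})

test_that("preset round-trips exactly through the structured-text config", {
  m <- fxEddyT1()
  f <- tempfile(fileext = ".yaml")
  writeEddyConfig(m, f)
  m2 <- readEddyConfig(f)
  for (ax in c("x", "y", "z")) {
    expect_identical(eddyComponents(m2, ax), eddyComponents(m, ax))
    expect_identical(eddyComponents(m2, ax, "b0"), eddyComponents(m, ax, "b0"))
  }
  ## the printed table values come back digit-exact
  expect_identical(100 * eddyComponents(m2, "x")$amplitude, c(9.82, 7.88))
  expect_identical(eddyComponents(m2, "y")$tau_ms, c(0.330, 2.33))
})

test_that("convolution with a step matches the closed-form step response", {
  n <- 6000
  g <- c(rep(0, 1000), rep(153, n - 1000))       # ideal step at 1 ms
  out <- convolveResponse(g, table1Gx, dt = 1)
  tAfter <- c(0.1, 0.5, 1, 3)                    # ms after the step
  idx <- 1001 + tAfter * 1000
  expect_equal(out[idx], -153 * stepResponse(table1Gx, tAfter), tolerance = 5e-3)
  ## causality: nothing before the step
  expect_true(all(out[1:1000] == 0))
  ## sign: a positive step induces an opposing (negative) field
  expect_lt(out[1002], 0)
  ## all-zero drive gives an all-zero field
  expect_identical(convolveResponse(rep(0, 100), table1Gx), rep(0, 100))
})

test_that("a short ramp converges to the ideal step response", {
  n <- 6000
  step <- c(rep(0, 1000), rep(153, n - 1000))
  ramp <- c(rep(0, 1000), seq(0, 153, length.out = 3), rep(153, n - 1003))
  oStep <- convolveResponse(step, table1Gx, dt = 1)
  oRamp <- convolveResponse(ramp, table1Gx, dt = 1)
  after <- 1100:n
  expect_lt(max(abs(oRamp[after] - oStep[after])) / max(abs(oStep[after])), 5e-3)
})

test_that("eddy response is linear in the drive", {
  set.seed(11)
  g1 <- stats::rnorm(2000) * 50
  g2 <- stats::rnorm(2000) * 50
  r12 <- convolveResponse(g1 + g2, table1Gy, dt = 1)
  r1 <- convolveResponse(g1, table1Gy, dt = 1)
  r2 <- convolveResponse(g2, table1Gy, dt = 1)
  expect_equal(r12, r1 + r2, tolerance = 1e-10)
  ## scaling
  expect_equal(convolveResponse(2 * g1, table1Gy, dt = 1), 2 * r1, tolerance = 1e-10)
})

test_that("effectiveGradient perturbs only axes with components and is identity for 'none'", {
  p <- sequenceVariant("test16")
  wf <- buildWaveform(p)
  expect_identical(effectiveGradient(wf, eddyPreset("none"))@g, wf@g)
  pert <- effectiveGradient(wf, fxEddyT1NoB0())
  expect_false(identical(pert@g[, 1], wf@g[, 1]))
  expect_identical(pert@g[, 3], wf@g[, 3])       # no z drive in this sequence
})

test_that("post-lobe residual field decays with the two preset time constants", {
  ## single trapezoid, then fit the tail of the eddy field: both time
  ## constants of the generating model must be recovered
  n <- 30000
  g <- .knotsToSeriesTest(c(0, 1000, 1200, 6000, 6200, n - 1), c(0, 0, 153, 153, 0, 0), n)
  out <- convolveResponse(g, table1Gx, dt = 1)
  tail_t <- seq(6300, 20000, by = 10)
  ser <- new("PeakShiftSeries",
             table = data.frame(delay_ms = (tail_t - 6200) / 1000,
                                amplitude = out[tail_t + 1] / 153),
             axis = "x", prepulseAmplitude = 153, prepulseDuration = 4.8,
             mode = "fast")
  fit <- fitExponentials(ser, 2)
  expect_equal(fit$components$tau_ms, c(0.287, 2.12), tolerance = 0.05)
})

test_that("steady oscillation reaches an antisymmetric periodic eddy cycle", {
  esUs <- 1000
  nCyc <- 30
  kt <- c(0, 500)
  kv <- c(0, 0)
  for (i in seq_len(nCyc)) {
    s <- (-1)^(i - 1)
    kt <- c(kt, 500 + (i - 1) * esUs + c(100, 900))
    kv <- c(kv, s * 153, s * 153)
  }
  n <- 500 + nCyc * esUs + 500
  g <- .knotsToSeriesTest(c(kt, n - 1), c(kv, 0), n)
  out <- convolveResponse(g, table1Gx, dt = 1)
  cyc <- function(i) out[(500 + (i - 1) * esUs) + seq_len(2 * esUs)]
  lateDiff <- max(abs(cyc(26) - cyc(28)))
  earlyDiff <- max(abs(cyc(2) - cyc(4)))
  expect_lt(lateDiff, 0.02 * earlyDiff)
  ## antisymmetry of the settled cycle: half-period shift flips the sign
  settled <- cyc(27)
  expect_lt(max(abs(settled[1:esUs] + settled[esUs + 1:esUs])),
            0.02 * max(abs(settled)))
})

test_that("B0 shift conversion inverts the phase accrual relation", {
  ## 60 and 140 degrees over 0.1 ms correspond to ~0.04 and ~0.09 mT
  expect_equal(b0FromPhase(60, 0.1), (60 / 360) / (gammaProton * 0.1), tolerance = 1e-12)
  expect_lt(abs(b0FromPhase(60, 0.1) - 0.04), 0.002)
  expect_lt(abs(b0FromPhase(140, 0.1) - 0.09), 0.002)
  expect_identical(b0FromPhase(0, 5), 0)
  expect_error(b0FromPhase(60, 0), "> 0")
  ## consistency with the forward accrual: a 0.0391 mT rectangle for 0.1 ms
  ## gives 60 degrees of proton phase
  b0 <- b0FromPhase(60, 0.1)
  expect_equal(360 * gammaProton * b0 * 0.1, 60, tolerance = 1e-9)
})

test_that("B0 shift series is linear in coupling and zero without components", {
  p <- sequenceVariant("test16")
  wf <- buildWaveform(p, reference = TRUE)
  expect_identical(b0ShiftTimeseries(wf, eddyPreset("none")), rep(0, nrow(wf@g)))
  m1 <- eddyModelSet(b0 = list(x = data.frame(coupling_ut = 0.2, tau_ms = 0.1)))
  m2 <- eddyModelSet(b0 = list(x = data.frame(coupling_ut = 0.4, tau_ms = 0.1)))
  expect_equal(b0ShiftTimeseries(wf, m2), 2 * b0ShiftTimeseries(wf, m1),
               tolerance = 1e-12)
})

test_that("calibrated B0 couplings reproduce the target phase alternation", {
  m <- fxEddyT1()
  expect_gt(eddyComponents(m, "y", "b0")$coupling_ut,
            eddyComponents(m, "x", "b0")$coupling_ut)
  ## verified end-to-end (simulated reference scans) in test-simulate.R
  expect_equal(eddyComponents(m, "x", "b0")$tau_ms, 0.1)
})

test_that("model validity catches bad components", {
  expect_error(eddyModelSet(gradient = list(x = data.frame(amplitude = 0.1, tau_ms = -1))),
               "time constants")
  expect_error(stepResponse(data.frame(amplitude = 0.1, tau_ms = 0), 1))
})
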