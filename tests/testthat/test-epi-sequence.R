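test_that("derived quantities reproduce the printed timing arithmetic", {
  one <- fxOneshot()
  d <- derivedQuantities(one)
  expect_equal(d$freq_resolution_hz_per_px, 15.625)
  expect_equal(d$acq_window_ms, 64)
  expect_equal(d$bandwidth_khz, 100)
  expect_equal(d$pixel_um[1], 240)               # 15.36 mm / 64

  d128 <- derivedQuantities(sequenceVariant("multishot128"))
  expect_equal(d128$pixel_um[1], 120)
  expect_equal(d128$scan_time_s, 1.6)            # 4 shots x 400 ms
  expect_equal(d128$acq_window_ms, 64)

  d256 <- derivedQuantities(sequenceVariant("multishot256"))
  expect_equal(d256$pixel_um[1], 60)
  expect_equal(d256$scan_time_s, 6.4)            # 16 shots x 400 ms

  d3 <- derivedQuantities(sequenceVariant("epi3d256"))
  expect_equal(d3$scan_time_s, 102.4)            # 256 shots x 400 ms
  expect_equal(derivedQuantities(sequenceVariant("epi3d256", tr = 800))$scan_time_s,
               204.8)
  expect_error(sequenceParams(c(0L, 0L)), "positive")
})

test_that("T2* of 40 ms gives a ~8 Hz Lorentzian linewidth", {
  expect_equal(lorentzianFwhm(40), 1000 / (pi * 40))
  expect_lt(abs(lorentzianFwhm(40) - 8), 0.05)
})

test_that("the readout train has the specified lobe structure", {
  p <- fxOneshot()
  wf <- buildReadoutTrain(p)
  g <- wf@g[, 1]
  ## lobe amplitude and count: 5 dummies + 64 acquired at 1 ms period
  expect_equal(max(g), 153)
  expect_equal(min(g), -153)
  expect_equal(nrow(wf@acq), 64L)
  ## flat-top value at each acquired echo center alternates sign
  centers <- round(wf@acq$center_us) + 1L
  expect_equal(g[centers], 153 * wf@acq$polarity)
  ## slew never exceeds amplitude / rise time
  expect_lte(maxSlewRate(wf), p@readoutAmplitude / p@riseTime + 1e-9)
  ## waveform starts and ends at zero, and one +/- cycle integrates to zero
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 0)
  b <- round(wf@acq$center_us[2] - 500) + 1L     # boundary between echoes 1|2
  expect_lt(abs(sum(g[b:(b + 1999)])), 1e-9)     # full 2-lobe cycle
  ## the sequence's k velocity spans the full-FOV band: gamma * G * FOV ~ 100 kHz
  expect_equal(gammaProton * 1e-3 * 153 * 15.36, 100, tolerance = 2e-3)
})

test_that("echo spacing too short for the sampling window is rejected", {
  expect_error(sequenceVariant("oneshot64", dwell = 14),
               "too short")
})

test_that("phase encoding tiles the Cartesian grid exactly once per variant", {
  for (v in c("oneshot64", "multishot128", "multishot256", "epi3d256")) {
    p <- sequenceVariant(v)
    lines <- sort(unlist(lapply(seq_len(p@nShots) - 1L,
                                function(s) kyLineIndices(p, s))))
    expect_identical(lines, 0:(p@matrixSize[2] - 1L))
  }
  ## 4-shot interleave: shot s covers lines {s, s+4, s+8, ...}
  p <- sequenceVariant("multishot128")
  expect_identical(kyLineIndices(p, 1L)[1:3], c(1L, 5L, 9L))
  expect_error(kyLineIndices(p, 4L), "out of range")
  expect_error(buildPhaseEncoding(p, shotIndex = -1L), "out of range")
})

test_that("one-shot trajectory covers 64 uniformly spaced ky lines at 1/FOV", {
  p <- fxOneshot()
  tr <- nominalTrajectory(buildWaveform(p))
  kyPerEcho <- unname(vapply(split(tr$ky, tr$echo), function(v) v[65], numeric(1)))
  expect_equal(diff(kyPerEcho), rep(1 / 15.36, 63), tolerance = 1e-9)
  expect_equal(kyPerEcho[1], -32 / 15.36, tolerance = 1e-9)
  ## ky is constant within each sampling window
  spread <- vapply(split(tr$ky, tr$echo), function(v) diff(range(v)), numeric(1))
  expect_lt(max(spread), 1e-9)
})

test_that("reference trajectory crosses k_ro = 0 once per echo at the center sample", {
  p <- fxOneshot()
  tr <- nominalTrajectory(buildWaveform(p, reference = TRUE))
  ns <- samplesPerEcho(p)
  byEcho <- split(tr, tr$echo)
  for (e in c(1, 2, 33, 64)) {
    kx <- byEcho[[e]]$kx
    expect_lt(abs(kx[ns / 2 + 1]), 1e-9)         # zero at the center sample
    expect_equal(sum(diff(kx > 1e-9) != 0), 1L)  # exactly one crossing
  }
  ## phase-encode channel identically zero in reference mode
  expect_lt(max(abs(tr$ky)), 1e-12)
  ## extreme samples approach +/- nx / (2 FOV) (outermost samples ride the
  ## ramps, so the extreme k falls a fraction of a percent short)
  expect_equal(max(tr$kx), 64 / (2 * 15.36), tolerance = 5e-3)
  expect_equal(min(tr$kx), -64 / (2 * 15.36), tolerance = 5e-3)
  ## alternating polarity: even echoes traverse k_ro in reverse
  expect_gt(byEcho[[2]]$kx[10] - byEcho[[2]]$kx[1], 0)
  expect_lt(byEcho[[1]]$kx[10] - byEcho[[1]]$kx[1], 0)
})

test_that("all paper variants build with the 64 ms window and slew bound intact", {
  for (v in c("oneshot64", "multishot128", "multishot256", "epi3d256")) {
    p <- sequenceVariant(v)
    expect_equal(acqWindow(p), 64)
    wf <- buildWaveform(p, shotIndex = p@nShots - 1L,
                        kzIndex = p@matrixSize[3] - 1L)
    expect_lte(maxSlewRate(wf), p@readoutAmplitude / p@riseTime + 1e-9)
    ## prephasing leaves k_ro = 0 at the first acquired echo center
    tr <- nominalTrajectory(wf)
    iro <- match(p@readoutAxis, c("x", "y", "z"))
    k1 <- split(tr[[c("kx", "ky", "kz")[iro]]], tr$echo)[[1]]
    expect_lt(abs(k1[samplesPerEcho(p) / 2 + 1]), 1e-6)
  }
})

test_that("constant phase-encode mode advances ky by one line per echo too", {
  p <- sequenceVariant("test16", blipMode = "constant")
  tr <- nominalTrajectory(buildWaveform(p))
  kyC <- unname(vapply(split(tr$ky, tr$echo), function(v) stats::median(v), numeric(1)))
  expect_equal(diff(kyC), rep(1 / 15.36, 15), tolerance = 1e-3)
})

test_that("waveform and trajectory CSV exports round-trip numerically", {
  p <- sequenceVariant("test16")
  wf <- buildWaveform(p)
  f1 <- tempfile(fileext = ".csv")
  exportWaveformCsv(wf, f1)
  back <- utils::read.csv(f1)
  expect_equal(back$Gx, wf@g[, 1])
  tr <- nominalTrajectory(wf)
  f2 <- tempfile(fileext = ".csv")
  exportTrajectoryCsv(tr, f2)
  expect_equal(utils::read.csv(f2)$kx, tr$kx)
})
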