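test_that("simulation is deterministic given a seed, byte for byte", {
  p <- sequenceVariant("test16")
  ph <- threeDiskPhantom()
  r1 <- simulateEpi(ph, p, noiseSd = 0.01, seed = 7L)
  r2 <- simulateEpi(ph, p, noiseSd = 0.01, seed = 7L)
  expect_identical(trainData(r1), trainData(r2))
  r3 <- simulateEpi(ph, p, noiseSd = 0.01, seed = 8L)
  expect_false(identical(trainData(r1), trainData(r3)))
  ## invalid inputs
  expect_error(simulateEpi(ph, p, noiseSd = -1), "non-negative")
  expect_error(simulateEpi(ph, p, noiseSd = 0.01), "seed")
  expect_error(simulateEpi(ph, p, noiseSd = 0.01, seed = 1.5), "integer")
})

test_that("unperturbed echoes peak at the window center with equal phases", {
  ref <- simulateReference(fxCapillaryIdeal(), fxOneshot())
  prof <- detectEchoPeaks(ref)
  tb <- profileTable(prof)
  ns <- samplesPerEcho(fxOneshot())
  expect_lt(max(abs(tb$position - ns / 2)), 0.02)
  expect_lt(max(abs(wrapDeg(tb$phase_deg - tb$phase_deg[1]))), 1e-6)
})

test_that("reference mode forces phase encoding off and one acquisition", {
  ref <- fxRefEddy()
  expect_equal(ref@mode, "reference")
  expect_equal(dim(trainData(ref))[3], 1L)
  expect_true(all(is.na(lineMap(ref)$kyIndex)))
})

test_that("gradient eddy shifts peak positions while pure B0 eddy shifts phases", {
  p <- fxOneshot()
  ph <- fxCapillary()
  ## gradient-only model: alternating positional shifts, constant phases
  refG <- simulateReference(ph, p, fxEddyT1NoB0())
  tbG <- profileTable(detectEchoPeaks(refG))
  ns <- samplesPerEcho(p)
  expect_gt(max(abs(tbG$position - ns / 2)), 1)
  expect_lt(max(abs(wrapDeg(tbG$phase_deg - tbG$phase_deg[1]))), 2)
  ## B0-only model: alternating phases, centered peaks
  b0only <- eddyModelSet(b0 = list(x = data.frame(coupling_ut = 0.13, tau_ms = 0.1)),
                         preset = "b0only")
  refB <- simulateReference(ph, p, b0only)
  tbB <- profileTable(detectEchoPeaks(refB))
  expect_lt(max(abs(tbB$position - ns / 2)), 0.1)
  expect_gt(stats::median(abs(phaseDifferences(detectEchoPeaks(refB)))), 30)
})

test_that("peak-position fluctuation settles after the early echoes", {
  tb <- profileTable(fxProfileEddy())
  ## odd-parity echoes share one steady position; the early train still
  ## carries the slow-eddy transient
  odd <- tb$position[seq(1, 63, by = 2)]
  early <- abs(diff(odd[1:5]))
  late <- abs(diff(odd[25:31]))
  expect_gt(max(early), 10 * max(late))
  expect_lt(max(late), 0.02)
})

test_that("calibrated B0 coupling reproduces the steady 60/140 degree alternation", {
  ## x readout
  dpx <- phaseDifferences(fxProfileEddy())
  steadyX <- stats::median(abs(dpx[32:63]))
  expect_lt(abs(steadyX - 60), 5)
  ## y readout: same sequence re-axed
  py <- sequenceVariant("oneshot64", readoutAxis = "y", phaseAxis = "x")
  refY <- simulateReference(fxCapillary(), py, fxEddyT1())
  dpy <- phaseDifferences(detectEchoPeaks(refY))
  steadyY <- stats::median(abs(dpy[32:63]))
  expect_lt(abs(steadyY - 140), 5)
})

test_that("reference peak positions are independent of phantom position", {
  p <- fxOneshot()
  eddy <- fxEddyT1()
  shifted <- capillaryPhantom(center = c(1.9, -1.3))
  tbA <- profileTable(fxProfileEddy())
  tbB <- profileTable(detectEchoPeaks(simulateReference(shifted, p, eddy)))
  expect_lt(max(abs(tbA$position - tbB$position)), 0.05)
})

test_that("recon energy matches the rasterized phantom energy (Parseval check)", {
  img <- fxImgIdeal()
  p <- fxOneshot()
  ras <- rasterizePhantom(fxCapillaryIdeal(), 64, 15.36)
  ## image values scale as (N / FOV)^2 relative to the continuous object
  scaled <- imageData(img) * (64 / 15.36)^2
  expect_equal(sum(scaled^2), sum(ras^2), tolerance = 0.1)
})

test_that("shifting the phantom shifts the reconstruction accordingly", {
  p <- sequenceVariant("test16")
  ph0 <- digitalPhantom(data.frame(x_mm = 0, y_mm = 0, r_mm = 0.5, amplitude = 1),
                        t2Star = Inf)
  shift_mm <- c(1.92, -2.88)                     # 2 and -3 pixels at 0.96 mm/px
  ph1 <- digitalPhantom(data.frame(x_mm = shift_mm[1], y_mm = shift_mm[2],
                                   r_mm = 0.5, amplitude = 1), t2Star = Inf)
  rec <- function(ph) imageData(reconstructImage(
    correctEchoTrain(simulateEpi(ph, p), identityProfile(p))))
  i0 <- rec(ph0)
  i1 <- rec(ph1)
  ## integer-pixel circular shift of the unshifted image
  shifted <- i0[((0:15 - 2) %% 16) + 1, ((0:15 + 3) %% 16) + 1]
  expect_lt(max(abs(i1 - shifted)) / max(i0), 0.02)
  ## and the bright pixel sits at the expected location
  w <- which(i1 == max(i1), arr.ind = TRUE)
  expect_equal(unname(w[1, ]), c(8 + 1 + 2, 8 + 1 - 3))
})
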