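test_that("identity-profile correction equals reversal plus decimation", {
  p <- sequenceVariant("test16")
  raw <- simulateEpi(threeDiskPhantom(), p, fxEddyT1(), noiseSd = 0.002, seed = 3L)
  cor <- correctEchoTrain(raw, identityProfile(p))
  expect_identical(trainData(cor), manualDecimate(raw))
  expect_true(cor@corrected)
})

test_that("correction preserves per-echo energy up to band-edge truncation", {
  raw <- fxRawEddy()
  prof <- fxProfileEddy()
  cor <- correctEchoTrain(raw, prof)
  p <- seqParams(raw)
  ## relative to the plain decimated train, the shift + phase stage moves
  ## energy only through the band edge
  eId <- sum(Mod(manualDecimate(raw))^2)
  eOut <- sum(Mod(trainData(cor))^2)
  expect_lt(abs(eOut - eId) / eId, 0.02)
  ## the resampling/phase stage itself is unitary: an integer shift of a
  ## periodic vector changes nothing
  ## the fractional shift is unitary except for the split Nyquist bin
  v <- trainData(raw)[, 1, 1]
  expect_equal(sum(Mod(v)^2),
               sum(Mod(epighost:::sincShift(v, 3.7))^2), tolerance = 1e-5)
})

test_that("geometry hash mismatches and echo-count mismatches are rejected", {
  p <- sequenceVariant("test16")
  raw <- simulateEpi(threeDiskPhantom(), p)
  pOther <- sequenceVariant("test16", te = 32)
  expect_error(correctEchoTrain(raw, identityProfile(pOther)), "geometry")
  expect_error(correctEchoTrain(correctEchoTrain(raw, identityProfile(p)),
                                identityProfile(p)), "already corrected")
})

test_that("phase differences wrap correctly", {
  mk <- function(phases) new("ReferenceScanProfile",
    table = data.frame(echo = seq_along(phases), position = 8,
                       phase_deg = phases, polarity = 1),
    paramsHash = "h", meta = list(samplesPerEcho = 16))
  expect_equal(phaseDifferences(mk(rep(12, 5))), rep(0, 4))
  expect_equal(phaseDifferences(mk(c(30, -30, 30, -30))), c(-60, 60, -60))
  expect_equal(phaseDifferences(mk(c(170, -170))), 20)   # wraps through 180
  expect_error(phaseDifferences(mk(5)), "at least 2")
})

test_that("flat echoes are reported with their index", {
  p <- sequenceVariant("test16")
  ref <- simulateReference(threeDiskPhantom(), p)
  ref@data[, 3, 1] <- 0
  expect_error(detectEchoPeaks(ref), "echo 3")
})

test_that("unperturbed capillary recon resolves the 19 lumens in place", {
  img <- fxImgIdeal()
  m <- imageData(img)
  ph <- fxCapillaryIdeal()
  px <- 15.36 / 64
  ## each lumen's local maximum lies within one pixel of the true center
  for (j in seq_len(19)) {
    ci <- round(ph@disks$x_mm[j] / px) + 33
    cj <- round(ph@disks$y_mm[j] / px) + 33
    win <- m[ci + (-2:2), cj + (-2:2)]
    w <- which(win == max(win), arr.ind = TRUE)
    expect_lte(max(abs(w[1, ] - 3)), 1)
  }
  ## lumen centers are bright, inter-capillary glass is dark
  expect_gt(m[33, 33], 4 * stats::median(m))
})

test_that("a small off-center disk reconstructs at its location", {
  p <- sequenceVariant("test16")
  ph <- digitalPhantom(data.frame(x_mm = 1.92, y_mm = -0.96, r_mm = 0.5,
                                  amplitude = 1), t2Star = Inf)
  img <- imageData(reconstructImage(
    correctEchoTrain(simulateEpi(ph, p), identityProfile(p))))
  w <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(w[1, ]), c(9 + 2, 9 - 1))  # +2 / -1 pixels at 0.96 mm/px
})

test_that("multishot sampling is equivalent to directly assembled k-space", {
  ## 4-shot 128^2 without eddy or relaxation: the corrected, reordered lines
  ## must equal the analytic transform on the Cartesian grid (same k data
  ## implies the same image)
  p <- sequenceVariant("multishot128")
  ph <- threeDiskPhantom(scale = 2, t2Star = Inf)
  raw <- simulateEpi(ph, p)
  img <- reconstructImage(correctEchoTrain(raw, identityProfile(p)))
  n <- 128
  ## readout k step actually sampled: gamma * G * dwell; phase-encode lines
  ## sit exactly on the 1/FOV grid
  dkx <- epighost::gammaProton * 1e-3 * 153 * 0.01
  kvx <- (seq_len(n) - 1 - n / 2) * dkx
  kvy <- (seq_len(n) - 1 - n / 2) / 15.36
  grid <- expand.grid(kx = kvx, ky = kvy)
  K <- matrix(analyticKspace(ph, grid$kx, grid$ky), n, n)
  K[1, ] <- 0                                    # unpaired -k_max edge cell
  sh <- function(m, idx) m[idx, idx]
  ish <- c((n / 2 + 1):n, 1:(n / 2))
  ref <- Mod(sh(stats::fft(sh(K, ish), inverse = TRUE) / n^2, ish))
  expect_lt(max(abs(imageData(img) - ref)) / max(ref), 1e-6)
})

test_that("missing k-space lines are reported by index", {
  p <- sequenceVariant("test16")
  raw <- simulateEpi(threeDiskPhantom(), p)
  cor <- correctEchoTrain(raw, identityProfile(p))
  cor@lineMap <- cor@lineMap[-c(3, 5), ]
  expect_error(reconstructImage(cor), "missing 2 line")
  expect_error(reconstructImage(correctEchoTrain(
    simulateReference(threeDiskPhantom(), p), identityProfile(p))),
    "reference")
})

test_that("ghost metric recovers a constructed signal/ghost ratio", {
  n <- 64
  obj <- rasterizePhantom(digitalPhantom(
    data.frame(x_mm = 0, y_mm = 0, r_mm = 2.5, amplitude = 1)), n, 15.36)
  synth <- obj + 0.1 * obj[, ((0:(n - 1) + n / 2) %% n) + 1]
  img <- new("ReconImage", data = synth, fov = rep(15.36, 3), provenance = "synthetic")
  rep_ <- ghostRatio(img, roiPx = 6)
  expect_equal(rep_@ratio, 10, tolerance = 0.02)
  expect_false(rep_@capped)
  ## degenerate: zero ghost region is capped and flagged
  img0 <- new("ReconImage", data = obj, fov = rep(15.36, 3), provenance = "synthetic")
  rep0 <- ghostRatio(img0, roiPx = 6)
  expect_true(rep0@capped)
  expect_gt(rep0@ratio, 1e10)
  expect_error(ghostRatio(img, roiPx = 40L), "too large")
})

test_that("reference-scan correction beats the uncorrected reconstruction", {
  raw <- fxRawEddy()
  p <- fxOneshot()
  imgU <- reconstructImage(correctEchoTrain(raw, identityProfile(p)))
  imgC <- reconstructImage(correctEchoTrain(raw, fxProfileEddy()))
  expect_gt(ghostRatio(imgC)@ratio, ghostRatio(imgU)@ratio)
  ras <- rasterizePhantom(fxCapillary(), 64, 15.36)
  expect_lt(rmsImageError(imgC, ras), rmsImageError(imgU, ras))
  ## provenance records the stages
  expect_true(any(grepl("refscan-correct", provenance(imgC))))
})

test_that("linear resampling kernel is available and close to the sinc kernel", {
  raw <- fxRawEddy()
  corS <- correctEchoTrain(raw, fxProfileEddy(), kernel = "sinc")
  corL <- correctEchoTrain(raw, fxProfileEddy(), kernel = "linear")
  relDiff <- sum(Mod(trainData(corS) - trainData(corL))^2) /
    sum(Mod(trainData(corS))^2)
  expect_lt(relDiff, 0.01)
  expect_equal(corL@meta$correction$kernel, "linear")
})

test_that("3D reconstruction places the planar object in the central slice", {
  p <- sequenceVariant("test16", matrixSize = c(16L, 16L, 2L))
  raw <- simulateEpi(threeDiskPhantom(scale = 1.2, t2Star = Inf), p)
  img <- reconstructImage(correctEchoTrain(raw, identityProfile(p)))
  m <- imageData(img)
  expect_equal(dim(m), c(16L, 16L, 2L))
  expect_gt(sum(m[, , 2]^2), 1e3 * sum(m[, , 1]^2))
})
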