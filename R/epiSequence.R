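## EPI sequence construction: parameter sets, gradient waveform synthesis on a
## 1 us raster, phase-encoding schemes (one-shot blips, interleaved multishot,
## 3D), nominal k-space trajectories, and derived timing/resolution numbers.

.axisCol <- function(axis) match(axis, c("x", "y", "z"))

#' Construct EPI sequence parameters
#'
#' See [SequenceParams-class] for the meaning of each field and
#' [sequenceVariant()] for the standard presets. Defaults follow the one-shot
#' sequence: 153 mT/m readout lobes with 0.2 ms rise time on a 1 us controller
#' raster, 10 us Nyquist dwell with double oversampling, five dummy switchings
#' before data acquisition, TE 80 ms, TR 400 ms.
#'
#' @param matrixSize integer (nx, ny) or (nx, ny, nz).
#' @param fov field of view, mm; scalar (isotropic) or per axis.
#' @param echoSpacing,riseTime,readoutAmplitude,dwell,oversampling,nDummy,te,tr
#'   see [SequenceParams-class].
#' @param nShots,echoesPerShot shot structure (product must equal ny).
#' @param readoutAxis,phaseAxis,sliceAxis axis assignment.
#' @param blipMode "blip" or "constant".
#' @return a validated [SequenceParams-class].
#' @export
sequenceParams <- function(matrixSize, fov = 15.36, echoSpacing = 1,
                           riseTime = 0.2, readoutAmplitude = 153, dwell = 10,
                           oversampling = 2L, nDummy = 5L, te = 80, tr = 400,
                           nShots = 1L, echoesPerShot = NULL,
                           readoutAxis = "x", phaseAxis = "y", sliceAxis = "z",
                           blipMode = "blip") {
  matrixSize <- as.integer(matrixSize)
  if (length(matrixSize) == 2L) matrixSize <- c(matrixSize, 1L)
  if (length(matrixSize) != 3L || any(matrixSize < 1L))
    stop("matrixSize must give positive (nx, ny[, nz])")
  if (any(fov <= 0)) stop("fov must be positive")
  if (length(fov) == 1L) fov <- rep(fov, 3)
  if (is.null(echoesPerShot)) echoesPerShot <- matrixSize[2L] %/% as.integer(nShots)
  new("SequenceParams",
      matrixSize = matrixSize, fov = as.numeric(fov),
      echoSpacing = echoSpacing, riseTime = riseTime,
      readoutAmplitude = readoutAmplitude, dwell = dwell,
      oversampling = as.integer(oversampling), nDummy = as.integer(nDummy),
      te = te, tr = tr, nShots = as.integer(nShots),
      echoesPerShot = as.integer(echoesPerShot),
      readoutAxis = readoutAxis, phaseAxis = phaseAxis, sliceAxis = sliceAxis,
      blipMode = blipMode)
}

#' Standard sequence variants
#'
#' The four acquisitions of the study plus a small test variant:
#' \describe{
#'   \item{oneshot64}{64 x 64 in one shot, 1 ms echo spacing, 64 echoes.}
#'   \item{multishot128}{128 x 128 in 4 interleaved shots of 32 echoes, 2 ms
#'     echo spacing.}
#'   \item{multishot256}{256 x 256 in 16 shots of 16 echoes, 4 ms echo
#'     spacing.}
#'   \item{epi3d256}{256 x 256 x 16 3D: the 16-shot scheme with 16 additional
#'     through-plane phase encodes (256 shots total).}
#'   \item{test16}{16 x 16 one-shot miniature (16 ms window, TE 30 ms) for
#'     fast exercises.}
#' }
#' All full-size variants keep the 64 ms total data-acquisition window
#' (`echoesPerShot * echoSpacing`), FOV 15.36 mm, TR 400 ms.
#'
#' @param name variant name.
#' @param ... overrides passed to [sequenceParams()].
#' @return a [SequenceParams-class].
#' @examples
#' derivedQuantities(sequenceVariant("multishot128"))
#' @export
sequenceVariant <- function(name = c("oneshot64", "multishot128", "multishot256",
                                     "epi3d256", "test16"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    oneshot64    = list(matrixSize = c(64L, 64L, 1L), echoSpacing = 1,
                        nShots = 1L, echoesPerShot = 64L),
    multishot128 = list(matrixSize = c(128L, 128L, 1L), echoSpacing = 2,
                        nShots = 4L, echoesPerShot = 32L),
    multishot256 = list(matrixSize = c(256L, 256L, 1L), echoSpacing = 4,
                        nShots = 16L, echoesPerShot = 16L),
    epi3d256     = list(matrixSize = c(256L, 256L, 16L), echoSpacing = 4,
                        nShots = 16L, echoesPerShot = 16L),
    test16       = list(matrixSize = c(16L, 16L, 1L), echoSpacing = 1,
                        nShots = 1L, echoesPerShot = 16L, te = 30))
  args <- utils::modifyList(base, list(...))
  do.call(sequenceParams, args)
}

#' Derived timing and resolution quantities
#'
#' @param params a [SequenceParams-class].
#' @return a list: `pixel_um` (per axis), `freq_resolution_hz_per_px`
#'   (1 / acquisition window), `bandwidth_khz` (quadrature receiver bandwidth,
#'   1 / dwell), `acq_window_ms`, `scan_time_s` (shots x kz encodes x TR), and
#'   `n_excitations`.
#' @examples
#' derivedQuantities(sequenceVariant("oneshot64"))$freq_resolution_hz_per_px
#' @export
derivedQuantities <- function(params) {
  stopifnot(is(params, "SequenceParams"))
  m <- params@matrixSize
  if (any(m == 0L) || any(params@fov == 0)) stop("matrix and fov must be nonzero")
  nEx <- params@nShots * m[3L]
  list(
    pixel_um = 1000 * params@fov / m,
    freq_resolution_hz_per_px = 1000 / acqWindow(params),
    bandwidth_khz = 1000 / params@dwell,
    acq_window_ms = acqWindow(params),
    scan_time_s = nEx * params@tr / 1000,
    n_excitations = nEx)
}

#' Lorentzian full width at half maximum from T2*
#'
#' An exponential decay with time constant T2* has a Lorentzian spectrum of
#' FWHM `1 / (pi * T2*)`; 40 ms gives about 8 Hz.
#'
#' @param t2StarMs decay constant, ms.
#' @return FWHM in Hz.
#' @export
lorentzianFwhm <- function(t2StarMs) 1000 / (pi * t2StarMs)

## ---- internal timing layout -------------------------------------------------

## all times in integer us from excitation (t = 0); raster index i <-> (i-1) us
.seqLayout <- function(params) {
  esUs <- params@echoSpacing * 1000
  riseUs <- params@riseTime * 1000
  wUs <- acqWindow(params) * 1000
  teUs <- params@te * 1000
  acqStart <- teUs - wUs / 2
  trainStart <- acqStart - params@nDummy * esUs
  if (trainStart < 2 * riseUs + 200)
    stop("TE too short: readout train would start before excitation")
  nLobes <- params@nDummy + params@echoesPerShot
  trainEnd <- trainStart + nLobes * esUs
  totalUs <- trainEnd + esUs
  list(esUs = esUs, riseUs = riseUs, teUs = teUs, tcUs = teUs / 2,
       acqStart = acqStart, trainStart = trainStart, trainEnd = trainEnd,
       nLobes = nLobes, totalUs = totalUs, n = as.integer(totalUs) + 1L,
       boundaries = trainStart + (0:nLobes) * esUs,
       echoCenters = trainStart + (params@nDummy + seq_len(params@echoesPerShot) - 0.5) * esUs,
       echoPolarity = (-1)^(params@nDummy + seq_len(params@echoesPerShot) - 1))
}

## piecewise-linear series from (time us, value) knots on the 1 us raster
.knotsToSeries <- function(knots, n) {
  kt <- knots$t
  kv <- knots$v
  o <- order(kt)
  stats::approx(kt[o], kv[o], xout = 0:(n - 1L), rule = 2)$y
}

.emptyWaveform <- function(params, lay) {
  g <- matrix(0, nrow = lay$n, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  acq <- data.frame(echo = seq_len(params@echoesPerShot),
                    center_us = lay$echoCenters,
                    nSamples = samplesPerEcho(params),
                    sampleDt_us = sampleDt(params),
                    polarity = lay$echoPolarity)
  new("GradientWaveform", dt = 1, g = g, acq = acq, tcUs = lay$tcUs,
      meta = list(params = params, paramsHash = paramsHash(params)))
}

## trapezoidal prephase block on one axis with the given area (mT/m * ms),
## placed in the window [from, to] us; returns updated knot list
.prephaseKnots <- function(area, from, to, riseUs, maxAmp) {
  durUs <- to - from
  flatUs <- durUs - 2 * riseUs
  if (flatUs < 0) stop("prephase window too short")
  amp <- area / ((durUs - riseUs) / 1000)
  if (abs(amp) > maxAmp + 1e-9)
    stop(sprintf("prephase amplitude %.3g mT/m exceeds the %.3g mT/m limit", amp, maxAmp))
  list(t = c(from, from + riseUs, to - riseUs, to),
       v = c(0, amp, amp, 0))
}

## choose the prephase window: after the refocusing pulse when the readout
## train leaves room there, otherwise right after excitation (the conjugation
## then flips its effect, which callers account for via the returned sign).
## the block must fit entirely on one side of the conjugation time. duration
## is sized so the trapezoid amplitude stays below ~85% of the lobe amplitude
.prephaseWindow <- function(lay, params, areaAbs) {
  A <- params@readoutAmplitude
  durUs <- round(max(1000 * (areaAbs / (0.85 * A) + params@riseTime),
                     3 * lay$riseUs))
  margin <- 100
  if (lay$trainStart - lay$tcUs >= durUs + 2 * margin)
    return(list(from = lay$tcUs + margin, to = lay$tcUs + margin + durUs, sign = +1))
  if (min(lay$tcUs, lay$trainStart) >= durUs + 2 * margin)
    return(list(from = margin, to = margin + durUs, sign = -1))
  stop("no room for a prephase block between excitation and the readout train")
}

## ---- waveform builders ------------------------------------------------------

#' Build the oscillating readout gradient train
#'
#' Alternating trapezoidal lobes at +/- the readout amplitude with linear
#' ramps of `riseTime` (ramp rate amplitude/riseTime, so a polarity transition
#' takes `2 * riseTime`), one lobe per `echoSpacing`, `nDummy` full lobes
#' before data acquisition, and a prephasing lobe that zeroes the readout
#' k-coordinate at the center of the first acquired echo (equivalently,
#' places k at -k_max at that echo's start). Acquisition windows are centered
#' on the lobe flat-tops; with the one-shot timing the outermost samples ride
#' the ramp ends.
#'
#' @param params a [SequenceParams-class].
#' @return a [GradientWaveform-class] with the readout channel populated.
#' @export
buildReadoutTrain <- function(params) {
  stopifnot(is(params, "SequenceParams"))
  lay <- .seqLayout(params)
  A <- params@readoutAmplitude
  b <- lay$boundaries
  nL <- lay$nLobes
  signs <- (-1)^(seq_len(nL) - 1)
  kt <- c(0, b[1])
  kv <- c(0, 0)
  kt <- c(kt, b[1] + lay$riseUs); kv <- c(kv, A)             # initial rise
  for (i in 2:nL) {                                          # polarity transitions
    kt <- c(kt, b[i] - lay$riseUs, b[i] + lay$riseUs)
    kv <- c(kv, signs[i - 1] * A, signs[i] * A)
  }
  kt <- c(kt, b[nL + 1] - lay$riseUs, b[nL + 1], lay$totalUs)  # final fall
  kv <- c(kv, signs[nL] * A, 0, 0)
  wf <- .emptyWaveform(params, lay)
  iro <- .axisCol(params@readoutAxis)
  wf@g[, iro] <- .knotsToSeries(list(t = kt, v = kv), lay$n)
  ## prephase: solve numerically for the area that zeroes k_ro (after the
  ## TE/2 conjugation) at the first acquired echo center
  kro <- .cumK(wf@g[, iro], wf@dt, lay$tcUs)
  kAtFirst <- kro[round(lay$echoCenters[1]) + 1L]
  areaAbs <- abs(kAtFirst) / (gammaProton * 1e-3)             # mT/m * ms
  win <- .prephaseWindow(lay, params, areaAbs)
  areaNeeded <- -win$sign * kAtFirst / (gammaProton * 1e-3)
  pp <- .prephaseKnots(areaNeeded, win$from, win$to, lay$riseUs, A)
  wf@g[, iro] <- wf@g[, iro] + .knotsToSeries(pp, lay$n)
  wf
}

#' Build the phase-encoding channel(s) for one shot
#'
#' In `"blip"` mode (default): a pre-readout encode sets the in-plane
#' phase-encode coordinate to line `shotIndex` (0-based, bottom-up), and a
#' train of triangular blips between acquired echoes advances ky by `nShots`
#' lines per echo, so the interleaves of all shots tile the Cartesian ky grid
#' exactly once. In `"constant"` mode the blip train is replaced by a constant
#' low-amplitude gradient of equal per-echo area across the acquisition. For
#' 3D (`nz > 1`), `kzIndex` selects the through-plane encode applied with the
#' pre-readout block.
#'
#' @param params a [SequenceParams-class].
#' @param shotIndex 0-based shot number in `[0, nShots)`.
#' @param kzIndex 0-based through-plane encode in `[0, nz)`.
#' @param reference logical; TRUE returns identically zero channels (the
#'   reference scan switches phase encoding off).
#' @return a [GradientWaveform-class] with phase/slice channels populated.
#' @export
buildPhaseEncoding <- function(params, shotIndex = 0L, kzIndex = 0L,
                               reference = FALSE) {
  stopifnot(is(params, "SequenceParams"))
  if (shotIndex < 0 || shotIndex >= params@nShots)
    stop(sprintf("shotIndex %d out of range [0, %d)", shotIndex, params@nShots))
  if (kzIndex < 0 || kzIndex >= params@matrixSize[3L])
    stop(sprintf("kzIndex %d out of range [0, %d)", kzIndex, params@matrixSize[3L]))
  lay <- .seqLayout(params)
  wf <- .emptyWaveform(params, lay)
  wf@meta$shotIndex <- as.integer(shotIndex)
  wf@meta$kzIndex <- as.integer(kzIndex)
  wf@meta$reference <- reference
  if (reference) return(wf)

  m <- params@matrixSize
  ipe <- .axisCol(params@phaseAxis)
  gam <- gammaProton * 1e-3                       # cycles/mm per mT/m per ms
  ## pre-readout encode: ky of the first acquired line of this shot
  ky0 <- (shotIndex - m[2L] / 2) / params@fov[ipe]
  win <- .prephaseWindow(lay, params, abs(ky0 / gam))
  areaPe <- win$sign * ky0 / gam                  # mT/m * ms
  knots <- .prephaseKnots(areaPe, win$from, win$to, lay$riseUs, params@readoutAmplitude)
  wf@g[, ipe] <- .knotsToSeries(knots, lay$n)

  dky <- params@nShots / params@fov[ipe]
  blipArea <- dky / gam                           # mT/m * ms per echo advance
  if (params@blipMode == "blip") {
    ## triangular blips centered on the lobe boundaries between acquired
    ## echoes, kept clear of the sampling windows
    sampUs <- m[1L] * params@dwell
    base <- max(4, 2 * floor(0.4 * (lay$esUs - sampUs)))
    amp <- 2 * blipArea / (base / 1000)
    bl <- lay$boundaries[(params@nDummy + 2):(lay$nLobes)]
    if (length(bl)) {
      kt <- as.vector(rbind(bl - base / 2, bl, bl + base / 2))
      kv <- rep(c(0, amp, 0), length(bl))
      wf@g[, ipe] <- wf@g[, ipe] +
        .knotsToSeries(list(t = c(0, kt, lay$totalUs), v = c(0, kv, 0)), lay$n)
    }
  } else {
    ## constant phase-encode gradient across the acquired train with the same
    ## per-echo area; ramped on/off over riseTime around the acquired lobes
    ampC <- blipArea / params@echoSpacing
    from <- lay$boundaries[params@nDummy + 1] + lay$esUs / 2
    to <- lay$boundaries[lay$nLobes + 1] - lay$esUs / 2
    wf@g[, ipe] <- wf@g[, ipe] + .knotsToSeries(
      list(t = c(0, from - lay$riseUs, from, to, to + lay$riseUs, lay$totalUs),
           v = c(0, 0, ampC, ampC, 0, 0)), lay$n)
  }

  if (m[3L] > 1L) {
    isl <- .axisCol(params@sliceAxis)
    kz0 <- (kzIndex - m[3L] / 2) / params@fov[isl]
    if (abs(kz0) > 0) {
      winZ <- .prephaseWindow(lay, params, abs(kz0 / gam))
      knotsZ <- .prephaseKnots(winZ$sign * kz0 / gam, winZ$from, winZ$to,
                               lay$riseUs, params@readoutAmplitude)
      wf@g[, isl] <- .knotsToSeries(knotsZ, lay$n)
    }
  }
  wf
}

#' Assemble the full per-shot gradient waveform
#'
#' Sum of [buildReadoutTrain()] and [buildPhaseEncoding()] channels.
#'
#' @inheritParams buildPhaseEncoding
#' @return a [GradientWaveform-class].
#' @export
buildWaveform <- function(params, shotIndex = 0L, kzIndex = 0L, reference = FALSE) {
  ro <- buildReadoutTrain(params)
  pe <- buildPhaseEncoding(params, shotIndex, kzIndex, reference = reference)
  out <- pe
  out@g <- ro@g + pe@g
  out
}

## cumulative k (cycles/mm) for one channel with spin-echo conjugation at tcUs;
## trapezoidal integration on the raster
.cumK <- function(g, dt, tcUs) {
  gam <- gammaProton * 1e-3                       # cycles/mm per mT/m per ms
  k <- gam * (dt / 1000) * (cumsum(g) - (g + g[1]) / 2)
  if (!is.na(tcUs)) {
    tcIdx <- round(tcUs / dt) + 1L
    if (tcIdx >= 1 && tcIdx <= length(k)) {
      sel <- seq_along(k) > tcIdx
      k[sel] <- k[sel] - 2 * k[tcIdx]
    }
  }
  k
}

#' k-space trajectory at the acquisition sample times
#'
#' Integrates the waveform (`k(t) = gamma * integral G dt`, with the
#' 180-degree refocusing modelled as conjugation of the accumulated k at
#' TE/2) and evaluates it at every acquisition sample.
#'
#' @param waveform a [GradientWaveform-class] (typically from
#'   [buildWaveform()] or [effectiveGradient()]).
#' @return a data.frame with one row per sample: `echo`, `sample` (1-based
#'   within the echo), `t_us`, `kx`, `ky`, `kz` (cycles/mm), `polarity`.
#' @export
nominalTrajectory <- function(waveform) {
  stopifnot(is(waveform, "GradientWaveform"))
  k <- vapply(1:3, function(i) .cumK(waveform@g[, i], waveform@dt, waveform@tcUs),
              numeric(nrow(waveform@g)))
  acq <- waveform@acq
  tAll <- lapply(seq_len(nrow(acq)), function(e) {
    ns <- acq$nSamples[e]
    acq$center_us[e] + (seq_len(ns) - 1 - ns / 2) * acq$sampleDt_us[e]
  })
  tUs <- unlist(tAll)
  tGrid <- (0:(nrow(waveform@g) - 1L)) * waveform@dt
  kS <- vapply(1:3, function(i) stats::approx(tGrid, k[, i], xout = tUs)$y,
               numeric(length(tUs)))
  data.frame(
    echo = rep(acq$echo, vapply(tAll, length, 1L)),
    sample = unlist(lapply(tAll, seq_along)),
    t_us = tUs, kx = kS[, 1], ky = kS[, 2], kz = kS[, 3],
    polarity = rep(acq$polarity, vapply(tAll, length, 1L)))
}

#' ky (and kz) line indices covered by each shot
#'
#' 0-based bottom-up line labels: shot `s` of an `nShots`-shot interleave
#' acquires lines `s, s + nShots, s + 2 nShots, ...`.
#'
#' @param params a [SequenceParams-class].
#' @param shotIndex 0-based shot.
#' @return integer vector of length `echoesPerShot`.
#' @export
kyLineIndices <- function(params, shotIndex = 0L) {
  stopifnot(is(params, "SequenceParams"))
  if (shotIndex < 0 || shotIndex >= params@nShots)
    stop(sprintf("shotIndex %d out of range [0, %d)", shotIndex, params@nShots))
  as.integer(shotIndex + (seq_len(params@echoesPerShot) - 1L) * params@nShots)
}

#' Maximum slew rate of a waveform, mT/m/ms
#'
#' @param waveform a [GradientWaveform-class].
#' @return maximum over channels and time of |dG/dt|.
#' @export
maxSlewRate <- function(waveform) {
  stopifnot(is(waveform, "GradientWaveform"))
  max(abs(apply(waveform@g, 2, diff))) / (waveform@dt / 1000)
}
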