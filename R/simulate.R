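## Raw EPI signal synthesis: sample the phantom's analytic k-space transform
## along the actual (eddy-perturbed) trajectory, with T2* envelope, B0-eddy
## phase accrual, and optional complex white noise.

## per-disk signal sampling; supports an optional per-disk off-resonance
## column `freq_hz` (static in-plane B0 inhomogeneity evaluated at the disk
## center), whose phase refocuses at the spin echo
.sampleSignal <- function(phantom, kro, kpe, tMs, te) {
  d <- phantom@disks
  s <- complex(real = rep(0, length(kro)))
  kr <- sqrt(kro^2 + kpe^2)
  hasOffRes <- "freq_hz" %in% names(d)
  for (j in seq_len(nrow(d))) {
    z <- 2 * pi * kr * d$r_mm[j]
    jinc <- ifelse(z < 1e-12, 1, 2 * besselJ(z, 1) / pmax(z, 1e-300))
    sj <- d$amplitude[j] * pi * d$r_mm[j]^2 * jinc *
      exp(-2i * pi * (kro * d$x_mm[j] + kpe * d$y_mm[j]))
    if (hasOffRes && d$freq_hz[j] != 0)
      sj <- sj * exp(2i * pi * d$freq_hz[j] * (tMs - te) / 1000)
    s <- s + sj
  }
  s
}

.simulateAcq <- function(phantom, params, eddy, shotIndex, kzIndex, reference) {
  wf <- buildWaveform(params, shotIndex, kzIndex, reference = reference)
  eff <- effectiveGradient(wf, eddy)
  traj <- nominalTrajectory(eff)               # actual trajectory incl. eddy
  iro <- .axisCol(params@readoutAxis)
  ipe <- .axisCol(params@phaseAxis)
  kro <- traj[[c("kx", "ky", "kz")[iro]]]
  kpe <- traj[[c("kx", "ky", "kz")[ipe]]]
  tMs <- traj$t_us / 1000
  ## B0 eddy phase driven by the applied (nominal) current switching
  b0 <- b0ShiftTimeseries(wf, eddy)
  sig <- .sampleSignal(phantom, kro, kpe, tMs, params@te)
  if (any(b0 != 0)) {
    phase <- gammaProton * cumsum(b0) * wf@dt / 1000     # cycles at raster
    tcIdx <- round(wf@tcUs / wf@dt) + 1L
    sel <- seq_along(phase) > tcIdx
    phase[sel] <- phase[sel] - 2 * phase[tcIdx]
    tGrid <- (0:(nrow(wf@g) - 1L)) * wf@dt
    phS <- stats::approx(tGrid, phase, xout = traj$t_us)$y
    sig <- sig * exp(2i * pi * phS)
  }
  env <- exp(-abs(tMs - params@te) / phantom@t2Star)
  sig <- sig * env
  matrix(sig, nrow = samplesPerEcho(params))   # samples x echoes
}

.simulate <- function(phantom, params, eddy, noiseSd, seed, reference) {
  stopifnot(is(phantom, "DigitalPhantom"), is(params, "SequenceParams"),
            is(eddy, "EddyModelSet"))
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd < 0)
    stop("noiseSd must be a single non-negative number")
  if (!is.null(seed) && !is.na(seed) &&
      (!is.numeric(seed) || seed != round(seed)))
    stop("seed must be a single integer (or NA for noiseless runs)")
  if (noiseSd > 0 && (is.null(seed) || is.na(seed)))
    stop("a seed is required when noiseSd > 0")
  m <- params@matrixSize
  nz <- if (reference) 1L else m[3L]
  nShots <- if (reference) 1L else params@nShots
  ns <- samplesPerEcho(params)
  nAcq <- nShots * nz
  dat <- array(complex(real = 0), dim = c(ns, params@echoesPerShot, nAcq))
  maps <- vector("list", nAcq)
  lay <- .seqLayout(params)
  a <- 0L
  for (kz in seq_len(nz) - 1L) for (sh in seq_len(nShots) - 1L) {
    a <- a + 1L
    dat[, , a] <- .simulateAcq(phantom, params, eddy, sh, kz, reference)
    maps[[a]] <- data.frame(
      acq = a, shot = sh, kzIndex = kz, echo = seq_len(params@echoesPerShot),
      kyIndex = if (reference) NA_integer_ else kyLineIndices(params, sh),
      polarity = lay$echoPolarity)
  }
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    nTot <- length(dat)
    dat <- dat + complex(real = stats::rnorm(nTot, sd = noiseSd),
                         imaginary = stats::rnorm(nTot, sd = noiseSd))
  }
  new("RawEchoTrain", data = dat, lineMap = do.call(rbind, maps),
      params = params, mode = if (reference) "reference" else "imaging",
      corrected = FALSE,
      seed = if (is.null(seed) || is.na(seed)) NA_integer_ else as.integer(seed),
      noiseSd = noiseSd, eddyPreset = eddy@preset, paramsHash = paramsHash(params))
}

#' Simulate an EPI acquisition
#'
#' Builds the per-shot gradient waveforms, perturbs them with the
#' eddy-current model ([effectiveGradient()]), integrates the actual k-space
#' trajectory (spin-echo conjugation at TE/2), samples the phantom's analytic
#' transform at the actual k positions, applies the T2* envelope (anchored at
#' the spin-echo center) and the accumulated B0-eddy phase, and optionally
#' adds complex white noise. Deterministic given `seed` (R's default
#' Mersenne-Twister generator).
#'
#' The phantom plane is spanned by the readout axis (phantom x) and the
#' phase-encode axis (phantom y); the excited slice is an ideal 2D plane, so
#' for 3D sequences the signal carries no kz dependence and the object
#' reconstructs into the central slice.
#'
#' @param phantom a [DigitalPhantom-class].
#' @param params a [SequenceParams-class].
#' @param eddy an [EddyModelSet-class] (default: no eddy currents).
#' @param noiseSd standard deviation of the complex noise per channel (0 for
#'   noiseless).
#' @param seed integer RNG seed (required if `noiseSd > 0`).
#' @return a [RawEchoTrain-class] in imaging mode.
#' @export
simulateEpi <- function(phantom, params, eddy = eddyPreset("none"),
                        noiseSd = 0, seed = NA_integer_) {
  .simulate(phantom, params, eddy, noiseSd, seed, reference = FALSE)
}

#' Simulate a reference scan (phase encoding off)
#'
#' As [simulateEpi()] but with all phase-encode channels switched off, so the
#' trajectory repeatedly passes through the k-space origin and every echo
#' refocuses there. One acquisition is produced regardless of the shot count
#' (all shots of a multishot sequence are identical without phase encoding).
#'
#' @inheritParams simulateEpi
#' @return a [RawEchoTrain-class] in reference mode.
#' @export
simulateReference <- function(phantom, params, eddy = eddyPreset("none"),
                              noiseSd = 0, seed = NA_integer_) {
  .simulate(phantom, params, eddy, noiseSd, seed, reference = TRUE)
}
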