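#' @import methods
NULL

#' Proton gyromagnetic ratio, kHz/mT (= MHz/T)
#'
#' Fixed constant used throughout for k-space and phase computations.
#' @export
gammaProton <- 42.577

## ---- EddyModelSet -----------------------------------------------------------

#' Multi-exponential eddy-current model for a three-axis gradient set
#'
#' An `EddyModelSet` holds, per gradient axis (x, y, z), the amplitudes and
#' time constants of the eddy-current gradient field (same spatial symmetry as
#' the driving coil) and, optionally, of the spatially homogeneous B0 shift.
#'
#' The step response of one axis is \eqn{e(t) = \sum_k c_k \exp(-t/\tau_k)},
#' with amplitudes expressed as dimensionless fractions of the applied gradient
#' step. The eddy field for an arbitrary waveform \eqn{G(t)} is the causal
#' convolution \eqn{g(t) = -dG/dt * e(t)}: a positive gradient step induces an
#' opposing (negative) eddy field immediately after the step.
#'
#' B0 components use a coupling in microtesla of B0 shift per mT/m of
#' instantaneous gradient step, with their own time constants.
#'
#' @slot gradient named list (`x`, `y`, `z`) of data frames with columns
#'   `amplitude` (fraction of applied step) and `tau_ms` (> 0).
#' @slot b0 named list (`x`, `y`, `z`) of data frames with columns
#'   `coupling_ut` (uT per mT/m step) and `tau_ms` (> 0).
#' @slot preset preset label ("table1_standard_coil", "table2_large_coil",
#'   "none", or "custom").
#' @seealso [eddyPreset()], [stepResponse()], [convolveResponse()]
#' @export
setClass("EddyModelSet",
  representation(gradient = "list", b0 = "list", preset = "character"),
  prototype(
    gradient = list(x = data.frame(amplitude = numeric(0), tau_ms = numeric(0)),
                    y = data.frame(amplitude = numeric(0), tau_ms = numeric(0)),
                    z = data.frame(amplitude = numeric(0), tau_ms = numeric(0))),
    b0 = list(x = data.frame(coupling_ut = numeric(0), tau_ms = numeric(0)),
              y = data.frame(coupling_ut = numeric(0), tau_ms = numeric(0)),
              z = data.frame(coupling_ut = numeric(0), tau_ms = numeric(0))),
    preset = "none"
  )
)

setValidity("EddyModelSet", function(object) {
  msgs <- character(0)
  for (nm in c("x", "y", "z")) {
    g <- object@gradient[[nm]]
    if (is.null(g) || !all(c("amplitude", "tau_ms") %in% names(g)))
      msgs <- c(msgs, sprintf("gradient[['%s']] must have columns amplitude, tau_ms", nm))
    else {
      if (any(!is.finite(g$amplitude))) msgs <- c(msgs, sprintf("%s: non-finite amplitude", nm))
      if (any(g$tau_ms <= 0)) msgs <- c(msgs, sprintf("%s: time constants must be > 0", nm))
    }
    b <- object@b0[[nm]]
    if (is.null(b) || !all(c("coupling_ut", "tau_ms") %in% names(b)))
      msgs <- c(msgs, sprintf("b0[['%s']] must have columns coupling_ut, tau_ms", nm))
    else if (any(b$tau_ms <= 0)) msgs <- c(msgs, sprintf("%s: B0 time constants must be > 0", nm))
  }
  if (length(msgs)) msgs else TRUE
})

## ---- SequenceParams ---------------------------------------------------------

#' EPI sequence parameters
#'
#' Describes a spin-echo EPI acquisition: matrix size, field of view, readout
#' lobe timing, sampling, shot structure, and axis assignment. Construct with
#' [sequenceParams()] or [sequenceVariant()].
#'
#' @slot matrixSize integer (nx, ny, nz); nz = 1 for 2D.
#' @slot fov numeric (mm) per axis.
#' @slot echoSpacing time between gradient echoes, ms.
#' @slot riseTime gradient rise time 0 to 100%, ms.
#' @slot readoutAmplitude readout lobe amplitude, mT/m.
#' @slot dwell Nyquist dwell time, us (the oversampled sampling interval is
#'   `dwell / oversampling`).
#' @slot oversampling integer readout oversampling factor.
#' @slot nDummy number of initial readout lobes without data acquisition.
#' @slot te,tr spin-echo time and repetition time, ms.
#' @slot nShots,echoesPerShot shot structure; `nShots * echoesPerShot` must
#'   equal ny.
#' @slot readoutAxis,phaseAxis,sliceAxis axis letters ("x", "y", "z").
#' @slot blipMode "blip" (phase-encode blips between echoes, the default) or
#'   "constant" (continuous low-amplitude phase-encode gradient).
#' @export
setClass("SequenceParams",
  representation(
    matrixSize = "integer", fov = "numeric",
    echoSpacing = "numeric", riseTime = "numeric",
    readoutAmplitude = "numeric", dwell = "numeric",
    oversampling = "integer", nDummy = "integer",
    te = "numeric", tr = "numeric",
    nShots = "integer", echoesPerShot = "integer",
    readoutAxis = "character", phaseAxis = "character", sliceAxis = "character",
    blipMode = "character"
  )
)

setValidity("SequenceParams", function(object) {
  m <- object@matrixSize
  msgs <- character(0)
  if (length(m) != 3L || any(m < 1L)) msgs <- c(msgs, "matrixSize must be 3 positive integers")
  if (length(object@fov) != 3L || any(object@fov <= 0)) msgs <- c(msgs, "fov must be 3 positive lengths (mm)")
  if (object@echoSpacing <= 0) msgs <- c(msgs, "echoSpacing must be > 0")
  if (object@riseTime <= 0) msgs <- c(msgs, "riseTime must be > 0")
  if (object@dwell <= 0) msgs <- c(msgs, "dwell must be > 0")
  if (object@oversampling < 1L) msgs <- c(msgs, "oversampling must be >= 1")
  if (length(m) == 3L && object@nShots * object@echoesPerShot != m[2L])
    msgs <- c(msgs, sprintf("nShots * echoesPerShot (%d) must equal ny (%d)",
                            object@nShots * object@echoesPerShot, m[2L]))
  ## sampling window (nx * dwell) must fit inside one lobe period leaving the
  ## central rise-time of each polarity transition free; sampling may ride the
  ## ramp ends (ramp sampling)
  if (length(m) == 3L && m[1L] * object@dwell / 1000 > object@echoSpacing - object@riseTime)
    msgs <- c(msgs, sprintf(
      "echo spacing %.3g ms too short for %d samples at %.3g us dwell with %.3g ms rise time",
      object@echoSpacing, m[1L], object@dwell, object@riseTime))
  axes <- c(object@readoutAxis, object@phaseAxis, object@sliceAxis)
  if (!setequal(axes, c("x", "y", "z"))) msgs <- c(msgs, "axes must be a permutation of x, y, z")
  if (!object@blipMode %in% c("blip", "constant")) msgs <- c(msgs, "blipMode must be 'blip' or 'constant'")
  if (object@te <= 0 || object@tr <= 0) msgs <- c(msgs, "te and tr must be > 0")
  if (length(msgs)) msgs else TRUE
})

## ---- GradientWaveform -------------------------------------------------------

#' Three-axis gradient waveform on a 1 us raster
#'
#' Amplitude time series for the x, y and z gradient channels, together with
#' the acquisition-window table (one row per acquired echo) and the spin-echo
#' conjugation time. Time starts at excitation (t = 0).
#'
#' @slot dt raster interval, us.
#' @slot g numeric matrix N x 3 (columns x, y, z), mT/m.
#' @slot acq data.frame with one row per acquired echo: `echo`, `center_us`,
#'   `nSamples`, `sampleDt_us`, `polarity` (+1/-1 sign of the readout lobe).
#' @slot tcUs time of the 180-degree refocusing pulse (k/phase conjugation), us;
#'   `NA` for waveforms without a spin echo.
#' @slot meta list of provenance fields (shot index, kz index, params hash, ...).
#' @export
setClass("GradientWaveform",
  representation(dt = "numeric", g = "matrix", acq = "data.frame",
                 tcUs = "numeric", meta = "list"),
  prototype(dt = 1, tcUs = NA_real_, meta = list())
)

setValidity("GradientWaveform", function(object) {
  msgs <- character(0)
  if (object@dt <= 0) msgs <- c(msgs, "dt must be > 0")
  if (ncol(object@g) != 3L) msgs <- c(msgs, "g must have 3 columns (x, y, z)")
  if (nrow(object@g) > 0 &&
      (any(object@g[1, ] != 0) || any(object@g[nrow(object@g), ] != 0)))
    msgs <- c(msgs, "waveform must begin and end at zero")
  if (length(msgs)) msgs else TRUE
})

## ---- DigitalPhantom ---------------------------------------------------------

#' Analytic digital phantom: superposition of uniform disks
#'
#' Each disk contributes `amplitude` signal per unit area inside radius `r_mm`
#' around (`x_mm`, `y_mm`); negative amplitudes allow annuli by superposition.
#' The phantom has an exact closed-form 2D Fourier transform, so raw EPI
#' signals can be sampled at arbitrary (off-grid) k-space positions.
#'
#' @slot disks data.frame with columns `x_mm`, `y_mm`, `r_mm`, `amplitude`.
#' @slot t2Star effective transverse decay constant, ms (may be `Inf` for an
#'   ideal non-relaxing phantom).
#' @slot name label.
#' @seealso [capillaryPhantom()], [analyticKspace()]
#' @export
setClass("DigitalPhantom",
  representation(disks = "data.frame", t2Star = "numeric", name = "character"),
  prototype(t2Star = 40, name = "phantom")
)

setValidity("DigitalPhantom", function(object) {
  msgs <- character(0)
  need <- c("x_mm", "y_mm", "r_mm", "amplitude")
  if (!all(need %in% names(object@disks)))
    msgs <- c(msgs, "disks must have columns x_mm, y_mm, r_mm, amplitude")
  else if (any(object@disks$r_mm <= 0)) msgs <- c(msgs, "disk radii must be > 0")
  if (object@t2Star <= 0) msgs <- c(msgs, "t2Star must be > 0")
  if (length(msgs)) msgs else TRUE
})

## ---- RawEchoTrain -----------------------------------------------------------

#' Raw EPI echo train
#'
#' Complex k-space samples indexed by (readout sample, echo, acquisition),
#' where one "acquisition" is a shot (times a kz encode for 3D). The line map
#' records which ky (and kz) line each echo of each acquisition covers.
#'
#' @slot data complex array, dim (samples per echo, echoes per shot, n
#'   acquisitions).
#' @slot lineMap data.frame with columns `acq`, `shot`, `kzIndex`, `echo`,
#'   `kyIndex` (0-based, bottom-up; NA in reference mode), `polarity`.
#' @slot params the [SequenceParams-class] used.
#' @slot mode "imaging" or "reference".
#' @slot corrected logical: has the reference-scan correction been applied
#'   (data then holds nx decimated samples per echo, all echoes in ascending
#'   readout order).
#' @slot seed integer RNG seed used for the noise draw (NA if noiseless).
#' @slot noiseSd complex-noise standard deviation per channel.
#' @slot eddyPreset label of the eddy model used.
#' @slot paramsHash hash of the sequence geometry; corrections require matching
#'   hashes between raw data and reference profile.
#' @slot meta list of provenance entries (correction stages, resampling kernel,
#'   ...).
#' @export
setClass("RawEchoTrain",
  representation(data = "array", lineMap = "data.frame", params = "SequenceParams",
                 mode = "character", corrected = "logical", seed = "integer",
                 noiseSd = "numeric", eddyPreset = "character", paramsHash = "character",
                 meta = "list"),
  prototype(mode = "imaging", corrected = FALSE, seed = NA_integer_, noiseSd = 0,
            meta = list())
)

setValidity("RawEchoTrain", function(object) {
  msgs <- character(0)
  if (!object@mode %in% c("imaging", "reference")) msgs <- c(msgs, "mode must be imaging or reference")
  if (length(dim(object@data)) != 3L) msgs <- c(msgs, "data must be a 3D array")
  p <- object@params
  expSamp <- if (object@corrected) p@matrixSize[1L] else p@matrixSize[1L] * p@oversampling
  if (length(dim(object@data)) == 3L && dim(object@data)[1L] != expSamp)
    msgs <- c(msgs, sprintf("expected %d samples per echo, found %d", expSamp, dim(object@data)[1L]))
  if (object@mode == "reference" && nrow(object@lineMap) &&
      !all(is.na(object@lineMap$kyIndex)))
    msgs <- c(msgs, "reference mode requires all-NA phase-encode line indices")
  if (length(msgs)) msgs else TRUE
})

## ---- ReferenceScanProfile ---------------------------------------------------

#' Reference-scan echo profile
#'
#' Per acquired echo, the relative peak position (fractional 0-based sample
#' index within the oversampled echo window, after even-echo time reversal)
#' and the peak phase in degrees, measured from a phase-encode-off reference
#' acquisition. These drive the resampling and zeroth-order phase correction.
#'
#' @slot table data.frame with columns `echo`, `position`, `phase_deg`,
#'   `polarity`.
#' @slot paramsHash geometry hash of the generating sequence.
#' @slot meta list (seed, eddy preset, samples per echo, ...).
#' @export
setClass("ReferenceScanProfile",
  representation(table = "data.frame", paramsHash = "character", meta = "list"),
  prototype(meta = list())
)

setValidity("ReferenceScanProfile", function(object) {
  tb <- object@table
  msgs <- character(0)
  if (!all(c("echo", "position", "phase_deg") %in% names(tb)))
    msgs <- c(msgs, "table must have columns echo, position, phase_deg")
  else {
    ns <- object@meta$samplesPerEcho
    if (!is.null(ns) && any(tb$position < 0 | tb$position >= ns))
      msgs <- c(msgs, "positions must lie in [0, samplesPerEcho)")
    if (any(tb$phase_deg <= -180 | tb$phase_deg > 180))
      msgs <- c(msgs, "phases must lie in (-180, 180]")
  }
  if (length(msgs)) msgs else TRUE
})

## ---- ReconImage -------------------------------------------------------------

#' Reconstructed magnitude image
#'
#' @slot data non-negative numeric array (nx x ny [x nz]).
#' @slot fov field of view per axis, mm.
#' @slot provenance character vector of processing stages applied.
#' @export
setClass("ReconImage",
  representation(data = "array", fov = "numeric", provenance = "character"),
  prototype(provenance = character(0))
)

setValidity("ReconImage", function(object) {
  if (any(object@data < 0)) "magnitude image must be non-negative" else TRUE
})

## ---- GhostMetricReport ------------------------------------------------------

#' N/2 ghost metric report
#'
#' Ratio of mean magnitude in a square signal region at the object center to
#' the mean in the same square displaced by ny/2 (wrapped) along the
#' phase-encoding direction.
#'
#' @slot signalMean,ghostMean,ratio the two ROI means and their ratio.
#' @slot roi list: `signalCenter`, `ghostCenter` (pixel indices), `sizePx`.
#' @slot capped TRUE if the ghost mean fell below the epsilon guard and the
#'   ratio was capped.
#' @slot overlap TRUE if the ghost ROI overlaps the object support (the ratio
#'   is then contaminated by true signal).
#' @export
setClass("GhostMetricReport",
  representation(signalMean = "numeric", ghostMean = "numeric", ratio = "numeric",
                 roi = "list", capped = "logical", overlap = "logical"),
  prototype(capped = FALSE, overlap = FALSE)
)

## ---- PeakShiftSeries --------------------------------------------------------

#' Delay-swept eddy-current measurement series
#'
#' Residual eddy-current gradient amplitude (as a fraction of the applied
#' prepulse gradient) versus the delay between the prepulse falling edge and
#' the measurement, as produced by the gradient-echo peak-shift experiment.
#'
#' @slot table data.frame with columns `delay_ms` (strictly increasing,
#'   first >= 0.1) and `amplitude` (fraction of applied gradient).
#' @slot axis gradient axis measured.
#' @slot prepulseAmplitude,prepulseDuration prepulse strength (mT/m) and
#'   duration (ms).
#' @slot mode "fast" (direct residual-field sampling) or "physics" (full echo
#'   simulation with peak detection).
#' @export
setClass("PeakShiftSeries",
  representation(table = "data.frame", axis = "character",
                 prepulseAmplitude = "numeric", prepulseDuration = "numeric",
                 mode = "character"),
  prototype(mode = "fast")
)

setValidity("PeakShiftSeries", function(object) {
  tb <- object@table
  msgs <- character(0)
  if (!all(c("delay_ms", "amplitude") %in% names(tb)))
    msgs <- c(msgs, "table must have columns delay_ms, amplitude")
  else {
    if (nrow(tb) == 0) msgs <- c(msgs, "series must be non-empty")
    if (nrow(tb) && (is.unsorted(tb$delay_ms, strictly = TRUE)))
      msgs <- c(msgs, "delays must be strictly increasing")
    if (nrow(tb) && tb$delay_ms[1] < 0.1) msgs <- c(msgs, "first delay must be >= 0.1 ms")
  }
  if (length(msgs)) msgs else TRUE
})
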