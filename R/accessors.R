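## Accessors and show methods for the package classes.

#' @rdname EddyModelSet-class
#' @param object an `EddyModelSet`
#' @param axis "x", "y" or "z"
#' @param type "gradient" for the eddy gradient-field components, "b0" for the
#'   B0-shift components
#' @return `eddyComponents()`: a data.frame of components for one axis.
#' @export
eddyComponents <- function(object, axis = c("x", "y", "z"),
                           type = c("gradient", "b0")) {
  stopifnot(is(object, "EddyModelSet"))
  axis <- match.arg(axis)
  type <- match.arg(type)
  if (type == "gradient") object@gradient[[axis]] else object@b0[[axis]]
}

#' @rdname EddyModelSet-class
#' @export
presetLabel <- function(object) {
  stopifnot(is(object, "EddyModelSet"))
  object@preset
}

#' @describeIn SequenceParams-class total data-acquisition window,
#'   `echoesPerShot * echoSpacing`, in ms.
#' @param params a `SequenceParams`
#' @export
acqWindow <- function(params) {
  stopifnot(is(params, "SequenceParams"))
  params@echoesPerShot * params@echoSpacing
}

#' @describeIn SequenceParams-class number of (oversampled) samples per echo.
#' @export
samplesPerEcho <- function(params) {
  stopifnot(is(params, "SequenceParams"))
  as.integer(params@matrixSize[1L] * params@oversampling)
}

#' @describeIn SequenceParams-class sampling interval `dwell / oversampling`, us.
#' @export
sampleDt <- function(params) {
  stopifnot(is(params, "SequenceParams"))
  params@dwell / params@oversampling
}

#' @describeIn SequenceParams-class hash of the acquisition geometry (matrix,
#'   fov, timing, shot structure, axes). Reference profiles may only correct
#'   raw data with an identical hash.
#' @export
paramsHash <- function(params) {
  stopifnot(is(params, "SequenceParams"))
  rlang::hash(list(
    params@matrixSize, params@fov, params@echoSpacing, params@riseTime,
    params@readoutAmplitude, params@dwell, params@oversampling, params@nDummy,
    params@te, params@nShots, params@echoesPerShot,
    params@readoutAxis, params@phaseAxis, params@sliceAxis, params@blipMode))
}

#' @rdname RawEchoTrain-class
#' @param x a `RawEchoTrain`
#' @export
trainData <- function(x) { stopifnot(is(x, "RawEchoTrain")); x@data }

#' @rdname RawEchoTrain-class
#' @export
lineMap <- function(x) { stopifnot(is(x, "RawEchoTrain")); x@lineMap }

#' @rdname RawEchoTrain-class
#' @export
seqParams <- function(x) {
  stopifnot(is(x, "RawEchoTrain") || is(x, "GradientWaveform"))
  if (is(x, "RawEchoTrain")) x@params else x@meta$params
}

#' @rdname ReferenceScanProfile-class
#' @param x a `ReferenceScanProfile`
#' @export
profileTable <- function(x) { stopifnot(is(x, "ReferenceScanProfile")); x@table }

#' @rdname ReconImage-class
#' @param x a `ReconImage`
#' @export
imageData <- function(x) { stopifnot(is(x, "ReconImage")); x@data }

#' @rdname ReconImage-class
#' @export
imageFov <- function(x) { stopifnot(is(x, "ReconImage")); x@fov }

#' @rdname ReconImage-class
#' @export
provenance <- function(x) { stopifnot(is(x, "ReconImage")); x@provenance }

#' @rdname PeakShiftSeries-class
#' @param x a `PeakShiftSeries`
#' @export
seriesTable <- function(x) { stopifnot(is(x, "PeakShiftSeries")); x@table }

## ---- show methods -----------------------------------------------------------

setMethod("show", "EddyModelSet", function(object) {
  cat("EddyModelSet, preset:", object@preset, "\n")
  for (nm in c("x", "y", "z")) {
    g <- object@gradient[[nm]]
    b <- object@b0[[nm]]
    cat(sprintf("  G%s: %d gradient component(s)%s", nm, nrow(g),
                if (nrow(g)) paste0(" [",
                  paste(sprintf("%.2f%%/%.3g ms", 100 * g$amplitude, g$tau_ms),
                        collapse = ", "), "]") else ""))
    if (nrow(b))
      cat(sprintf("; %d B0 component(s) [%s]", nrow(b),
                  paste(sprintf("%.3g uT per mT/m, tau %.3g ms",
                                b$coupling_ut, b$tau_ms), collapse = ", ")))
    cat("\n")
  }
})

setMethod("show", "SequenceParams", function(object) {
  m <- object@matrixSize
  cat(sprintf("SequenceParams: %d x %d%s EPI, FOV %.4g mm\n", m[1], m[2],
              if (m[3] > 1) sprintf(" x %d", m[3]) else "", object@fov[1]))
  cat(sprintf("  %d shot(s) x %d echoes, echo spacing %.3g ms (window %.4g ms)\n",
              object@nShots, object@echoesPerShot, object@echoSpacing, acqWindow(object)))
  cat(sprintf("  readout %s %.4g mT/m, rise %.3g ms, dwell %.3g us x%d oversampling\n",
              object@readoutAxis, object@readoutAmplitude, object@riseTime,
              object@dwell, object@oversampling))
  cat(sprintf("  TE %.4g ms, TR %.4g ms, %d dummy lobes, blip mode '%s'\n",
              object@te, object@tr, object@nDummy, object@blipMode))
})

setMethod("show", "GradientWaveform", function(object) {
  n <- nrow(object@g)
  cat(sprintf("GradientWaveform: %d points at %.3g us (%.4g ms), %d acquisition window(s)\n",
              n, object@dt, n * object@dt / 1000, nrow(object@acq)))
  rng <- apply(object@g, 2, function(v) max(abs(v)))
  cat(sprintf("  max |G| (mT/m): x %.4g, y %.4g, z %.4g; conjugation at %.4g ms\n",
              rng[1], rng[2], rng[3], object@tcUs / 1000))
})

setMethod("show", "DigitalPhantom", function(object) {
  cat(sprintf("DigitalPhantom '%s': %d disk(s), T2* = %.4g ms, total signal %.5g\n",
              object@name, nrow(object@disks), object@t2Star, totalSignal(object)))
})

setMethod("show", "RawEchoTrain", function(object) {
  d <- dim(object@data)
  cat(sprintf("RawEchoTrain (%s%s): %d samples x %d echoes x %d acquisition(s)\n",
              object@mode, if (object@corrected) ", corrected" else "",
              d[1], d[2], d[3]))
  cat(sprintf("  eddy preset '%s', noise sd %.3g, seed %s\n", object@eddyPreset,
              object@noiseSd, ifelse(is.na(object@seed), "none", object@seed)))
})

setMethod("show", "ReferenceScanProfile", function(object) {
  tb <- object@table
  cat(sprintf("ReferenceScanProfile: %d echoes\n", nrow(tb)))
  if (nrow(tb) > 1) {
    dphi <- wrapDeg(diff(tb$phase_deg))
    cat(sprintf("  peak position range %.3f..%.3f, median |successive phase diff| %.1f deg\n",
                min(tb$position), max(tb$position), stats::median(abs(dphi))))
  }
})

setMethod("show", "ReconImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("ReconImage: %s, FOV %s mm\n", paste(d, collapse = " x "),
              paste(signif(object@fov[seq_along(d)], 4), collapse = " x ")))
  cat("  stages:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "GhostMetricReport", function(object) {
  cat(sprintf("GhostMetricReport: signal/ghost ratio = %.4g (signal %.4g, ghost %.4g)\n",
              object@ratio, object@signalMean, object@ghostMean))
  if (object@capped) cat("  [ghost mean below epsilon guard; ratio capped]\n")
  if (object@overlap) cat("  [warning: ghost ROI overlaps object support]\n")
})

setMethod("show", "PeakShiftSeries", function(object) {
  cat(sprintf("PeakShiftSeries (%s axis, %s mode): %d delays %.3g..%.3g ms, prepulse %.4g mT/m x %.3g ms\n",
              object@axis, object@mode, nrow(object@table),
              min(object@table$delay_ms), max(object@table$delay_ms),
              object@prepulseAmplitude, object@prepulseDuration))
})
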