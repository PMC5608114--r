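## Multi-exponential eddy-current model: step response, convolution with
## arbitrary gradient waveforms, B0-shift coupling, and the coil presets.

## measured eddy parameters for the two unshielded coil sets; amplitudes are
## fractions of the applied gradient step, time constants in ms
.presetStandardCoil <- list(
  x = data.frame(amplitude = c(9.82, 7.88) / 100, tau_ms = c(0.287, 2.12)),
  y = data.frame(amplitude = c(7.62, 6.27) / 100, tau_ms = c(0.330, 2.33)),
  z = data.frame(amplitude = c(5.57, 4.89) / 100, tau_ms = c(0.283, 1.99))
)

.presetLargeCoil <- list(
  x = data.frame(amplitude = c(20.1, 14.6) / 100, tau_ms = c(2.12, 12.7)),
  y = data.frame(amplitude = numeric(0), tau_ms = numeric(0)),
  z = data.frame(amplitude = c(20.4, 19.7) / 100, tau_ms = c(1.48, 9.70))
)

.emptyComp <- function() data.frame(amplitude = numeric(0), tau_ms = numeric(0))
.emptyB0 <- function() data.frame(coupling_ut = numeric(0), tau_ms = numeric(0))

.presetCache <- new.env(parent = emptyenv())

#' Construct an eddy-current model set
#'
#' @param gradient named list (`x`, `y`, `z`) of data frames with columns
#'   `amplitude` (fraction of the applied gradient step) and `tau_ms`.
#'   Missing axes get no components.
#' @param b0 named list (`x`, `y`, `z`) of data frames with columns
#'   `coupling_ut` (uT of B0 shift per mT/m of instantaneous gradient step)
#'   and `tau_ms`. Missing axes get no components.
#' @param preset label to record.
#' @return an [EddyModelSet-class].
#' @export
eddyModelSet <- function(gradient = list(), b0 = list(), preset = "custom") {
  fill <- function(lst, empty) {
    out <- list(x = empty(), y = empty(), z = empty())
    for (nm in intersect(names(lst), c("x", "y", "z"))) out[[nm]] <- lst[[nm]]
    out
  }
  new("EddyModelSet", gradient = fill(gradient, .emptyComp),
      b0 = fill(b0, .emptyB0), preset = preset)
}

#' Eddy-current presets for the two unshielded gradient coil sets
#'
#' `"table1_standard_coil"` holds the measured two-component eddy gradient
#' fields of the 39/32 mm (outer/inner diameter) coil set: time constants fall
#' into a fast (~0.3 ms) and a slow (~2 ms) group with amplitudes 5-10% of the
#' applied gradient. `"table2_large_coil"` holds the 45/41 mm coil set (x and z
#' axes; amplitudes about twice as large, slow constants ~10 ms). `"none"` is
#' an ideal eddy-free system.
#'
#' When `b0 = TRUE` (default, standard coil only) a single B0-shift component
#' per axis with time constant `b0Tau` is added. Its coupling is calibrated
#' numerically so that, in the steady part of a one-shot 64 x 64 reference
#' scan, the per-echo phase alternation equals `b0TargetsDeg` for the
#' respective readout axis (defaults 60 degrees for x, 140 for y; z is not
#' separately characterized and reuses the x target). The B0 time constant was
#' not measured on the hardware; 0.1 ms is the documented assumption.
#'
#' @param name preset name.
#' @param b0 include the calibrated B0-shift components (standard coil only).
#' @param b0Tau B0 eddy time constant, ms.
#' @param b0TargetsDeg named numeric: target steady per-echo phase alternation
#'   (degrees) per readout axis.
#' @return an [EddyModelSet-class].
#' @examples
#' eddyPreset("table1_standard_coil")
#' stepResponse(eddyComponents(eddyPreset("table1_standard_coil"), "x"), 0)
#' @export
eddyPreset <- function(name = c("table1_standard_coil", "table2_large_coil", "none"),
                       b0 = TRUE, b0Tau = 0.1,
                       b0TargetsDeg = c(x = 60, y = 140, z = 60)) {
  name <- match.arg(name)
  if (name == "none")
    return(eddyModelSet(preset = "none"))
  grad <- if (name == "table1_standard_coil") .presetStandardCoil else .presetLargeCoil
  useB0 <- b0 && name == "table1_standard_coil"
  b0List <- list()
  if (useB0) {
    key <- paste0(name, "|", b0Tau, "|", paste(b0TargetsDeg, collapse = ","))
    if (is.null(.presetCache[[key]])) {
      b0New <- list()
      for (ax in c("x", "y", "z")) {
        cpl <- calibrateB0Coupling(b0TargetsDeg[[ax]], axis = ax, tau = b0Tau)
        b0New[[ax]] <- data.frame(coupling_ut = cpl, tau_ms = b0Tau)
      }
      .presetCache[[key]] <- b0New
    }
    b0List <- .presetCache[[key]]
  }
  eddyModelSet(gradient = grad, b0 = b0List, preset = name)
}

#' Eddy-current step response
#'
#' Response of the eddy gradient field to a unit gradient step applied at
#' t = 0: \eqn{e(t) = \sum_k c_k \exp(-t/\tau_k)}, as a dimensionless fraction
#' of the step amplitude.
#'
#' @param components data.frame with columns `amplitude`, `tau_ms` (e.g. from
#'   [eddyComponents()]).
#' @param t time since the step, ms (vectorized, must be >= 0).
#' @return numeric vector, same length as `t`.
#' @examples
#' ## the fast ~0.3 ms component decays to about 4% within one 1 ms interval
#' stepResponse(data.frame(amplitude = 1, tau_ms = 0.3), 1.0)
#' @export
stepResponse <- function(components, t) {
  if (any(t < 0)) stop("step response is causal: t must be >= 0")
  if (NROW(components) == 0) return(rep(0, length(t)))
  stopifnot(all(c("amplitude", "tau_ms") %in% names(components)),
            all(components$tau_ms > 0), all(is.finite(components$amplitude)))
  colSums(components$amplitude * exp(-outer(1 / components$tau_ms, t)))
}

#' Convolve a gradient waveform with the eddy-current response
#'
#' Computes the eddy gradient field \eqn{g(t) = -dG/dt * e(t)} by causal
#' discrete convolution on the waveform raster. A positive gradient step
#' produces an opposing (negative) eddy field immediately after the step.
#'
#' @param g numeric gradient series (mT/m) on a uniform raster, or a
#'   [GradientWaveform-class] (then `axis` selects the channel).
#' @param components eddy components (data.frame `amplitude`, `tau_ms`).
#' @param dt raster interval, us (ignored for a `GradientWaveform`).
#' @param axis channel to use when `g` is a `GradientWaveform`.
#' @return numeric eddy-field series (mT/m), same length as the input.
#' @export
convolveResponse <- function(g, components, dt = 1, axis = c("x", "y", "z")) {
  if (is(g, "GradientWaveform")) {
    axis <- match.arg(axis)
    dt <- g@dt
    g <- g@g[, match(axis, c("x", "y", "z"))]
  }
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("waveform must be on a uniform raster with a positive scalar dt")
  if (NROW(components) == 0 || all(g == 0)) return(rep(0, length(g)))
  dG <- diff(c(0, g))
  dtMs <- dt / 1000
  ## kernel long enough for the slowest component to decay below 1e-9 of its
  ## amplitude, capped at the series length
  m <- min(length(g), ceiling(max(components$tau_ms) * log(1e9) / dtMs) + 1L)
  kern <- stepResponse(components, (seq_len(m) - 1) * dtMs)
  out <- -causalConvolve(dG, kern)
  ## exact causality: the FFT convolution leaves ~1e-13 noise ahead of the
  ## first switching event
  first <- which(dG != 0)[1]
  if (!is.na(first) && first > 1L) out[seq_len(first - 1L)] <- 0
  out
}

#' Actual gradient waveform including eddy-current fields
#'
#' Adds the per-axis eddy gradient field (from [convolveResponse()]) to the
#' nominal waveform. With the `"none"` preset the input is returned unchanged.
#'
#' @param nominal a [GradientWaveform-class].
#' @param model an [EddyModelSet-class].
#' @return a [GradientWaveform-class] with the perturbed amplitude series.
#' @export
effectiveGradient <- function(nominal, model) {
  stopifnot(is(nominal, "GradientWaveform"), is(model, "EddyModelSet"))
  if (all(vapply(model@gradient, nrow, 1L) == 0L)) return(nominal)
  g <- nominal@g
  for (i in 1:3) {
    ax <- c("x", "y", "z")[i]
    comp <- model@gradient[[ax]]
    if (nrow(comp)) g[, i] <- g[, i] + convolveResponse(nominal@g[, i], comp, dt = nominal@dt)
  }
  out <- nominal
  out@g <- g
  out@meta$eddyPreset <- model@preset
  out
}

#' B0-shift time series induced by gradient switching
#'
#' Convolves each axis's gradient derivative with that axis's B0-shift
#' exponential response (coupling in uT per mT/m of step) and sums the axes.
#' Returns zero when the model has no B0 components.
#'
#' @param waveform a [GradientWaveform-class].
#' @param model an [EddyModelSet-class].
#' @return numeric B0 series (mT) on the waveform raster.
#' @export
b0ShiftTimeseries <- function(waveform, model) {
  stopifnot(is(waveform, "GradientWaveform"), is(model, "EddyModelSet"))
  n <- nrow(waveform@g)
  b0 <- rep(0, n)
  for (i in 1:3) {
    ax <- c("x", "y", "z")[i]
    comp <- model@b0[[ax]]
    if (nrow(comp) == 0) next
    asGrad <- data.frame(amplitude = comp$coupling_ut / 1000, tau_ms = comp$tau_ms)
    b0 <- b0 + convolveResponse(waveform@g[, i], asGrad, dt = waveform@dt)
  }
  b0
}

#' Convert a proton phase accrual to an equivalent B0 shift
#'
#' A B0 shift applied constantly for `duration` ms accrues
#' `360 * gamma * B0 * duration` degrees of proton phase; this inverts that
#' relation. The steady ~60 and ~140 degree per-echo phase alternations of the
#' one-shot reference scans correspond to ~0.04 and ~0.09 mT over 0.1 ms.
#'
#' @param phase phase in degrees (vectorized).
#' @param duration assumed constant-application time, ms.
#' @return B0 shift in mT.
#' @examples
#' b0FromPhase(60, 0.1)   # ~0.04 mT
#' b0FromPhase(140, 0.1)  # ~0.09 mT
#' @export
b0FromPhase <- function(phase, duration) {
  stopifnotScalar(duration, "duration")
  if (duration <= 0) stop("duration must be > 0")
  (phase / 360) / (gammaProton * duration)
}

#' Calibrate the B0-eddy coupling against a target phase alternation
#'
#' Builds the steady one-shot reference readout train with the given axis as
#' readout, computes the B0 series for a unit coupling (1 uT per mT/m),
#' integrates the proton phase at the acquired echo centers, measures the
#' steady unwrapped per-echo phase step over the last half of the train, and
#' scales the coupling linearly to hit `targetDeg`.
#'
#' @param targetDeg target steady per-echo phase alternation, degrees.
#' @param axis readout axis being calibrated.
#' @param tau B0 eddy time constant, ms.
#' @param params sequence used for calibration; default the one-shot 64 x 64
#'   variant re-axed so that `axis` is the readout.
#' @return coupling in uT per mT/m.
#' @export
calibrateB0Coupling <- function(targetDeg, axis = c("x", "y", "z"), tau = 0.1,
                                params = NULL) {
  axis <- match.arg(axis)
  if (is.null(params)) {
    others <- setdiff(c("x", "y", "z"), axis)
    params <- sequenceVariant("oneshot64", readoutAxis = axis,
                              phaseAxis = others[1], sliceAxis = others[2])
  }
  wf <- buildReadoutTrain(params)
  model <- eddyModelSet(
    b0 = stats::setNames(list(data.frame(coupling_ut = 1, tau_ms = tau)), axis),
    preset = "calibration")
  b0 <- b0ShiftTimeseries(wf, model)
  ## unwrapped proton phase (degrees) at raster points, conjugated at TE/2
  phase <- 360 * gammaProton * cumsum(b0) * wf@dt / 1000
  tcIdx <- round(wf@tcUs / wf@dt) + 1L
  phase[seq_along(phase) > tcIdx] <- phase[seq_along(phase) > tcIdx] - 2 * phase[tcIdx]
  centers <- round(wf@acq$center_us / wf@dt) + 1L
  phAtEcho <- phase[centers]
  steps <- abs(diff(phAtEcho))
  late <- steps[seq(ceiling(length(steps) / 2), length(steps))]
  perUnit <- stats::median(late)
  if (perUnit <= 0) stop("calibration failed: no phase alternation produced")
  targetDeg / perUnit
}
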