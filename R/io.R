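## Configuration, container I/O and exports: YAML run configs, the raw-train
## container, CSV tables, and NIfTI/TIFF image writers.

.runConfigKeys <- c("variant", "params", "eddy", "phantom", "noiseSd", "seed",
                    "outputDir", "stages")

#' Read / write a run configuration
#'
#' A run configuration is a YAML document with keys `variant` (sequence
#' variant name), `params` (named [sequenceParams()] overrides), `eddy`
#' (preset name, or inline per-axis component tables), `phantom` ("capillary",
#' "threeDisk", or an inline disk table), `noiseSd`, `seed`, `outputDir` and
#' `stages`. Unknown keys are rejected; round-tripping through
#' `writeRunConfig()` is lossless (floats are serialized at full precision).
#'
#' @param path file path.
#' @param config named list.
#' @return `readRunConfig()`: the validated named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .runConfigKeys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(.runConfigKeys, collapse = ", ")))
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), .runConfigKeys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

## resolve config pieces into package objects
.configParams <- function(cfg) {
  variant <- cfg$variant %||% "oneshot64"
  over <- cfg$params %||% list()
  do.call(sequenceVariant, c(list(name = variant), over))
}

.configEddy <- function(cfg) {
  e <- cfg$eddy %||% "none"
  if (is.character(e)) {
    valid <- c("table1_standard_coil", "table2_large_coil", "none")
    if (!e %in% valid)
      stop(sprintf("unknown eddy preset '%s'; valid presets: %s", e,
                   paste(valid, collapse = ", ")))
    return(eddyPreset(e))
  }
  eddyModelSet(gradient = lapply(e$gradient, as.data.frame),
               b0 = lapply(e$b0 %||% list(), as.data.frame))
}

.configPhantom <- function(cfg) {
  ph <- cfg$phantom %||% "capillary"
  if (is.character(ph)) {
    switch(ph,
           capillary = capillaryPhantom(),
           threeDisk = threeDiskPhantom(),
           stop(sprintf("unknown phantom '%s'; valid: capillary, threeDisk", ph)))
  } else {
    digitalPhantom(as.data.frame(ph$disks), t2Star = ph$t2Star %||% 40,
                   name = ph$name %||% "custom")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- raw-train container ----------------------------------------------------

#' Persist / load a raw echo train
#'
#' Container schema (version 1), one serialized list per file:
#' `data` (complex array sample x echo x acquisition), `lineMap`, `params`
#' (all sequence fields by name), `mode`, `corrected`, `seed`, `noiseSd`,
#' `eddyPreset`, `paramsHash`, `meta`, `schema`. The stored metadata are
#' sufficient to regenerate the acquisition exactly.
#'
#' @param train a [RawEchoTrain-class].
#' @param path file path.
#' @return `readEchoTrain()`: the reconstructed [RawEchoTrain-class].
#' @export
writeEchoTrain <- function(train, path) {
  stopifnot(is(train, "RawEchoTrain"))
  p <- train@params
  payload <- list(
    schema = "epighost-rawtrain-v1",
    data = train@data, lineMap = train@lineMap,
    params = list(matrixSize = p@matrixSize, fov = p@fov,
                  echoSpacing = p@echoSpacing, riseTime = p@riseTime,
                  readoutAmplitude = p@readoutAmplitude, dwell = p@dwell,
                  oversampling = p@oversampling, nDummy = p@nDummy,
                  te = p@te, tr = p@tr, nShots = p@nShots,
                  echoesPerShot = p@echoesPerShot,
                  readoutAxis = p@readoutAxis, phaseAxis = p@phaseAxis,
                  sliceAxis = p@sliceAxis, blipMode = p@blipMode),
    mode = train@mode, corrected = train@corrected, seed = train@seed,
    noiseSd = train@noiseSd, eddyPreset = train@eddyPreset,
    paramsHash = train@paramsHash, meta = train@meta)
  saveRDS(payload, path, version = 2)
  invisible(path)
}

#' @rdname writeEchoTrain
#' @export
readEchoTrain <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema, "epighost-rawtrain-v1"))
    stop("not an epighost raw-train container (schema mismatch)")
  params <- do.call(sequenceParams, payload$params)
  new("RawEchoTrain", data = payload$data, lineMap = payload$lineMap,
      params = params, mode = payload$mode, corrected = payload$corrected,
      seed = payload$seed, noiseSd = payload$noiseSd,
      eddyPreset = payload$eddyPreset, paramsHash = payload$paramsHash,
      meta = payload$meta)
}

## ---- CSV exports ------------------------------------------------------------

#' CSV exports of package objects
#'
#' `exportWaveformCsv()` writes (t_us, Gx, Gy, Gz); `exportTrajectoryCsv()`
#' writes the per-sample trajectory table; `exportProfileCsv()` the reference
#' profile; `exportSeriesCsv()` a peak-shift series; `exportGhostReportCsv()`
#' one row per ghost report. `exportEchoCsv()` writes one echo of a raw train
#' as (sample, re, im).
#'
#' @param x object to export.
#' @param path output file.
#' @param ... passthrough (`echo`, `acq` for `exportEchoCsv`).
#' @return the path, invisibly.
#' @export
exportWaveformCsv <- function(x, path) {
  stopifnot(is(x, "GradientWaveform"))
  df <- data.frame(t_us = (seq_len(nrow(x@g)) - 1) * x@dt,
                   Gx = x@g[, 1], Gy = x@g[, 2], Gz = x@g[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportWaveformCsv
#' @export
exportTrajectoryCsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportWaveformCsv
#' @export
exportProfileCsv <- function(x, path) {
  stopifnot(is(x, "ReferenceScanProfile"))
  utils::write.csv(x@table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportWaveformCsv
#' @export
exportSeriesCsv <- function(x, path) {
  stopifnot(is(x, "PeakShiftSeries"))
  utils::write.csv(x@table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportWaveformCsv
#' @export
readSeriesCsv <- function(path, axis = "x") {
  tb <- utils::read.csv(path)
  new("PeakShiftSeries", table = tb[, c("delay_ms", "amplitude")], axis = axis,
      prepulseAmplitude = NA_real_, prepulseDuration = NA_real_, mode = "fast")
}

#' @rdname exportWaveformCsv
#' @export
exportGhostReportCsv <- function(x, path) {
  if (is(x, "GhostMetricReport")) x <- list(x)
  rows <- lapply(x, function(r)
    data.frame(signal_mean = r@signalMean, ghost_mean = r@ghostMean,
               ratio = r@ratio, roi_px = r@roi$sizePx,
               capped = r@capped, overlap = r@overlap))
  df <- do.call(rbind, rows)
  if (!is.null(names(x))) df <- cbind(label = names(x), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportWaveformCsv
#' @export
exportEchoCsv <- function(x, path, echo = 1L, acq = 1L) {
  stopifnot(is(x, "RawEchoTrain"))
  v <- x@data[, echo, acq]
  utils::write.csv(data.frame(sample = seq_along(v), re = Re(v), im = Im(v)),
                   path, row.names = FALSE)
  invisible(path)
}

## ---- image writers ----------------------------------------------------------

#' Write a reconstructed image as NIfTI or TIFF
#'
#' NIfTI output carries the voxel size in mm from the image FOV; TIFF output
#' is 32-bit float, scaled to [0, 1] by the maximum.
#'
#' @param image a [ReconImage-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeReconNifti <- function(image, path) {
  stopifnot(is(image, "ReconImage"))
  d <- dim(image@data)
  vox <- image@fov[seq_along(d)] / d
  nii <- RNifti::asNifti(image@data)
  RNifti::pixdim(nii) <- vox
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname writeReconNifti
#' @export
writeReconTiff <- function(image, path) {
  stopifnot(is(image, "ReconImage"))
  img <- image@data
  if (length(dim(img)) == 3L) img <- img[, , floor(dim(img)[3L] / 2) + 1L]
  tiff::writeTIFF(t(img[, ncol(img):1]) / max(img), path,
                  bits.per.sample = 32L)
  invisible(path)
}

## ---- eddy preset config -----------------------------------------------------

#' Read / write eddy-model configuration files
#'
#' Structured-text (YAML) representation of an [EddyModelSet-class]: per axis,
#' parallel lists `amplitude_percent` / `time_constant_ms` for the gradient
#' eddy components and `b0_coupling` (uT per mT/m) / `b0_tau_ms` for the B0
#' components, plus the preset label. Round-trips exactly (full-precision
#' floats).
#'
#' @param model an [EddyModelSet-class].
#' @param path file path.
#' @return `readEddyConfig()`: the reconstructed [EddyModelSet-class].
#' @export
writeEddyConfig <- function(model, path) {
  stopifnot(is(model, "EddyModelSet"))
  axes <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
    g <- model@gradient[[ax]]
    b <- model@b0[[ax]]
    list(amplitude_percent = as.list(100 * g$amplitude),
         time_constant_ms = as.list(g$tau_ms),
         b0_coupling = as.list(b$coupling_ut),
         b0_tau_ms = as.list(b$tau_ms))
  })
  yaml::write_yaml(list(preset = model@preset, axes = axes), path, precision = 17)
  invisible(path)
}

#' @rdname writeEddyConfig
#' @export
readEddyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  grad <- list(); b0 <- list()
  for (ax in c("x", "y", "z")) {
    a <- cfg$axes[[ax]]
    grad[[ax]] <- data.frame(amplitude = unlist(a$amplitude_percent) / 100,
                             tau_ms = unlist(a$time_constant_ms))
    if (length(a$b0_coupling))
      b0[[ax]] <- data.frame(coupling_ut = unlist(a$b0_coupling),
                             tau_ms = unlist(a$b0_tau_ms))
  }
  eddyModelSet(gradient = grad, b0 = b0, preset = cfg$preset %||% "custom")
}

#' Export a sampled response series as CSV
#'
#' Writes (t_ms, value) rows for any response time series on a uniform
#' raster, e.g. the output of [convolveResponse()] or [b0ShiftTimeseries()].
#'
#' @param values numeric series.
#' @param dt raster interval, us.
#' @param path output file.
#' @param name column name for the values.
#' @return the path, invisibly.
#' @export
exportResponseCsv <- function(values, dt, path, name = "value") {
  df <- data.frame(t_ms = (seq_along(values) - 1) * dt / 1000, v = values)
  names(df)[2] <- name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
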