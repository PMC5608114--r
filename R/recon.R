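## Reference-scan correction and FFT reconstruction: echo-peak detection,
## resampling along the readout to align peak echo times, zeroth-order phase
## correction, Cartesian reordering + centered FFT, and the N/2-ghost metric.

## normalize a negative-polarity echo to ascending readout order on the
## centered DFT sample grid: index map j -> (ns - j) mod ns (0-based), which
## keeps the k = 0 sample fixed
.reverseEcho <- function(v) c(v[1], rev(v[-1]))

#' Detect echo peaks and phases in a reference scan
#'
#' Per acquired echo (negative-polarity echoes are time-reversed first so all
#' echoes share one readout direction): the magnitude maximum is refined to a
#' fractional sample index by three-point parabolic interpolation, and the
#' peak phase is the argument of the complex signal linearly interpolated at
#' that fractional index.
#'
#' @param ref a [RawEchoTrain-class] in reference mode.
#' @return a [ReferenceScanProfile-class].
#' @export
detectEchoPeaks <- function(ref) {
  stopifnot(is(ref, "RawEchoTrain"))
  if (ref@mode != "reference") stop("echo-peak detection requires a reference-mode train")
  if (ref@corrected) stop("expected an uncorrected reference train")
  ns <- dim(ref@data)[1L]
  nEcho <- dim(ref@data)[2L]
  lm1 <- ref@lineMap[ref@lineMap$acq == 1L, ]
  tab <- data.frame(echo = seq_len(nEcho), position = NA_real_,
                    phase_deg = NA_real_, polarity = lm1$polarity[seq_len(nEcho)])
  for (e in seq_len(nEcho)) {
    v <- ref@data[, e, 1L]
    if (tab$polarity[e] < 0) v <- .reverseEcho(v)
    mag <- Mod(v)
    if (max(mag) == 0 || max(mag) - min(mag) < 1e-300 * ns)
      stop(sprintf("echo %d is flat or all-zero; cannot locate its peak", e))
    p0 <- which.max(mag)
    frac <- 0
    if (p0 > 1 && p0 < ns) {
      ym <- mag[p0 - 1]; y0 <- mag[p0]; yp <- mag[p0 + 1]
      den <- ym - 2 * y0 + yp
      if (den < 0) frac <- 0.5 * (ym - yp) / den
      frac <- max(-0.5, min(0.5, frac))
    }
    pos <- (p0 - 1) + frac                       # fractional 0-based index
    pos <- max(0, min(ns - 1e-9, pos))
    tab$position[e] <- pos
    tab$phase_deg[e] <- wrapDeg(Arg(complexInterp(v, pos)) * 180 / pi)
  }
  new("ReferenceScanProfile", table = tab, paramsHash = ref@paramsHash,
      meta = list(samplesPerEcho = ns, seed = ref@seed,
                  eddyPreset = ref@eddyPreset))
}

#' Successive-echo phase differences of a reference profile
#'
#' @param profile a [ReferenceScanProfile-class].
#' @return numeric vector of wrapped differences in (-180, 180], length one
#'   less than the number of echoes.
#' @export
phaseDifferences <- function(profile) {
  stopifnot(is(profile, "ReferenceScanProfile"))
  ph <- profile@table$phase_deg
  if (length(ph) < 2) stop("need at least 2 echoes for phase differences")
  wrapDeg(diff(ph))
}

#' Identity reference profile
#'
#' All peak positions at the window center and all phases zero; correcting
#' with it reduces to even-echo reversal plus decimation (used for
#' "uncorrected" reconstructions).
#'
#' @param params a [SequenceParams-class].
#' @return a [ReferenceScanProfile-class].
#' @export
identityProfile <- function(params) {
  stopifnot(is(params, "SequenceParams"))
  lay <- .seqLayout(params)
  ns <- samplesPerEcho(params)
  new("ReferenceScanProfile",
      table = data.frame(echo = seq_len(params@echoesPerShot),
                         position = ns / 2, phase_deg = 0,
                         polarity = lay$echoPolarity),
      paramsHash = paramsHash(params),
      meta = list(samplesPerEcho = ns, identity = TRUE))
}

#' Apply the reference-scan correction to a raw echo train
#'
#' Per echo: time-reverse negative-polarity echoes, resample the oversampled
#' readout by `(window center - measured peak position)` to align the peak
#' echo times in the switching period, multiply by `exp(-i * peak phase)`
#' (zeroth-order phase correction), and decimate the oversampling down to nx
#' samples on the Cartesian readout grid. The profile's geometry hash must
#' match the raw data's: a profile is only reusable while the gradient coil
#' geometry and sequence are unchanged (it may then correct a different
#' sample).
#'
#' @param raw a [RawEchoTrain-class] (imaging or reference mode, uncorrected).
#' @param profile a [ReferenceScanProfile-class] from [detectEchoPeaks()] or
#'   [identityProfile()].
#' @param kernel resampling kernel: "sinc" (band-limited periodic shift,
#'   default) or "linear".
#' @return a corrected [RawEchoTrain-class] with nx samples per echo.
#' @export
correctEchoTrain <- function(raw, profile, kernel = c("sinc", "linear")) {
  stopifnot(is(raw, "RawEchoTrain"), is(profile, "ReferenceScanProfile"))
  kernel <- match.arg(kernel)
  if (raw@corrected) stop("train is already corrected")
  if (!identical(raw@paramsHash, profile@paramsHash))
    stop("geometry mismatch: the reference profile was measured for a different sequence geometry")
  ns <- dim(raw@data)[1L]
  nEcho <- dim(raw@data)[2L]
  if (nrow(profile@table) != nEcho)
    stop(sprintf("profile has %d echoes but the train has %d", nrow(profile@table), nEcho))
  p <- raw@params
  os <- p@oversampling
  nx <- p@matrixSize[1L]
  keep <- seq(1L, ns, by = os)
  out <- array(complex(real = 0), dim = c(nx, nEcho, dim(raw@data)[3L]))
  shifts <- ns / 2 - profile@table$position
  phasors <- exp(-1i * profile@table$phase_deg * pi / 180)
  for (a in seq_len(dim(raw@data)[3L])) {
    pol <- raw@lineMap$polarity[raw@lineMap$acq == a]
    for (e in seq_len(nEcho)) {
      v <- raw@data[, e, a]
      if (pol[e] < 0) v <- .reverseEcho(v)
      delta <- -shifts[e]                        # evaluate input at j + delta
      if (delta != 0) {
        if (kernel == "sinc") v <- sincShift(v, delta)
        else {
          idx <- (seq_len(ns) - 1 + delta) %% ns
          v <- vapply(idx, function(q) complexInterp(v, q), complex(1))
        }
      }
      w <- v[keep] * phasors[e]
      ## the unpaired -k_max edge cell of the centered DFT grid is zeroed:
      ## opposite-polarity readouts measure opposite band edges there, so the
      ## cell has no parity-consistent partner
      w[1L] <- 0
      out[, e, a] <- w
    }
  }
  res <- raw
  res@data <- out
  res@corrected <- TRUE
  res@meta <- c(raw@meta, list(correction = list(
    kernel = kernel, profileIdentity = isTRUE(profile@meta$identity),
    profileSeed = profile@meta$seed)))
  res
}

#' Reconstruct an image from a corrected echo train
#'
#' Reorders echoes and shots to Cartesian ky (and kz) order using the line
#' map, applies a centered inverse FFT along each encoded dimension, and
#' returns the magnitude image. Every ky (x kz) line must be present exactly
#' once; missing lines are reported.
#'
#' @param corrected a corrected imaging-mode [RawEchoTrain-class].
#' @return a [ReconImage-class].
#' @export
reconstructImage <- function(corrected) {
  stopifnot(is(corrected, "RawEchoTrain"))
  if (!corrected@corrected) stop("reconstruct a corrected train (see correctEchoTrain)")
  if (corrected@mode != "imaging") stop("cannot reconstruct a reference scan")
  p <- corrected@params
  m <- p@matrixSize
  lm <- corrected@lineMap
  want <- expand.grid(kyIndex = 0:(m[2L] - 1L), kzIndex = 0:(m[3L] - 1L))
  have <- paste(lm$kyIndex, lm$kzIndex)
  missing <- setdiff(paste(want$kyIndex, want$kzIndex), have)
  if (length(missing))
    stop(sprintf("incomplete k-space: missing %d line(s): %s", length(missing),
                 paste(utils::head(missing, 8), collapse = "; ")))
  if (any(duplicated(have)))
    stop("duplicated k-space lines in the line map")
  K <- array(complex(real = 0), dim = m)
  for (r in seq_len(nrow(lm)))
    K[, lm$kyIndex[r] + 1L, lm$kzIndex[r] + 1L] <- corrected@data[, lm$echo[r], lm$acq[r]]
  img <- K
  for (d in seq_len(ifelse(m[3L] > 1L, 3L, 2L))) img <- centeredIfftDim(img, d)
  if (m[3L] == 1L) img <- array(img, dim = m[1:2])
  stages <- c(sprintf("simulate[%s]", corrected@eddyPreset),
              if (!is.null(corrected@meta$correction)) {
                if (corrected@meta$correction$profileIdentity) "reverse+decimate"
                else sprintf("refscan-correct[%s]", corrected@meta$correction$kernel)
              },
              if (m[3L] > 1L) "fft3" else "fft2")
  new("ReconImage", data = Mod(img), fov = p@fov, provenance = stages)
}

#' N/2 ghost metric
#'
#' Ratio of the mean magnitude in a square region at the object center to the
#' mean in the same square displaced by ny/2 (with wraparound) along the
#' phase-encoding direction. Larger is better. For 3D images the central
#' slice is used unless `slice` is given.
#'
#' @param image a [ReconImage-class].
#' @param roiPx ROI square side, pixels.
#' @param signalCenter optional (i, j) pixel indices of the signal ROI center;
#'   default: magnitude centroid.
#' @param slice 3D only: slice index (default central).
#' @return a [GhostMetricReport-class]. The report is flagged `capped` when
#'   the ghost mean falls below `1e-12 * max` (ratio then reported against the
#'   epsilon guard) and `overlap` when the ghost ROI intersects the object
#'   support (> 50% of maximum).
#' @export
ghostRatio <- function(image, roiPx = 8L, signalCenter = NULL, slice = NULL) {
  stopifnot(is(image, "ReconImage"))
  img <- image@data
  if (length(dim(img)) == 3L) {
    if (is.null(slice)) slice <- floor(dim(img)[3L] / 2) + 1L
    img <- img[, , slice]
  }
  nx <- nrow(img); ny <- ncol(img)
  if (roiPx > min(nx, ny) / 2) stop("ROI too large for the image grid")
  if (is.null(signalCenter)) {
    w <- img / sum(img)
    signalCenter <- round(c(sum(row(img) * w), sum(col(img) * w)))
  }
  ghostCenter <- c(signalCenter[1], ((signalCenter[2] - 1 + ny / 2) %% ny) + 1)
  roiIdx <- function(center) {
    di <- ((center[1] - 1 + seq_len(roiPx) - ceiling(roiPx / 2)) %% nx) + 1
    dj <- ((center[2] - 1 + seq_len(roiPx) - ceiling(roiPx / 2)) %% ny) + 1
    list(i = di, j = dj)
  }
  sR <- roiIdx(signalCenter)
  gR <- roiIdx(ghostCenter)
  signalMean <- mean(img[sR$i, sR$j])
  ghostMean <- mean(img[gR$i, gR$j])
  eps <- 1e-12 * max(img)
  capped <- ghostMean < eps
  support <- img > 0.5 * max(img)
  overlap <- any(support[gR$i, gR$j])
  new("GhostMetricReport", signalMean = signalMean, ghostMean = ghostMean,
      ratio = signalMean / max(ghostMean, eps),
      roi = list(signalCenter = signalCenter, ghostCenter = ghostCenter,
                 sizePx = roiPx),
      capped = capped, overlap = overlap)
}

#' Relative RMS error of an image against a reference
#'
#' Scales the image by the least-squares optimal factor before comparison
#' (reconstruction units are arbitrary), then returns
#' `||alpha * I - R|| / ||R||`.
#'
#' @param image a [ReconImage-class] or numeric matrix.
#' @param reference numeric matrix of the same size (e.g. from
#'   [rasterizePhantom()]).
#' @return relative RMS error (dimensionless).
#' @export
rmsImageError <- function(image, reference) {
  I <- if (is(image, "ReconImage")) image@data else image
  if (length(dim(I)) == 3L) I <- I[, , floor(dim(I)[3L] / 2) + 1L]
  stopifnot(all(dim(I) == dim(reference)))
  alpha <- sum(I * reference) / sum(I * I)
  sqrt(sum((alpha * I - reference)^2) / sum(reference^2))
}
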