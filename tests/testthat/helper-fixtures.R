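## Shared fixtures, built once per test run and cached (several tests reuse
## the same simulations; the cache keeps the suite fast without on-disk data).

.fxCache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fxCache[[name]])) .fxCache[[name]] <- force(build)()
  .fxCache[[name]]
}

table1Gx <- data.frame(amplitude = c(9.82, 7.88) / 100, tau_ms = c(0.287, 2.12))
table1Gy <- data.frame(amplitude = c(7.62, 6.27) / 100, tau_ms = c(0.330, 2.33))
table1Gz <- data.frame(amplitude = c(5.57, 4.89) / 100, tau_ms = c(0.283, 1.99))

fxEddyT1 <- function() fx("eddyT1", function() eddyPreset("table1_standard_coil"))
fxEddyT1NoB0 <- function() fx("eddyT1noB0", function() eddyPreset("table1_standard_coil", b0 = FALSE))

fxOneshot <- function() fx("oneshot", function() sequenceVariant("oneshot64"))
fxCapillary <- function() fx("capillary", function() capillaryPhantom())
fxCapillaryIdeal <- function() fx("capillaryIdeal", function() capillaryPhantom(t2Star = Inf))

## one-shot 64x64 imaging + reference under the standard-coil eddy model
fxRawEddy <- function() fx("rawEddy", function()
  simulateEpi(fxCapillary(), fxOneshot(), fxEddyT1()))
fxRefEddy <- function() fx("refEddy", function()
  simulateReference(fxCapillary(), fxOneshot(), fxEddyT1()))
fxProfileEddy <- function() fx("profileEddy", function() detectEchoPeaks(fxRefEddy()))

## ideal (no eddy, no relaxation) one-shot acquisition and reconstruction
fxRawIdeal <- function() fx("rawIdeal", function()
  simulateEpi(fxCapillaryIdeal(), fxOneshot()))
fxImgIdeal <- function() fx("imgIdeal", function()
  reconstructImage(correctEchoTrain(fxRawIdeal(), identityProfile(fxOneshot()))))

## manual reference implementation of reversal + decimation used as the
## identity-correction oracle (same grid convention as the package)
manualDecimate <- function(raw) {
  p <- seqParams(raw)
  ns <- dim(trainData(raw))[1L]
  os <- p@oversampling
  out <- array(complex(real = 0), dim = c(p@matrixSize[1L], dim(trainData(raw))[2:3]))
  for (a in seq_len(dim(out)[3])) {
    pol <- lineMap(raw)$polarity[lineMap(raw)$acq == a]
    for (e in seq_len(dim(out)[2])) {
      v <- trainData(raw)[, e, a]
      if (pol[e] < 0) v <- c(v[1], rev(v[-1]))
      w <- v[seq(1L, ns, by = os)]
      w[1L] <- 0
      out[, e, a] <- w
    }
  }
  out
}

## piecewise-linear series on the 1 us raster (local oracle helper)
.knotsToSeriesTest <- function(t, v, n)
  stats::approx(t, v, xout = 0:(n - 1), rule = 2)$y
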