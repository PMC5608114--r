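## Internal numeric helpers.

#' Wrap angles in degrees to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrapDeg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

## centered FFT index shifts (standard fftshift / ifftshift for any length)
fftShift <- function(x) {
  n <- length(x)
  x[c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))]
}

ifftShift <- function(x) {
  n <- length(x)
  x[c((ceiling(n / 2) + 1):n, seq_len(ceiling(n / 2)))]
}

## apply fft along one dimension of an array, centered conventions:
## image = fftShift(ifft(ifftShift(k))) per dimension
centeredIfftDim <- function(a, dim) {
  n <- dim(a)[dim]
  idxIn <- ifftShiftIdx(n)
  idxOut <- fftShiftIdx(n)
  a <- indexDim(a, dim, idxIn)
  a <- applyFftDim(a, dim, inverse = TRUE) / n
  indexDim(a, dim, idxOut)
}

fftShiftIdx <- function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))
ifftShiftIdx <- function(n) c((ceiling(n / 2) + 1):n, seq_len(ceiling(n / 2)))

indexDim <- function(a, dim, idx) {
  nd <- length(dim(a))
  args <- rep(list(quote(expr = )), nd)
  args[[dim]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

applyFftDim <- function(a, dim, inverse = FALSE) {
  d <- dim(a)
  perm <- c(dim, setdiff(seq_along(d), dim))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[dim])
  m <- stats::mvfft(m, inverse = inverse)
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

## band-limited (periodic sinc) sub-sample shift of a complex vector:
## output[j] = input evaluated at (j + delta) on the periodic grid
sincShift <- function(x, delta) {
  n <- length(x)
  if (delta == 0) return(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  if (n %% 2 == 0) {
    ## split the Nyquist bin symmetrically so real inputs stay real
    X <- stats::fft(x)
    ph <- exp(2i * pi * f * delta)
    ph[n / 2 + 1] <- cos(2 * pi * f[n / 2 + 1] * delta)
    return(stats::fft(X * ph, inverse = TRUE) / n)
  }
  stats::fft(stats::fft(x) * exp(2i * pi * f * delta), inverse = TRUE) / n
}

## linear interpolation of a complex series at fractional 0-based index
complexInterp <- function(x, pos) {
  n <- length(x)
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- max(0, min(n - 2, i0))
  x[i0 + 1] * (1 - frac) + x[i0 + 2] * frac
}

## causal discrete convolution of a driving series with an exponential kernel
## sampled on the same raster; FFT-based, linear (non-circular)
causalConvolve <- function(drive, kernel) {
  n <- length(drive)
  m <- length(kernel)
  nf <- stats::nextn(n + m - 1, 2)
  full <- Re(stats::fft(stats::fft(c(drive, rep(0, nf - n))) *
                        stats::fft(c(kernel, rep(0, nf - m))), inverse = TRUE)) / nf
  full[seq_len(n)]
}

## trapezoid helper: ramp a series linearly between breakpoints; used by the
## waveform builder. times in raster units (integer indices).
stopifnotScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
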