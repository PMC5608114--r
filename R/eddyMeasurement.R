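## Delay-swept eddy-current measurement: simulate the gradient-echo peak-shift
## experiment after an intense prepulse, and fit multi-exponential decay
## parameters from the resulting series.

#' Simulate the delay-swept eddy-current measurement
#'
#' An intense readout ("prepulse") gradient is applied before the RF pulse; a
#' gradient echo formed after a variable delay from the prepulse falling edge
#' senses the residual eddy-current gradient field, expressed as a fraction of
#' the applied prepulse amplitude.
#'
#' Two measurement modes:
#' \describe{
#'   \item{fast}{directly samples the residual field from the convolution
#'     model: `stepResponse(d) - stepResponse(d + prepulseDuration)`. With a
#'     prepulse much longer than the slowest time constant this equals the
#'     step response at the delays (the default 20 ms prepulse leaves the
#'     truncation term below 0.03%).}
#'   \item{physics}{simulates the echo: builds the prepulse + bipolar readout
#'     waveform on the 1 us raster, perturbs it with the eddy model, finds the
#'     shift of the k-space zero crossing, subtracts a baseline run without
#'     the prepulse (removing the readout's own eddy contribution), and
#'     converts the shift back to an average residual fraction. The average
#'     over the RF-to-echo window is attributed to the window midpoint, so
#'     reported delays are the effective window midpoints (second-order\n#'     accurate).}
#' }
#'
#' @param eddy an [EddyModelSet-class].
#' @param axis gradient axis measured.
#' @param delays delays from the prepulse falling edge to the RF pulse, ms
#'   (strictly increasing, first >= 0.1).
#' @param prepulseAmplitude prepulse amplitude, mT/m.
#' @param prepulseDuration prepulse duration, ms (should be much longer than
#'   the slowest eddy time constant).
#' @param mode "fast" or "physics".
#' @param readoutAmplitude,readoutHalf physics mode: amplitude (mT/m) and
#'   dephase-lobe duration (ms) of the bipolar measurement readout; the
#'   amplitude must exceed the strongest residual eddy field.
#' @return a [PeakShiftSeries-class].
#' @examples
#' s <- simulatePeakShift(eddyPreset("table1_standard_coil", b0 = FALSE), "x",
#'                        delays = seq(0.1, 10, by = 0.1))
#' head(seriesTable(s))
#' @export
simulatePeakShift <- function(eddy, axis = c("x", "y", "z"),
                              delays = seq(0.1, 10, by = 0.1),
                              prepulseAmplitude = 153, prepulseDuration = 20,
                              mode = c("fast", "physics"),
                              readoutAmplitude = 100, readoutHalf = 0.1) {
  stopifnot(is(eddy, "EddyModelSet"))
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  if (length(delays) == 0) stop("delays must be non-empty")
  comp <- eddy@gradient[[axis]]
  if (mode == "fast") {
    amp <- stepResponse(comp, delays) - stepResponse(comp, delays + prepulseDuration)
    tb <- data.frame(delay_ms = delays, amplitude = amp)
  } else {
    res <- vapply(delays, function(d)
      .physicsPeakShift(comp, d, prepulseAmplitude, prepulseDuration,
                        readoutAmplitude, readoutHalf), numeric(2))
    tb <- data.frame(delay_ms = res["delay_ms", ], amplitude = res["fraction", ])
  }
  new("PeakShiftSeries", table = tb, axis = axis,
      prepulseAmplitude = prepulseAmplitude, prepulseDuration = prepulseDuration,
      mode = mode)
}

## one physics-mode measurement: echo-shift with prepulse minus baseline.
## the readout must be stronger than the residual eddy field so the dephase
## lobe still dephases; the shift-derived average over the RF-to-echo window
## is attributed to the window midpoint (second-order accurate)
.physicsPeakShift <- function(comp, delay, gPre, durPre, gRo, half) {
  riseUs <- 20                                  # fast ramps for the test pulses
  durUs <- durPre * 1000
  hUs <- half * 1000
  rfUs <- durUs + delay * 1000                  # prepulse falls at durUs
  totUs <- rfUs + 4 * hUs + 1000
  n <- as.integer(totUs) + 1L

  mkSeries <- function(withPre) {
    kt <- c(0)
    kv <- c(0)
    if (withPre) {
      kt <- c(kt, 100, 100 + riseUs, durUs - riseUs, durUs)
      kv <- c(kv, 0, gPre, gPre, 0)
    }
    ## bipolar readout after the RF: dephase -gRo for half, rephase +gRo
    kt <- c(kt, rfUs, rfUs + riseUs, rfUs + hUs - riseUs, rfUs + hUs + riseUs,
            rfUs + 3 * hUs - riseUs, rfUs + 3 * hUs, totUs)
    kv <- c(kv, 0, -gRo, -gRo, gRo, gRo, 0, 0)
    .knotsToSeries(list(t = kt, v = kv), n)
  }

  kSeries <- function(g) {
    gTot <- g + convolveResponse(g, comp, dt = 1)
    kAll <- cumsum(gTot) - (gTot + gTot[1]) / 2  # mT/m * us (gamma factored out)
    kAll - kAll[as.integer(rfUs) + 1L]           # phase reference: the RF pulse
  }
  echoTime <- function(k) {
    i0 <- as.integer(rfUs) + 1L + as.integer(hUs)  # search after the dephase lobe
    seg <- k[i0:n]
    cross <- which(seg[-length(seg)] < 0 & seg[-1] >= 0)[1]
    if (is.na(cross))
      stop("no echo formed in the measurement readout (readout too weak against the eddy field?)")
    i <- i0 + cross - 1L
    (i - 1) + (-k[i]) / (k[i + 1] - k[i])        # fractional raster index (us)
  }

  kWith <- kSeries(mkSeries(TRUE))
  kBase <- kSeries(mkSeries(FALSE))
  tWith <- echoTime(kWith)
  ## the readout drive (and hence its own eddy response) is identical in both
  ## runs, so at the with-prepulse echo the prepulse-eddy phase integral is
  ## exactly minus the baseline k there:
  ##   0 = kBase(tWith) + gammaInt[g_eddy,prepulse], both referenced to the RF
  i <- floor(tWith) + 1L
  kB <- kBase[i] + (tWith - (i - 1)) * (kBase[i + 1] - kBase[i])
  intPre <- -kB / 1000                           # mT/m * ms
  tIntMs <- (tWith - rfUs) / 1000                # effective sensing window
  c(fraction = intPre / (tIntMs * gPre),
    delay_ms = delay + tIntMs / 2)
}

#' Fit multi-exponential eddy components to a peak-shift series
#'
#' Nonlinear least squares over amplitudes and time constants of
#' \eqn{\sum_k a_k \exp(-t/\tau_k)}, with bounds `a >= 0`,
#' `tau in [0.01, 100]` ms. Initialization combines a log-linear fit of the
#' series tail (slow component) with a log-linear fit of the early residual
#' (fast component), plus a deterministic coarse multi-start grid of time
#' constants (log-spaced 0.1-20 ms); the best converged refinement by
#' residual norm wins. Components are returned sorted by ascending time
#' constant.
#'
#' @param series a [PeakShiftSeries-class].
#' @param nComponents number of exponentials (1 to 3).
#' @return a list: `components` (data.frame `amplitude`, `tau_ms`),
#'   `residualNorm` (L2 of the residuals), `covariance` (parameter covariance
#'   proxy from the final fit, or NULL), `nStartsTried`.
#' @export
fitExponentials <- function(series, nComponents = 2L) {
  stopifnot(is(series, "PeakShiftSeries"))
  n <- as.integer(nComponents)
  if (n < 1L || n > 3L) stop("nComponents must be 1, 2 or 3")
  tb <- series@table
  if (nrow(tb) < 2L * n + 1L)
    stop(sprintf("need at least %d points to fit %d components", 2L * n + 1L, n))
  t <- tb$delay_ms
  y <- tb$amplitude
  if (max(abs(y)) == 0)
    return(list(components = data.frame(amplitude = rep(0, n), tau_ms = rep(1, n)),
                residualNorm = 0, covariance = NULL, nStartsTried = 0L))

  model <- function(par) {
    a <- par[seq_len(n)]
    tau <- par[n + seq_len(n)]
    colSums(a * exp(-outer(1 / tau, t)))
  }
  resid <- function(par) y - model(par)

  ## amplitudes for fixed time constants by linear least squares (clipped)
  ampsFor <- function(tau) {
    X <- exp(-outer(t, 1 / tau))
    a <- tryCatch(stats::coef(stats::lm.fit(X, y)), error = function(e) rep(NA, n))
    a[!is.finite(a) | a < 0] <- 1e-6 * max(abs(y))
    a
  }

  starts <- list()
  ## heuristic: tail log-linear for the slowest, residual log-linear for the fast
  tauH <- rep(NA_real_, n)
  tail_i <- t >= stats::quantile(t, 0.6) & y > 0
  if (sum(tail_i) >= 2) {
    cf <- stats::coef(stats::lm(log(y[tail_i]) ~ t[tail_i]))
    if (is.finite(cf[2]) && cf[2] < 0) {
      tauH[n] <- min(100, max(0.01, -1 / cf[2]))
      if (n >= 2) {
        ySlow <- y - exp(cf[1]) * exp(-t / tauH[n])
        early_i <- t <= stats::quantile(t, 0.3) & ySlow > 0
        if (sum(early_i) >= 2) {
          sl2 <- stats::coef(stats::lm(log(ySlow[early_i]) ~ t[early_i]))[2]
          if (is.finite(sl2) && sl2 < 0) tauH[1] <- min(100, max(0.01, -1 / sl2))
        }
      }
    }
  }
  if (all(is.finite(tauH))) {
    if (n >= 3) tauH[2] <- sqrt(tauH[1] * tauH[n])
    starts[[length(starts) + 1L]] <- c(ampsFor(tauH), tauH)
  }
  ## coarse deterministic grid
  grid <- exp(seq(log(0.1), log(20), length.out = 6))
  combos <- utils::combn(seq_along(grid), n)
  for (j in seq_len(ncol(combos))) {
    tau <- grid[combos[, j]]
    starts[[length(starts) + 1L]] <- c(ampsFor(tau), tau)
  }

  lower <- c(rep(0, n), rep(0.01, n))
  upper <- c(rep(Inf, n), rep(100, n))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-9), c(rep(Inf, n), rep(99, n)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop(sprintf("exponential fit failed to converge from %d starts (series '%s', %d points)",
                 length(starts), series@axis, nrow(tb)))
  par <- best$fit$par
  o <- order(par[n + seq_len(n)])
  comps <- data.frame(amplitude = par[seq_len(n)][o], tau_ms = par[n + seq_len(n)][o])
  covar <- tryCatch({
    h <- best$fit$hessian
    s2 <- best$rss / max(1, length(y) - 2 * n)
    s2 * solve(h)
  }, error = function(e) NULL)
  list(components = comps, residualNorm = sqrt(best$rss), covariance = covar,
       nStartsTried = length(starts))
}
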