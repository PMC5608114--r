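## Analytic digital phantoms (superpositions of uniform disks) and their
## exact k-space transform, plus rasterization for ground-truth comparisons.

#' Create a digital phantom from a disk table
#'
#' @param disks data.frame with columns `x_mm`, `y_mm`, `r_mm`, `amplitude`.
#' @param t2Star effective T2*, ms (`Inf` for an ideal non-relaxing phantom).
#' @param name label.
#' @return a [DigitalPhantom-class].
#' @export
digitalPhantom <- function(disks, t2Star = 40, name = "phantom") {
  new("DigitalPhantom", disks = as.data.frame(disks), t2Star = t2Star, name = name)
}

#' Total integrated signal of a phantom
#'
#' Sum of `amplitude * pi * r^2` over the disks (the k = 0 value of the
#' transform), in signal units x mm^2.
#'
#' @param phantom a [DigitalPhantom-class].
#' @export
totalSignal <- function(phantom) {
  stopifnot(is(phantom, "DigitalPhantom"))
  d <- phantom@disks
  sum(d$amplitude * pi * d$r_mm^2)
}

#' Capillary-bundle water phantom
#'
#' Emulates a bundle of water-filled glass capillaries in an NMR tube: the
#' water lumens (inner diameter `id`) are unit-amplitude disks on a hexagonal
#' centered packing (1 + 6 + 12 + ... rings) at pitch `od`; the glass walls
#' and the space between capillaries carry no signal. All lumens must fit
#' within the tube's inner radius.
#'
#' @param nCapillaries number of capillaries (a centered hexagonal count: 1,
#'   7, 19, 37, ... or any prefix of the ring-filling order).
#' @param od capillary outer diameter (packing pitch), mm.
#' @param id capillary inner diameter (lumen), mm.
#' @param tubeId tube inner diameter, mm.
#' @param t2Star effective T2*, ms.
#' @param center bundle center (x, y), mm.
#' @return a [DigitalPhantom-class].
#' @examples
#' ph <- capillaryPhantom()         # 19 lumens of radius 0.45 mm at 1.4 mm pitch
#' totalSignal(ph)                  # 19 * pi * 0.45^2
#' @export
capillaryPhantom <- function(nCapillaries = 19L, od = 1.4, id = 0.9,
                             tubeId = 9.0, t2Star = 40, center = c(0, 0)) {
  if (!(od > id && id > 0)) stop("need od > id > 0")
  ## hexagonal centered packing: origin, then rings of 6*k sites at radius k*od
  pts <- matrix(0, nrow = 1, ncol = 2)
  ring <- 1L
  while (nrow(pts) < nCapillaries) {
    ## walk the hexagon ring: start at (ring, 0) in axial coords
    ax <- c(ring, 0)
    dirs <- matrix(c(-1, 1, -1, 0, 0, -1, 1, -1, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
    ringPts <- matrix(0, nrow = 6 * ring, ncol = 2)
    idx <- 1L
    for (d in 1:6) for (s in seq_len(ring)) {
      ringPts[idx, ] <- ax
      ax <- ax + dirs[d, ]
      idx <- idx + 1L
    }
    ## axial -> cartesian (pointy-top hex lattice, pitch od)
    xy <- cbind(od * (ringPts[, 1] + ringPts[, 2] / 2),
                od * ringPts[, 2] * sqrt(3) / 2)
    pts <- rbind(pts, xy)
    ring <- ring + 1L
  }
  pts <- pts[seq_len(nCapillaries), , drop = FALSE]
  rLumen <- id / 2
  if (any(sqrt(rowSums(pts^2)) + rLumen > tubeId / 2 + 1e-9))
    stop(sprintf("packing overflow: %d capillaries at %.3g mm pitch do not fit a %.3g mm tube",
                 nCapillaries, od, tubeId))
  digitalPhantom(
    data.frame(x_mm = pts[, 1] + center[1], y_mm = pts[, 2] + center[2],
               r_mm = rLumen, amplitude = 1),
    t2Star = t2Star, name = sprintf("capillary%d", nCapillaries))
}

#' Three-disk test phantom
#'
#' A small asymmetric phantom (three unequal disks) used as the "different
#' sample" in cross-sample reference-scan reuse exercises and as a fast test
#' fixture.
#'
#' @param scale overall size scale, mm.
#' @param t2Star effective T2*, ms.
#' @return a [DigitalPhantom-class].
#' @export
threeDiskPhantom <- function(scale = 1, t2Star = 40) {
  digitalPhantom(
    data.frame(x_mm = scale * c(-1.8, 1.6, 0.3),
               y_mm = scale * c(-1.2, -0.8, 1.9),
               r_mm = scale * c(1.5, 0.9, 1.1),
               amplitude = c(1, 0.8, 1.2)),
    t2Star = t2Star, name = "threeDisk")
}

#' Exact k-space transform of a disk phantom
#'
#' The 2D Fourier transform of a uniform disk of radius R and amplitude A at
#' center c is \eqn{A \pi R^2 \, [2 J_1(2\pi|k|R) / (2\pi|k|R)] \,
#' e^{-i 2\pi k \cdot c}} (the bracket is 1 at k = 0); the phantom transform
#' is the sum over disks. Valid at arbitrary, off-grid k positions.
#'
#' @param phantom a [DigitalPhantom-class].
#' @param kx,ky k-space coordinates, cycles/mm (vectors of equal length).
#' @return complex vector of k-space values.
#' @export
analyticKspace <- function(phantom, kx, ky) {
  stopifnot(is(phantom, "DigitalPhantom"), length(kx) == length(ky))
  d <- phantom@disks
  s <- complex(real = rep(0, length(kx)))
  kr <- sqrt(kx^2 + ky^2)
  for (j in seq_len(nrow(d))) {
    z <- 2 * pi * kr * d$r_mm[j]
    jinc <- ifelse(z < 1e-12, 1, 2 * besselJ(z, 1) / pmax(z, 1e-300))
    s <- s + d$amplitude[j] * pi * d$r_mm[j]^2 * jinc *
      exp(-2i * pi * (kx * d$x_mm[j] + ky * d$y_mm[j]))
  }
  s
}

#' Rasterize a phantom onto a pixel grid
#'
#' Pixel i (1-based) maps to coordinate `(i - 1 - n/2) * fov / n` mm, matching
#' the FFT reconstruction convention. Disk edges are anti-aliased by linear
#' coverage over one pixel width.
#'
#' @param phantom a [DigitalPhantom-class].
#' @param n grid size (n x n).
#' @param fov field of view, mm.
#' @return numeric n x n matrix (first index x, second y).
#' @export
rasterizePhantom <- function(phantom, n, fov) {
  stopifnot(is(phantom, "DigitalPhantom"))
  px <- fov / n
  coords <- (seq_len(n) - 1 - n / 2) * px
  img <- matrix(0, n, n)
  d <- phantom@disks
  for (j in seq_len(nrow(d))) {
    dx <- coords - d$x_mm[j]
    dy <- coords - d$y_mm[j]
    dist <- sqrt(outer(dx^2, dy^2, `+`))
    cov <- pmin(1, pmax(0, 0.5 + (d$r_mm[j] - dist) / px))
    img <- img + d$amplitude[j] * cov
  }
  img
}
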