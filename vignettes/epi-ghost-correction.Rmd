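---
title: "Simulating EPI under eddy currents and correcting the N/2 ghost with a reference scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating EPI under eddy currents and correcting the N/2 ghost with a reference scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epighost)
```

## The physical model

`epighost` simulates spin-echo echo-planar imaging (EPI) on a small-bore
system whose unshielded gradient coil couples strongly to the surrounding
conductors. Three physical ingredients are modelled; everything else (RF
excitation, slice selection, relaxation during excitation) is idealized.

**Eddy-current gradient field.** Each gradient axis has a linear,
time-invariant eddy response. A unit gradient step applied at $t=0$ induces
an opposing field

$$e(t) = \sum_k c_k\, e^{-t/\tau_k},$$

with dimensionless amplitudes $c_k$ (fractions of the applied step) and time
constants $\tau_k$ in ms. For an arbitrary waveform $G(t)$ the eddy field is
the causal convolution

$$g(t) = -\frac{dG}{dt} * e(t),$$

so the *actual* gradient is $G + g$. The bundled presets hold the measured
two-component models of two unshielded coil sets; for the 39/32 mm set the
constants group into a fast (~0.3 ms) and a slow (~2 ms) family with
amplitudes between 4.9% and 9.8%. Spatially varying (higher-order) eddy
fields and cross-axis coupling are out of scope — each axis only drives its
own symmetry plus the homogeneous term below.

**B0 shift.** Gradient switching also induces a spatially homogeneous field
shift. It is modelled per axis as the same convolution with coupling in µT
of B0 per mT/m of step and a single time constant. The hardware time
constant of this term is not known from the measurements the presets are
based on; the package adopts 0.1 ms as a documented assumption and exposes
it (`b0Tau`). The coupling itself is not a measured quantity either — what
is known is its *effect*: a steady per-echo phase alternation of ~60°
(x readout) and ~140° (y readout) in the one-shot reference scan.
`calibrateB0Coupling()` therefore simulates the steady readout train with a
unit coupling, integrates the proton phase at the echo centers, and scales
the coupling linearly (the map is exactly linear in the coupling because
phases are taken unwrapped). `eddyPreset("table1_standard_coil")` performs
this calibration once per session and caches it; the z axis, for which no
phase alternation is reported, reuses the x target.

**Signal synthesis.** The phantom is a superposition of uniform disks, whose
2D Fourier transform is closed-form (`analyticKspace()`), so the raw signal
can be sampled at arbitrary, off-grid k positions:
$S(\mathbf k)=\sum_j A_j \pi R_j^2\,\mathrm{jinc}(2\pi|\mathbf k|R_j)
e^{-2\pi i\,\mathbf k\cdot\mathbf c_j}$. The simulator integrates the actual
(eddy-perturbed) trajectory $\mathbf k(t)=\gamma\!\int (G+g)\,dt$ with the
180° refocusing pulse modelled as conjugation of the accumulated k (and of
the accumulated B0 phase) at TE/2, multiplies by a $T_2^*$ envelope
$e^{-|t-TE|/T_2^*}$ anchored at the spin-echo center, applies the
accumulated B0-eddy phase, and optionally adds complex white Gaussian noise
(R's Mersenne-Twister, seeded). $T_1$ saturation would only scale the
steady-state amplitude and is not simulated.

## Sequence construction

All waveforms live on a 1 µs raster (the resolution of the pulse-sequence
controller being emulated). The readout train consists of trapezoidal lobes
of ±153 mT/m with a ramp rate of amplitude/riseTime (rise time 0.2 ms,
0→100%), one lobe per echo spacing, five dummy lobes before data
acquisition, and a prephasing lobe. Acquisition windows of
`nx × dwell` (dwell 10 µs, double oversampling → 5 µs samples) are centered
on the lobe flat-tops.

Two timing choices deserve comment:

- **Ramp sampling.** With a 1 ms echo spacing, 0.2 ms ramps on both sides of
  a polarity transition leave a 0.6 ms flat-top, while 64 samples at 10 µs
  span 0.64 ms; the outermost samples of the one-shot variant therefore ride
  the ramp ends, exactly as the timing implies. The constructor only
  requires `nx·dwell ≤ echoSpacing − riseTime`, which all four standard
  variants satisfy. The consequence is that the extreme k samples fall ~0.3%
  short of the nominal ±nx/(2·FOV) and the outer k cells are slightly
  non-uniform — a sub-percent image effect that the tests quantify.
- **Refocusing inside the dummy train.** TE is 80 ms for every variant. For
  echo spacings of 2 and 4 ms the dummy lobes begin before TE/2, so the
  (ideal, instantaneous) 180° pulse falls inside the dummy train. The
  conjugation is applied exactly at TE/2 wherever it falls, and the
  prephasing areas are solved numerically so that the readout k coordinate
  is zero at the center of the first acquired echo in every variant.

Phase encoding defaults to triangular blips placed on the lobe transitions,
sized to advance ky by `nShots` lines per echo and kept clear of the
sampling windows; a constant-gradient alternative with the same per-echo
area sits behind `blipMode = "constant"`. The per-shot pre-encode (the
"e5" lobe) selects the interleave — shot *s* acquires lines *s*,
*s+nShots*, … bottom-up — and 3D variants add a through-plane pre-encode
("e6"). Prephase blocks are trapezoids with the same ramp rate, placed
after the refocusing point when the train leaves room there and directly
after excitation otherwise (their area sign then accounts for the
conjugation); their duration adapts so the amplitude stays below ~85% of
the readout amplitude. The exact shape and placement of these lobes is not
prescribed by the hardware being emulated and is the package's own choice.

## Reference-scan correction

`detectEchoPeaks()` time-reverses negative-polarity echoes, refines the
magnitude maximum with three-point parabolic interpolation and takes the
phase of the linearly interpolated complex signal at the fractional peak.
`correctEchoTrain()` then shift-resamples each oversampled echo by
(window center − measured position) with a band-limited (periodic-sinc)
kernel — a linear kernel is available for speed and recorded in the output's
provenance — multiplies by $e^{-i\,\hat\phi}$ (zeroth-order correction only;
a linear-in-k phase term is deliberately *not* fitted, matching the
correction being emulated), and decimates the oversampling to the nx-point
Cartesian grid. Per-echo peak values are used literally rather than smoothed
across echoes; smoothing can be applied upstream by editing the profile
table. Correction requires the profile's geometry hash to match the data's:
a profile remains valid across *samples* (its peak positions derive from
k-origin crossings, which are object-independent) but not across sequence
geometries.

Three numerical conventions matter here:

- **Even-echo index map.** On the centered DFT grid with offsets
  $-n/2,\dots,n/2-1$, time reversal is implemented as the index map
  $j \mapsto (n-j) \bmod n$, which maps the grid onto itself and keeps the
  k=0 sample fixed — so an ideal acquisition needs *no* resampling at all.
- **Unpaired edge cell.** The $-k_\max$ cell of that asymmetric grid is
  measured by one readout polarity only (the other polarity measures
  $+k_\max$); the cell is zeroed during decimation for parity consistency.
- **Split Nyquist bin.** The periodic-sinc shift splits the Nyquist bin
  symmetrically (cosine weight) so real inputs stay real; the shift is then
  unitary except for that bin, which bounds the energy change of the whole
  correction by the band-edge truncation.

`reconstructImage()` reorders lines via the acquisition's line map, applies
centered inverse FFTs, and returns magnitudes. `ghostRatio()` quantifies the
N/2 ghost as the ratio of mean magnitudes in a square ROI at the object
center versus the same square displaced by ny/2 (wrapped) along phase
encoding, with an ε-guard of $10^{-12}\cdot\max$ for empty ghost regions and
an overlap flag when the ghost ROI intersects the >50%-of-maximum support.

## What the synthetic data do and do not emulate

The generator's defaults are the study conditions of the system being
modelled: FOV 15.36 mm; matrices 64², 128² (4 shots), 256² (16 shots) and
256²×16; 64 ms acquisition window in all variants; TE 80 ms, TR 400 ms;
±153 mT/m readout with 0.2 ms rise; five dummy switchings; double
oversampling; the capillary phantom (19 lumens of 0.9 mm inner diameter at
1.4 mm pitch inside a 9 mm tube — arranged as a centered hexagonal 1+6+12
packing, which "closely packed" implies but does not uniquely determine);
$T_2^*$ = 40 ms. The delay-swept eddy measurement uses delays 0.1–10 ms in
0.1 ms steps; the prepulse (153 mT/m, 20 ms) is a documented assumption, long
enough that the rising-edge term biases the series by <0.03%.

Passing tests on these data demonstrate the *mechanism*: that the
multi-exponential model produces the observed peak-shift and
phase-alternation signatures, that the fitting recovers generating
parameters, and that the reference-scan correction removes the ghost the
model creates. They do not demonstrate performance on real hardware, where
eddy fields vary spatially (the reason edge slices of 3D acquisitions
resist this correction), coils vibrate, $B_0$ drifts, and the ghost ratio
depends on ROI placement. The hardware-measured ghost ratios of the system
this emulates (≈8 and ≈7) are therefore *not* reproduction targets; the
package's end-to-end checks are relative properties — corrected versus
uncorrected — under its own study conditions.

## Numerical choices and degenerate inputs

- Convolutions are FFT-based on the 1 µs raster with kernels truncated when
  the slowest exponential has decayed below $10^{-9}$; exact causality is
  enforced by zeroing the output ahead of the first switching event.
- Trajectories use cumulative trapezoidal integration; acquisition samples
  interpolate linearly between raster points (they coincide with raster
  points for all standard variants).
- The peak detector rejects flat/all-zero echoes with the echo index in the
  error; parabolic refinement is clamped to ±0.5 samples.
- The exponential fitter (bounded Levenberg–Marquardt via `minpack.lm`)
  combines a tail/early log-linear initialization with a deterministic
  log-spaced τ grid (0.1–20 ms) and returns the best refinement by residual
  norm; bounds are $a \ge 0$, $\tau \in [0.01, 100]$ ms. An all-zero series
  short-circuits to zero amplitudes. Recovery degrades as the two time
  constants approach each other (the τ ratio of ~7 in the presets is
  comfortable); this is documented rather than asserted.
- The physics mode of the peak-shift experiment measures the echo through
  the k-space zero crossing, subtracts a baseline run without the prepulse
  (removing the measurement readout's own eddy response exactly, by
  linearity), and attributes the windowed average to the window midpoint
  (second-order accurate); the fast mode samples the residual field
  directly. Equivalence of the two is asserted at 2% in the tests.
- The identity criterion (no eddy ⇒ no correction needed) is asserted with
  a non-relaxing phantom ($T_2^*=\infty$). With $T_2^*=40$ ms the intra-echo
  decay slope itself creates a ~1% odd/even inconsistency — real physics,
  present in any EPI readout, that a zeroth-order reference correction does
  not remove — which would mask the numerical identity being tested. The
  parity ghost is quantified by comparing acquisitions with 5 and 6 dummy
  lobes, which flips the polarity that measures each line.

## Problem sizes

The test suite simulates the 64² one-shot and 128² four-shot variants in
full, the 256² and 3D variants at the waveform/trajectory level, and a 16²
miniature for pipeline round-trips; the rasterization oracle runs at 1024².
These sizes keep the whole suite in the tens of seconds while exercising
every code path; all physics scales linearly in the raster length and
sample count, so larger runs change cost, not behavior.

## Known limitations

Zeroth-order phase correction cannot remove intra-echo B0-phase curvature or
the k-velocity distortion of the gradient eddy (image scaling along the
readout); both survive correction here as they do on hardware. No
off-resonance unwarping, partial Fourier, or parallel imaging. The B0-eddy
time constant and coupling are calibrated assumptions, not measurements. The
raw-train container is an RDS-serialized documented schema with CSV/NIfTI/
TIFF exports for interoperability.
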