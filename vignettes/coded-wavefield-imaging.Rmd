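---
title: "Coded-wavefield ultrasound imaging: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coded-wavefield ultrasound imaging: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cusi` implements the full measurement-and-reconstruction chain of
computational ultrasound imaging: an undersampled matrix probe whose
element fields are scrambled by a plastic phase mask, a Hadamard
synthetic-aperture transmit scheme, a matrix-free model `v = A u` built
from per-element calibration fields, and Doppler processing of the
reconstructed volume ensemble. This vignette records the model, its
assumptions, the tunable parameters, and the numerical and design
decisions — including which features of real data the synthetic chain
does and does not emulate.

## The imaging physics

**Probe.** An `n_x × n_y` (default 8 × 8) kerf-less lattice of square
elements, 1.25 mm pitch, 13.8 MHz centre frequency, 65% fractional
bandwidth, in a 1500 m/s medium. Elements this large (~13λ across) are
extremely directional: bare, the array cannot form high-resolution images,
which is the point — the mask, not the hardware, supplies the diversity.

**Encoding mask.** A thin phase screen of thickness `h(x, y)` in a fast
plastic (Rexolite, c ≈ 2337 m/s — the literature value; configurable)
imposing the delay `Δt = h (1/c_mask − 1/c_medium)`. The generator filters
white noise with an isotropic Gaussian kernel calibrated so the surface
autocorrelation FWHM equals the target feature size (default 370 µm), then
min–max rescales to the height range (default 1.2 mm). The published
surface statistics do not pin down a spectral family; Gaussian-filtered
noise is the simplest admissible choice. A raised-cosine ring (1 mm)
tapers the border with zero gradient at both ends, avoiding diffracting
discontinuities. Amplitude effects — internal mask reverberations,
transmission losses, absorption — are deliberately not modelled: the
reconstruction only requires that simulation and model share identical
fields, exactly as the physical system only requires fields as calibrated.

**Propagation.** Fields move between parallel planes by the angular
spectrum method with time convention `exp(+i2πft)`: propagating
components gain `exp(−i d k_z)`, evanescent components decay, and
components beyond the angular cutoff `k_c = k·D/√(D² + d²)` (D the padded
lateral dimension, d the propagated distance) are zeroed as undersampled.
All transforms are zero-padded ×2 (configurable) against wraparound. The
propagator phase and magnitude are validated against a direct
Rayleigh–Sommerfeld summation oracle (≤3% RMS on 64×64 grids; measured
≈0.01%), Parseval energy conservation, and ±d reversibility.

**Calibration.** The physical system is calibrated once with a hydrophone
scan of every element's field on a plane beyond the waveguide; that
measurement does not exist here, so `synthesize_calibration()` stands in:
piston field → phase screen → angular-spectrum step to the calibration
plane (default 12 mm, the offset below which too few elements insonify
each voxel) → scaled by a toneburst × Gaussian-element-response pulse
spectrum. The 12 mm × 12 mm / 40 µm plane defaults mirror the physical
scan. The synthetic calibration reproduces the *structure* of the real
one (directional bare fields, mask-broadened k-space, per-frequency
complex fields) but not its measurement artifacts: no hydrophone
directivity, no positioning jitter, no measurement noise. Tests passing
on the synthetic system therefore validate the *algorithms*, not the
robustness of the physical calibration.

**Waveguide.** Not simulated: the calibration plane lies beyond it, so
its physics is absorbed into the fields. Its two documented roles are
still representable — the 12 mm offset (z of the calibration plane) and
energy confinement, computable via `energy_outside_window()` and a hard
`apply_aperture_window()` clip for energy studies.

## The operator and solvers

`imaging_operator()` applies `A` and `Aᴴ` without materializing them.
Per frequency, element fields start at the calibration plane and are
stepped slice-by-slice through the volume; at each depth the encoded
transmit fields `P H` and the pulse-echo products accumulate the forward
or adjoint sum. Two numerical choices matter:

* fields stay on the padded plane throughout the depth loop, and the
  angular cutoff uses the *cumulative* distance from the calibration
  plane, so a streamed pass is equal (to roundoff, ~1e−14) to
  reconstructing each slice with one direct step — the slice-streaming
  equivalence property;
* forward and adjoint share one traversal with conjugation reversed, so
  the pair is adjoint to machine precision (randomized inner-product
  tests, and dense agreement with an independently materialized matrix on
  tiny systems).

Peak working memory is O(padded plane × elements) complex values per
frequency; frames are batched through one traversal.

With `phase_only = TRUE` the model keeps only `e^{i arg A}`; entries with
modulus below `amplitude_floor` (default 1e−6, relative to the
frequency–depth block maximum) are zeroed because their phase is
numerically meaningless — `arg(0)` is undefined and such entries carry no
information. Phase-only columns all have norm `√(N_ω N_t N_e)`, the
"sensitivity reweighted to unity" property.

Solvers: the matched filter (default) is a single adjoint application of
the phase-only model. LSMR (implemented in-package from the published
algorithm; no R implementation exists in the dependency stack) minimizes
the residual with monotone estimated residual norms; its iterate at
`max_iter = 8` is the regularized default since later iterations mostly
fit noise. TwIST minimizes `‖v − Au‖² + λ‖u‖₁` with
`λ = lambda_factor·max|Aᴴv|` (default factor 0.2), complex magnitude
soft-thresholding, the published two-step coefficients (`lam1 = 1e−4`),
internal rescaling of the operator to unit spectral norm (power-iteration
estimate, fixed internal seed), and a monotone safeguard that falls back
to the plain IST step; debiasing refits the nonzero support by conjugate
gradients. TwIST with `lambda_factor ≥ 1` provably returns the zero
image; with λ → 0 it converges to the least-squares solution, verified
against a dense QR oracle on a small well-conditioned instance (the
convergence rate of first-order methods makes a severely ill-conditioned
tiny system unusable for that comparison, so the oracle instance uses a
coarse plane where the condition number is ~70).

## Doppler processing

PDI is the per-voxel sum of `|u|²` over frames. The printed formula in
the source literature sums `|u|`, its text says "power"; power is the
default here (`magnitude = TRUE` gives the other convention). CDI is
`arg Σ u(n)u(n+lag)*` over consecutive valid frames; positive phase means
flow away from the probe, and `axial_velocity()` converts by
`w = φ·c·f_rate/(4π f_c)` with Nyquist velocity `c·f_rate/(4 f_c)`. The
subframe scheme reconstructs one subframe per consecutive group of
`subset` transmissions and sliding-window sums `N_t/subset` of them, so
every output image compounds all `N_t` orthogonal transmissions while
successive images are only `subset` transmissions apart; the output count
is exactly `(N_t/subset)·N_f − (N_t/subset − 1)` (a strict sliding
window; edge subframes appear in fewer windows).

Preprocessing: jitter rejection thresholds the lag-1 frame-difference
norm at `median + k·MAD` (default k = 5 — the literature reports only an
"empirically determined threshold"; a robust scale-free rule is
reproducible), flagging both frames of a spiking pair; the first frame
inherits its successor's validity. Block-prefix dropping invalidates the
first `n_drop` frames of each hardware block. The SVD clutter filter
reshapes valid frames to `(N_ω N_t N_e, N_f)`, discards the leading
`floor(0.65·N_sv)` singular components (the floor convention reproduces
the published 5226-of-8041 count) and reconstitutes the tensor; filtering
before reconstruction or after (on the volume stack) agrees on the PDI
within 1% when the clutter subspace is well separated, since per-frame
reconstruction is linear.

## The synthetic data generator and its limits

Phantoms are point-scatterer sets per frame. `spiral_phantom()` is the
classic coded-aperture test object; `flow_phantom()` seeds scatterers
uniformly in a cylinder and advects them along the axis by
`speed/frame_rate` per frame with wrap-around, plus an optional static
"tissue" cloud with amplitude `1/static_fraction`. Scatterers are
deposited on the voxel grid by trilinear spreading and pushed through the
*same* forward operator the reconstruction uses, plus circular complex
white Gaussian noise per tensor entry. This shared code path is
deliberate: it makes simulation and model exactly consistent, which is
what the acquisition–reconstruction contract requires, and it means the
simulations do not probe model mismatch (speckle from sub-resolution
microstructure, aberration, attenuation, calibration error — none are
emulated).

Two properties of the gridded scatterer model matter for Doppler studies
and are easy to miss:

* **Phase aliasing of sub-voxel motion.** Trilinear deposition represents
  a moving scatterer as amplitude blending between neighbouring voxels.
  The model column phase advances by ~`2k·spacing` per axial voxel, so
  blended motion carries a usable lag-1 phase only when
  `2k·spacing < π`. At 15.625 MHz and 40–80 µm spacing this is violated
  (real continuous scatterers have no such limit — this is purely a
  limitation of gridded simulation). The Doppler recovery studies
  therefore run on a 4 MHz desk variant with 50 µm voxels
  (`2k·spacing ≈ 2.1 < π`), where recovered velocities land within a few
  percent of truth.
* **Wrap coherence.** When a scatterer wraps from tube end to start it
  jumps by the tube length L, adding `2kL (mod 2π)` to its echo phase.
  The study tube length is an integer number of two-way half-wavelengths
  (750 µm = 4·λ/2 at 4 MHz) so wrap events are phase-coherent; a
  non-resonant L injects broadband phase noise that biases the lag-1
  phase toward zero (~30% velocity underestimation at 650 µm in the same
  geometry).

## Study sizes and reproducibility

Default problem sizes are desk scale — 2×2 to 8×8 elements, 4–8
frequencies, ≤64³ voxel grids, ≤16-frame ensembles — chosen so each study
is a single-CPU, minutes-scale computation while preserving every
structural property of the full-scale system (the published in vivo scale
of 64 elements × 128 frequencies × ~10⁶ voxels × thousands of frames is
reachable with the same code, just slow). All stochastic stages take
explicit seeds, run under a local RNG that never touches the caller's
state, and are bit-reproducible; pipeline manifests record config, seeds
and output hashes.

## Known limitations

* Synthetic calibration: algorithm validation, not hardware validation
  (no hydrophone directivity, no skull/film attenuation, no aberration).
* The near-probe degradation of the physical system appears in this
  synthetic model as collapsed per-voxel element coverage and raised
  side lobes; the correlation-map *main lobe* near the probe is actually
  narrow (mask speckle decorrelates quickly), so main-lobe width alone is
  not a faithful near-field quality measure here.
* Axial flow only; no vector Doppler, no spectral Doppler, no
  microbubble processing.
* The ℓ1 path (TwIST) inherits first-order convergence: on severely
  ill-conditioned systems it needs many iterations, which is why the
  least-squares default is the early-stopped Krylov solver.
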