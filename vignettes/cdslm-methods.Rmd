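---
title: "Models and methods behind cdslm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cdslm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdslm)
```

# The problem

Optically cleared tissue is never optically homogeneous: residual
refractive-index (RI) variation along the detection path displaces the
effective focal plane as a light-sheet microscope steps through a
millimetre-scale specimen. Without compensation the excitation sheet and
the detection focal plane drift apart — first-order defocus — and image
quality degrades with depth. `cdslm` implements the computational side of
a cleared-tissue digital scanned light-sheet microscope (C-DSLM) that
corrects this drift: a patterned excitation sheet provides a known image
feature, FFT- and DCT-based metrics find the co-planar detection focus,
a sparse calibration curve is interpolated over the scan, HiLo
structured-illumination reconstruction removes residual out-of-focus
haze, and stereological/cell-count quantification runs on the corrected
stacks. Because the original instrument's image data cannot ship with a
package, every algorithm is exercised against a *virtual microscope*
with analytically known ground truth.

# The virtual microscope

## Geometry and excitation

A specimen is a non-negative fluorophore density on a `(z, y, x)` voxel
grid (`specimen_volume()`), with z the axial stepping axis and x the
sheet-propagation (and pattern-modulation) axis. The excitation sheet is
a Gaussian beam (`light_sheet_model()`): intensity FWHM
`w(x) = FWHM0 * sqrt(1 + (x/z_R)^2)` around the waist, with Rayleigh
length `z_R = pi n w0^2 / lambda`, `w0 = FWHM0 / sqrt(2 ln 2)`. Each
image column x sees a Gaussian axial excitation profile of that local
thickness, scaled by `w0-sigma / local-sigma` so every column carries
the same beam energy — a thinner sheet is brighter, not weaker. An
optional tilt (shadow mitigation on the real instrument) ramps the sheet
centre linearly across x. The structured exposure multiplies the
excitation by `(1 + M cos(2 pi x / period + phase)) / 2`; at `M = 0` the
patterned arm delivers exactly half the uniform dose, which is the
normalisation the HiLo demodulation `|U - 2S|` assumes.

## First-order defocus

The focus displacement at depth z is modelled as the line integral
`offset(z) = ∫ (n(z') - n_immersion) dz'` (`required_focus_offset()`).
For homogeneous media this is `(n - n_imm) * z`; for matched media it is
identically zero. The literal product of absolute index and path length
would be nonzero even for matched media, so the differential form is
used; piecewise-constant profiles integrate exactly and arbitrary
`n(z)` functions integrate by trapezoid at sub-micrometre steps.

## Detection

Detection (`detection_model()`) renders the plane displaced from the
sheet by the focal mismatch `applied - required` sharply. Each excited z
slice is blurred laterally by an isotropic Gaussian whose width grows
with that slice's distance m to the focal plane:
`sigma(m) = sigma0 * sqrt(1 + (m / DOF)^2)`, and blurred light is lost
at the field edges rather than reflected. Summing the blurred slices
gives the noiseless image; Poisson shot noise plus additive Gaussian
read noise (default SD 2 counts), both driven by one integer seed,
gives the recorded image. Per-slice blurring matters twice: it lets
out-of-focus content lose its excitation pattern (the contrast HiLo
sectioning exploits) and it makes the edge-column brightness depend on
where the excitation waist sits (the contrast the ETL-1 sweep-limit rule
reads out). No diffraction PSF, scattering, shadow stripes,
photobleaching or chromatic effects are simulated — first-order defocus
is deliberately the only aberration.

## Phantoms

Three seeded specimen classes cover the use cases: Gaussian beads
(calibration targets and count-like objects), straight fibers
(myelin-track-like tubes), and alveolar foam — either a thresholded
smoothed Gaussian random field whose characteristic airspace scales with
the requested mean and whose exact air mask is returned as ground truth,
or a deterministic slab geometry with exactly commanded gap and wall
widths for chord-length oracles. The random foam emulates airspace
topology only; it has no pleural boundary, vasculature, or anisotropic
septal structure, so passing stereology tests demonstrates correctness
of the estimator, not biological realism.

# Focus metrics

`estimate_modulation_frequency()` sums the structured image along y,
removes the mean, and takes the magnitude spectrum; the largest non-DC
bin is refined by three-point parabolic interpolation of log-magnitude.
A peak is accepted only if it exceeds 6 times the median non-DC
magnitude: for a flat Rayleigh-distributed noise spectrum the
false-accept probability per image is below 1e-9, which is what keeps
heavily defocused (pattern-free) candidates from reporting spurious
frequencies during coarse searches. `modulation_mse()` is the squared
error against the commanded frequency.

`se_dct()` — Shannon entropy of the discrete cosine transform — is the
fine focus criterion: 3x3 median prefilter (the minimal filtering that
makes the metric robust at this image depth), orthonormal 2-D DCT-II,
absolute coefficients normalised to a probability vector, entropy in
bits. The normalisation makes the metric invariant to exposure scaling,
which cross-plane comparison requires. An optional radial coefficient
cutoff is exposed but off by default. The DCT is computed through the
even/odd-reordering FFT factorisation and is validated in the tests
against a direct cosine-sum oracle.

# Autofocus and calibration

The coarse search images the pattern at candidate detection offsets and
keeps the candidate with minimal frequency MSE; ties break toward the
smallest actuation. Because near-focus candidates estimate the
frequency almost equally well, the coarse ranking is only reliable to
one or two candidate spacings; the fine SE-DCT search therefore spans
+/-45 µm around the coarse pick at 3 µm steps by default — wide enough
to absorb the coarse slop, still inside the coarse neighbourhood.
Equal fine maxima at both window ends are reported with a warning and
resolved toward the window centre.

`build_calibration()` runs coarse+fine plus an excitation sweep at each
requested sheet position (4–10 positions are typical), centring each
coarse window on a linear extrapolation of the points already
calibrated. Failed positions are excluded rather than extrapolated; at
least two must survive. `interpolate_calibration()` is piecewise-linear
with clamping beyond the first/last point — "interpolation at the
Nyquist limit" is read as: the interpolated map is evaluated at the
scan's own axial sampling, which lazy per-query evaluation reproduces
exactly. `cdslm_scan()` applies the interpolated offset per plane;
`standard_scan()` holds one constant offset, reproducing the
depth-proportional residual of uncompensated LSFM.

The ETL-1 oscillation limits are the one place the source procedure is
genuinely under-specified ("three summed pixel rows"). The
interpretation implemented: the far-left and far-right image columns
(orthogonal to propagation) are summed over a sweep of the excitation
waist position; the limits are the sweep values maximising each edge
sum, i.e. the settings parking the waist at each field edge. This is
only informative when the Rayleigh length is comparable to the field
width — with a long sheet every sweep setting looks identical, and the
function then reports degenerate limits with a warning.

# HiLo reconstruction

`demodulate()` is `D = |U - 2S|`; `hilo_reconstruct()` fuses
`I = eta * G(D) + (U - G(U))` with a Gaussian low-pass G whose width is
`sigma = sqrt(2 ln 2) / (2 pi f_c)` (half amplitude at the crossover
`f_c`, default half the pattern frequency) and a high-pass that is its
exact complement, so `I = U` exactly when `eta * D_LP = U_LP`. All
reconstruction convolutions use reflective padding; identity checks in
the tests use interior pixels only. With `eta = pi/(2M)` and a
flat in-focus scene the reconstruction returns U up to the
discrete-sampling bias of `|cos|` (the sampled mean of `|cos|` at 8
samples per period differs from `2/pi` by 5%; at 16 samples by 1.3%),
which is why fine pattern sampling is used in the identity tests.

## Choosing eta automatically

Theory gives `eta = pi/(2M)`, but M is rarely known exactly, so eta is
selected on a subset of planes by jointly maximising sharpness and
brightness recovery. For each candidate (16 log-spaced values in
`[pi/16, 4*pi]` by default) the score is the product of the min-max
normalised SE-DCT and a brightness-restoration term
`min(B_I/B_U, B_U/B_I)`. The second term deserves a note: the
reconstruction's raw mean brightness is affine-increasing in eta, so
"maximise brightness" taken literally has no optimum, and normalising
both metrics over the candidate grid pins the argmax mid-grid whatever
the data say. Scoring brightness as agreement with the uniform image's
level is the well-posed reading: for a demodulated pair the fused
low-pass band restores the uniform level exactly at `eta = pi/(2M)`, so
the term peaks at the theoretical weight and scales correctly with M.
The per-candidate table (SE-DCT, raw brightness, match, score) is
attached to the result so alternative scalarisations can be audited.
Selection should run on well-focused planes: out-of-focus haze is
present in U but cancelled in D, which biases the match — and hence the
selected eta — upward.

# Quantification

Mean linear intercept: sample lines run along the requested axes on a
lattice (spacing in voxels); a chord is a maximal airspace run wholly
inside the region mask and bounded on both ends by in-region tissue.
Runs touching the image or region border are censored — the
conservative standard choice. `mli_2d()` pools horizontal and vertical
families; `mli_3d()` pools the requested axis-aligned families on the
3-D lattice (oblique families are not used) and retains per-axis
sub-results for anisotropy inspection. L_m is the pooled mean, reported
with its SD because pooling structures of different scales (distal and
proximal airspaces) legitimately widens the chord distribution — the
tests reproduce this on bimodal slab phantoms. Analytic oracles used in
the tests: parallel slabs of gap d give L_m = d exactly; a disk of
radius R gives pi R / 2; a sphere gives 4R/3.

Cell counting: a Gaussian-smoothed background (default sigma 50 px,
about 10x an expected cell diameter; large-sigma subtraction rather
than rolling-ball) is removed, a user threshold selects positive
pixels, connected components are labelled (8-neighbour in 2D,
26-neighbour in 3D by default — built on an igraph adjacency
decomposition), objects inside the configured single-cell size range
count as one, larger objects count as `round(size / median in-range
size)` (the multi-cellular correction), smaller ones are discarded. If
only oversize objects exist the single-cell size cannot be estimated
and the function refuses rather than guessing.

# I/O and the tiled layout

Stacks are uncompressed multi-page TIFF with a plain-text `key=value`
sidecar (voxel geometry, axial step, pattern period, seed, scan mode).
16-bit integer stacks round-trip bit-exactly; float ground-truth stacks
are stored min-max normalised at 32-bit depth with the range recorded
in the sidecar and restored on read. The tiled writer lays tiles out as
`V/V_H/V_H_D.tif` with coordinates in tenths of micrometres zero-padded
to six digits — the classic two-level convention the TeraStitcher
stitcher ingests — and a structural validator checks name patterns and
coordinate consistency. Stitching itself is out of scope.

# Study conditions used by the tests and the acceptance script

The deep-specimen bench is a 3 mm stack (301 planes of 48 x 64 at
2 x 2 x 10 µm voxels, 20 000 beads) under a homogeneous 1.45 vs 1.0
index mismatch — the CLARITY-cleared-tissue-in-air-objective regime,
0.45 µm of defocus per µm of depth; sheet FWHM 10 µm (Rayleigh length
about 0.7 mm), pattern period 16 µm (8 px), detection DOF 15 µm,
in-focus blur sigma 1.5 µm, read noise 2 counts, bead amplitude giving
a shot-noise SNR near 40. Autofocus is verified at 21 planes across the
range; calibration uses 7 positions at 500 µm spacing. HiLo and
eta-selection scenes use 81-plane foam volumes at 2 µm voxels with the
sheet geometry chosen for each regime (thick sheet + shallow DOF for
haze, thin sheet for in-focus selection). These sizes keep every check
analytic or brute-force verifiable at desk scale; they are not
instrument settings.

# Known limitations

- The defocus-to-blur map is a smooth empirical Gaussian model, not a
  wave-optical PSF; absolute SE-DCT values are therefore only
  comparable within a configuration.
- The ETL-1 limit rule is one reading of an under-specified procedure
  and needs waist contrast across the field to be informative.
- Automatic eta selection assumes the subset planes are in focus and
  that out-of-focus content demodulates; heavy haze biases it upward.
- The random foam phantom matches airspace scale, not lung anatomy;
  MLI correctness is demonstrated on geometric oracles.
- The simulator's per-slice blur ignores within-plane RI variation: a
  single offset is assumed valid across a plane, as in the instrument's
  low/moderate-NA regime.
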