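# cdslm

Computational toolkit for **cleared-tissue digital scanned light-sheet
microscopy (C-DSLM)**: autofocus against first-order defocus in
refractive-index-mismatched cleared tissue, HiLo structured-illumination
reconstruction, and the downstream quantification (3D mean linear
intercept stereology, fluorescent cell counting) — together with a
virtual light-sheet microscope that makes every algorithm testable
against analytic ground truth, without instrument hardware or archived
tissue data.

## Who this is for

Light-sheet microscopists and image-analysis developers who need the
C-DSLM processing chain as reusable, tested R functions: to prototype
autofocus/calibration strategies on simulated specimens, to reconstruct
and quantify acquired uniform/structured stacks, or to write
acquisition output in a TeraStitcher-ingestible layout.

## The science in brief

Cleared tissue retains spatially heterogeneous refractive index *n(z)*.
As a light sheet steps to depth *z*, the detection focal plane shifts by
the first-order defocus

```
Δz_focus(z) = ∫₀^z ( n(z') − n_immersion ) dz'        (≈ (n − n_imm)·z for homogeneous media)
```

C-DSLM finds the compensating detection offset automatically using a
sinusoidally patterned sheet:

1. **Coarse:** sweep candidate offsets, estimate the pattern frequency
   from an FFT of the structured image summed along the non-modulated
   axis, and keep the offset minimising the mean squared error against
   the commanded frequency.
2. **Fine:** maximise the Shannon entropy of the image's DCT (SE-DCT) —
   higher for sharper images — in a window around the coarse pick.
3. **Calibrate:** repeat at 4–10 sheet positions, interpolate linearly,
   and scan with the interpolated offsets.

Each plane is acquired twice (uniform *U*, structured *S*) and fused by
HiLo reconstruction:

```
D = |U − 2S|                      (partial demodulation; haze cancels)
I_HiLo = η · D_LP + U_HP          (Gaussian low-pass / complementary high-pass)
η = π / 2M  theoretically, or selected automatically per stack
```

Corrected stacks feed a 3D mean-linear-intercept estimator (airspace
chord lengths L_m on a volumetric line lattice) and a
threshold/connected-component cell counter with a median-size
multi-cell split rule.

## Worked example

A 3 mm bead phantom imaged through a CLARITY-like mismatch (specimen
n = 1.45, air objective n = 1.0 — i.e. 0.45 µm of defocus per µm of
depth), calibrated at 7 positions and scanned in both modes:

```r
library(cdslm)

vol <- make_bead_volume(20000, c(301, 48, 64), voxel_size_um = c(2, 2, 10),
                        seed = 7)
scope <- virtual_scope(
  vol,
  light_sheet_model(waist_fwhm_um = 10, refractive_index_medium = 1.45,
                    modulation_period_um = 16),
  detection_model(depth_of_field_um = 15, base_blur_sigma_um = 1.5,
                  pixel_size_um = 2),
  ri_profile(n_immersion = 1.0, n = 1.45, z_range = c(0, 3010))
)

cal <- build_calibration(scope, seq(0, 3000, by = 500), seed = 5)
cal
#> <cdslm_calibration> 7 points over z = [0, 3000] um
#> # A tibble: 7 × 4
#>   sheet_z_um focus_offset_um etl1_low_um etl1_high_um
#>        <dbl>           <dbl>       <dbl>        <dbl>
#> 1          0               0        31.5         47.2
#> 2        500             225        63          110.
#> 3       1000             453        0            47.2
#> 4       1500             675        0           126
#> 5       2000             900        63          110.
#> 6       2500            1122       15.8          31.5
#> 7       3000            1347       63            94.5
```

The recovered `focus_offset_um` column tracks the analytic defocus line
0.45·z (0, 225, 450, … 1350 µm) to within the 3 µm fine search step.
Scanning with the interpolated calibration versus a constant offset:

```r
glance(cdslm_scan(scope, cal, 0, 3000, 150, seed = 21))
#> # A tibble: 1 × 5
#>   mode  n_planes mean_residual_um max_residual_um mean_sedct
#> 1 cdslm       21             1.26               3       9.16

glance(standard_scan(scope, 0, 3000, 150, initial_offset_um = 0, seed = 21))
#> # A tibble: 1 × 5
#>   mode     n_planes mean_residual_um max_residual_um mean_sedct
#> 1 standard       21              675            1350       5.98
```

The calibrated scan stays within 3 µm of focus everywhere and is
sharper (SE-DCT 9.2 vs 6.0 bits on average); the constant-offset scan's
residual grows to 1.35 mm at depth — the uncompensated-LSFM failure
mode. Stereology on a slab phantom with exactly 12 µm airspaces:

```r
fo <- make_foam_volume(c(72, 16, 16), mean_airspace_um = 12, wall_um = 4,
                       voxel_size_um = c(1, 1, 1), geometry = "slab")
glance(mli_3d(fo$air_mask, grid = grid_spec(2, axes = "z")))
#> # A tibble: 1 × 4
#>   lm_um sd_um n_chords n_lines
#> 1    12     0      256      64
```

Every result type has `tidy()` / `glance()` methods and an `autoplot()`
(calibration curves, scan reports, chord histograms, object-size
histograms). A thin command-line front end (`exec/cdslm`, subcommands
`simulate`, `calibrate`, `scan`, `hilo`, `mli`, `count`, `tile`) wraps
the same functions and logs full provenance per run.

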