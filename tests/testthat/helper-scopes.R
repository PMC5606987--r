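# Shared virtual-microscope fixtures, built in code at test time.

# Deep (3 mm) bead specimen under a CLARITY-like index mismatch
# (n = 1.45 specimen vs n = 1.0 air objective): the autofocus test bench.
make_deep_scope <- function(n_beads = 20000, nz = 301, seed = 7,
                            n_sample = 1.45, n_immersion = 1.0) {
  vol <- make_bead_volume(n_beads, c(nz, 48, 64), voxel_size_um = c(2, 2, 10),
                          seed = seed)
  sheet <- light_sheet_model(waist_fwhm_um = 10,
                             refractive_index_medium = n_sample,
                             modulation_period_um = 16)   # 8 px, k = 0.125
  det <- detection_model(depth_of_field_um = 15, base_blur_sigma_um = 1.5,
                         pixel_size_um = 2)
  prof <- ri_profile(n_immersion = n_immersion, n = n_sample,
                     z_range = c(0, (nz - 1) * 10 + 1))
  virtual_scope(vol, sheet, det, prof)
}

# Small foam specimen with a thick sheet: out-of-focus haze for HiLo.
make_haze_scope <- function(M = 1, seed = 9, waist_fwhm_um = 40,
                            depth_of_field_um = 3) {
  fo <- make_foam_volume(c(81, 64, 64), mean_airspace_um = 24,
                         voxel_size_um = c(2, 2, 2), seed = seed,
                         amplitude = 600)
  sheet <- light_sheet_model(waist_fwhm_um = waist_fwhm_um,
                             refractive_index_medium = 1.45,
                             modulation_amplitude = M,
                             modulation_period_um = 16)
  det <- detection_model(depth_of_field_um = depth_of_field_um,
                         base_blur_sigma_um = 1.5, pixel_size_um = 2)
  prof <- ri_profile(n_immersion = 1.45, n = 1.45, z_range = c(0, 170))
  list(scope = virtual_scope(fo$volume, sheet, det, prof),
       air_mask = fo$air_mask)
}

# Thin sheet fully inside the depth of field: in-focus scenes for the
# eta-selection tests.
make_infocus_scope <- function(M = 1, seed = 4) {
  fo <- make_foam_volume(c(81, 64, 64), mean_airspace_um = 24,
                         voxel_size_um = c(2, 2, 2), seed = seed,
                         amplitude = 600)
  sheet <- light_sheet_model(waist_fwhm_um = 6,
                             refractive_index_medium = 1.45,
                             modulation_amplitude = M,
                             modulation_period_um = 16)
  det <- detection_model(depth_of_field_um = 6, base_blur_sigma_um = 1.5,
                         pixel_size_um = 2)
  prof <- ri_profile(n_immersion = 1.45, n = 1.45, z_range = c(0, 170))
  virtual_scope(fo$volume, sheet, det, prof)
}

# Disk fixture for the cell counter: n_single disks of radius 5 px plus
# optionally one fused pair, on a zero background.
make_disk_image <- function(n_single = 25, fused_pair = FALSE, side = 200,
                            value = 100) {
  yy <- matrix(rep(seq_len(side), side), side)
  xx <- t(yy)
  ctr <- expand.grid(y = seq(20, 180, 40), x = seq(20, 180, 40))
  img <- matrix(0, side, side)
  for (i in seq_len(n_single)) {
    img[(yy - ctr$y[i])^2 + (xx - ctr$x[i])^2 <= 25] <- value
  }
  # the fused pair occupies the last (unused) lattice site
  if (fused_pair) {
    img[(yy - 180)^2 + (xx - 180)^2 <= 25] <- value
    img[(yy - 180)^2 + (xx - 189)^2 <= 25] <- value
  }
  img
}

disk_count_config <- function() {
  cell_count_config(background_sigma_px = 50, threshold = 50,
                    size_range_px = c(40, 130))
}
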