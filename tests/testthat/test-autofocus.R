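test_that("search configuration enforces its geometry", {
  cfg <- search_config()
  expect_lte(cfg$fine_step_um, cfg$coarse_step_um)
  expect_error(search_config(fine_step_um = 50), "exceed")
  expect_error(search_config(fine_range_um = 400), "neighbourhood")
  expect_error(search_config(coarse_range_um = -1), "positive")
})

test_that("coarse search locks onto the true offset by pattern MSE", {
  sc <- make_deep_scope(n_beads = 8000, nz = 121)
  z <- 600  # true offset 270 um under the 1.45 vs 1.0 mismatch
  best <- coarse_focus_search(
    function(o) acquire_plane(sc, z, o, noise = FALSE)$structured,
    seq(-30, 570, 30), 0.125
  )
  expect_lte(abs(as.numeric(best) - 270), 30)
  ser <- attr(best, "series")
  expect_equal(nrow(ser), 21)
})

test_that("coarse search is centred for matched-index specimens", {
  sc <- make_infocus_scope(seed = 3)
  best <- coarse_focus_search(
    function(o) acquire_plane(sc, 80, o, seed = 5)$structured,
    seq(-90, 90, 30), 0.125
  )
  expect_equal(as.numeric(best), 0)
})

test_that("all-dark specimens raise pattern-not-found", {
  dark <- virtual_scope(
    specimen_volume(array(0, c(11, 16, 32)), c(2, 2, 4)),
    light_sheet_model(modulation_period_um = 16),
    detection_model(pixel_size_um = 2, read_noise_sd = 0),
    ri_profile(1.45, n = 1.45, z_range = c(0, 100))
  )
  expect_error(
    coarse_focus_search(
      function(o) acquire_plane(dark, 20, o, noise = FALSE)$structured,
      c(-30, 0, 30), 0.125
    ),
    class = "cdslm_pattern_not_found"
  )
  expect_error(coarse_focus_search(function(o) o, c(0, 1), 0.1), "3 candidate")
})

test_that("fine search refines the coarse pick to within one fine step", {
  sc <- make_deep_scope(n_beads = 8000, nz = 121)
  z <- 260  # true offset 117 um
  refined <- fine_focus_search(
    function(o) acquire_plane(sc, z, o, seed = 31)$uniform,
    center_offset = 120, fine_range_um = 15, fine_step_um = 3
  )
  expect_lte(abs(as.numeric(refined) - 117), 3)
  again <- fine_focus_search(
    function(o) acquire_plane(sc, z, o, seed = 31)$uniform,
    center_offset = 120, fine_range_um = 15, fine_step_um = 3
  )
  expect_identical(as.numeric(refined), as.numeric(again))
})

test_that("fine search keeps the centre when nothing improves on it", {
  # metric engineered to peak exactly at the centre offset
  fake <- function(off) {
    base <- outer(sin(1:32 / 3), cos(1:32 / 4)) * 50 + 60
    gaussian_blur(base, 0.2 + abs(off) / 10)
  }
  best <- fine_focus_search(fake, 0, fine_range_um = 9, fine_step_um = 3)
  expect_equal(as.numeric(best), 0)
})

test_that("fine search warns on equal maxima at both window ends", {
  flat <- function(off) matrix(7, 16, 16)  # se_dct 0 everywhere
  expect_warning(
    best <- fine_focus_search(flat, 10, fine_range_um = 6, fine_step_um = 3),
    "both range ends"
  )
  expect_equal(as.numeric(best), 10)
})

test_that("excitation sweep limits bracket the field edges", {
  # short Rayleigh length so the waist position matters across the field
  den <- array(200, c(41, 48, 64))
  set.seed(7)
  den <- den * (1 + 0.2 * array(runif(length(den)), dim(den)))
  sc <- virtual_scope(
    specimen_volume(den, c(2, 2, 2)),
    light_sheet_model(waist_fwhm_um = 3, refractive_index_medium = 1.45,
                      modulation_period_um = 16),
    detection_model(depth_of_field_um = 2, base_blur_sigma_um = 1.5,
                    pixel_size_um = 2),
    ri_profile(1.45, n = 1.45, z_range = c(0, 100))
  )
  step <- 14.125
  sweep_vals <- seq(-64, 190, by = step)  # field spans x = 0..126
  imgs <- lapply(sweep_vals, function(wx) {
    acquire_plane(sc, 40, 0, noise = FALSE, waist_x_um = wx)$uniform
  })
  lim <- determine_etl1_limits(imgs, sweep_vals)
  expect_lte(lim[["low"]], lim[["high"]])
  expect_lte(abs(lim[["low"]] - 0), step)
  expect_lte(abs(lim[["high"]] - 126), step)
})

test_that("symmetric sweeps give symmetric limits and flat sweeps warn", {
  # edge-column responses mirrored about the middle sweep value: the left
  # sum peaks one step below centre, the right sum one step above
  lvals <- c(1, 3, 2, 1, 0)
  rvals <- rev(lvals)
  sym <- lapply(1:5, function(i) {
    img <- matrix(1, 8, 9)
    img[, 1] <- lvals[i]
    img[, 9] <- rvals[i]
    img
  })
  vals <- -2:2
  lim <- determine_etl1_limits(sym, vals)
  expect_equal(unname(lim[["low"]] + lim[["high"]]), 0)
  expect_equal(unname(lim), c(-1, 1), ignore_attr = TRUE)

  expect_warning(
    lim2 <- determine_etl1_limits(replicate(5, matrix(4, 6, 6),
                                            simplify = FALSE), vals),
    "no waist contrast"
  )
  expect_equal(unname(lim2[["low"]]), unname(lim2[["high"]]))
  expect_error(determine_etl1_limits(sym[1:2], vals[1:2]), "3 sweep")
})

test_that("calibration recovers the analytic defocus line", {
  sc <- make_deep_scope(n_beads = 20000, nz = 301)
  cfg <- search_config(coarse_range_um = 600, coarse_step_um = 30)
  cal <- build_calibration(sc, c(0, 1000, 2000), cfg, seed = 5)
  expect_s3_class(cal, "cdslm_calibration")
  expect_true(all(abs(cal$points$focus_offset_um - c(0, 450, 900)) <=
                    cfg$fine_step_um + 1e-9))
})

test_that("matched-index calibration is flat at zero offset", {
  sc <- make_deep_scope(n_beads = 8000, nz = 61, n_sample = 1.45,
                        n_immersion = 1.45)
  cal <- build_calibration(sc, c(0, 300, 600), seed = 2)
  expect_true(all(abs(cal$points$focus_offset_um) <= 3))
})

test_that("calibration fails cleanly when too few positions survive", {
  dark <- virtual_scope(
    specimen_volume(array(0, c(21, 16, 32)), c(2, 2, 4)),
    light_sheet_model(modulation_period_um = 16),
    detection_model(pixel_size_um = 2, read_noise_sd = 0),
    ri_profile(1.45, n = 1.45, z_range = c(0, 100))
  )
  expect_error(
    suppressWarnings(build_calibration(dark, c(0, 40, 80), noise = FALSE)),
    "fewer than 2"
  )
  sc <- make_infocus_scope()
  expect_error(build_calibration(sc, 80), "at least 2")
})

test_that("interpolation reproduces stored points, affine maps and clamps", {
  pts <- tibble::tibble(
    sheet_z_um = c(0, 400, 1100, 2000),
    focus_offset_um = 0.45 * c(0, 400, 1100, 2000) + 12,
    etl1_low_um = c(0, 5, 10, 15),
    etl1_high_um = c(100, 110, 120, 130)
  )
  curve <- cdslm:::new_calibration_curve(pts)
  # stored points exactly
  got <- interpolate_calibration(curve, pts$sheet_z_um)
  expect_equal(got$focus_offset_um, pts$focus_offset_um)
  expect_equal(got$etl1_low_um, pts$etl1_low_um)
  # affine ground truth recovered exactly anywhere inside
  q <- c(123.4, 700, 1555.5)
  expect_equal(interpolate_calibration(curve, q)$focus_offset_um,
               0.45 * q + 12, tolerance = 1e-12)
  # clamped extrapolation
  out <- interpolate_calibration(curve, c(-500, 5000))
  expect_equal(out$focus_offset_um, c(12, 912))
  expect_equal(out$etl1_high_um, c(100, 130))
})

test_that("calibrated scans stay in focus while constant-offset scans drift", {
  sc <- make_deep_scope(n_beads = 20000, nz = 301)
  cal <- build_calibration(sc, seq(0, 3000, by = 500), seed = 5)
  s_c <- cdslm_scan(sc, cal, 0, 3000, 150, seed = 21)
  s_s <- standard_scan(sc, 0, 3000, 150, initial_offset_um = 0, seed = 21)
  rc <- tidy(s_c); rs <- tidy(s_s)
  expect_true(all(rc$residual_um <= cal$interpolation_step_um + 3))
  # constant-offset residual equals (n - n_imm) * depth exactly
  expect_equal(rs$residual_um, 0.45 * rs$sheet_z_um, tolerance = 1e-9)
  expect_true(all(diff(rs$residual_um) > 0))
  # image quality: calibrated beats constant-offset at every depth beyond 0
  expect_true(all(rc$sedct[-1] > rs$sedct[-1]))
  # determinism
  s_c2 <- cdslm_scan(sc, cal, 0, 3000, 150, seed = 21)
  expect_identical(s_c$pairs[[5]]$uniform, s_c2$pairs[[5]]$uniform)
  expect_error(cdslm_scan(sc, cal, 0, 100, -5), "positive")
  expect_error(standard_scan(sc, 0, 100, 0), "positive")
})

test_that("matched-index scans have identically zero residual", {
  sc <- make_deep_scope(n_beads = 4000, nz = 61, n_sample = 1.45,
                        n_immersion = 1.45)
  s <- standard_scan(sc, 0, 600, 100, seed = 3)
  expect_equal(max(tidy(s)$residual_um), 0)
})

test_that("calibration curves round-trip through CSV", {
  pts <- tibble::tibble(sheet_z_um = c(0, 500, 1000),
                        focus_offset_um = c(0, 225, 450),
                        etl1_low_um = c(0, 1, 2), etl1_high_um = c(9, 8, 7))
  curve <- cdslm:::new_calibration_curve(pts)
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration(curve, f)
  back <- read_calibration(f)
  expect_equal(back$points, curve$points)
  expect_error(read_calibration({
    f2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), f2)
    f2
  }), "columns")
})
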