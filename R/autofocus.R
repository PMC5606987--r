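#' Autofocus search configuration
#'
#' Ranges and steps for the coarse (pattern-frequency MSE) and fine
#' (SE-DCT) focal searches, all in micrometres of detection-focus offset.
#'
#' @param coarse_range_um half-width of the coarse candidate range.
#' @param coarse_step_um coarse candidate spacing.
#' @param fine_range_um half-width of the fine search around the coarse
#'   pick.
#' @param fine_step_um fine candidate spacing (must not exceed the coarse
#'   step).
#' @param known_modulation_frequency commanded pattern frequency in
#'   cycles/pixel (NULL: derived from the scope at calibration time).
#' @return an object of class `cdslm_search_config`.
#' @export
search_config <- function(coarse_range_um = 300, coarse_step_um = 30,
                          fine_range_um = 45, fine_step_um = 3,
                          known_modulation_frequency = NULL) {
  assert_positive(coarse_range_um, "coarse_range_um")
  assert_positive(coarse_step_um, "coarse_step_um")
  assert_positive(fine_range_um, "fine_range_um")
  assert_positive(fine_step_um, "fine_step_um")
  if (fine_step_um > coarse_step_um) {
    stop("`fine_step_um` must not exceed `coarse_step_um`", call. = FALSE)
  }
  if (fine_range_um > coarse_range_um) {
    stop("fine range must lie within the coarse neighbourhood", call. = FALSE)
  }
  structure(list(coarse_range_um = coarse_range_um,
                 coarse_step_um = coarse_step_um,
                 fine_range_um = fine_range_um,
                 fine_step_um = fine_step_um,
                 known_modulation_frequency = known_modulation_frequency),
            class = "cdslm_search_config")
}

cdslm_error <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}

#' Coarse focal search by pattern-frequency MSE
#'
#' Acquires a structured image at each candidate offset and returns the
#' candidate whose estimated modulation frequency has the smallest squared
#' error against the commanded frequency. Ties break toward the smallest
#' absolute offset. If no candidate yields a detectable modulation peak a
#' "pattern not found" error (class `cdslm_pattern_not_found`) is raised —
#' the practical remedy is to lower the pattern frequency.
#'
#' @param acquire_fn function of one offset returning a structured image
#'   matrix.
#' @param candidate_offsets at least three candidate offsets, micrometres.
#' @param known_frequency commanded pattern frequency, cycles/pixel.
#' @return the best offset (scalar), with the per-candidate metric table
#'   in attribute `"series"`.
#' @export
coarse_focus_search <- function(acquire_fn, candidate_offsets, known_frequency) {
  if (length(candidate_offsets) < 3L) {
    stop("need at least 3 candidate offsets", call. = FALSE)
  }
  rows <- purrr::map(candidate_offsets, function(off) {
    img <- acquire_fn(off)
    est <- tryCatch(
      estimate_modulation_frequency(img, known_frequency = known_frequency),
      cdslm_no_modulation = function(e) NULL
    )
    tibble::tibble(
      offset_um = off,
      frequency = if (is.null(est)) NA_real_ else est$frequency_cyc_per_px,
      mse = if (is.null(est)) NA_real_ else est$mse_vs_known
    )
  })
  series <- dplyr::bind_rows(rows)
  ok <- which(!is.na(series$mse))
  if (length(ok) == 0L) {
    stop(cdslm_error("cdslm_pattern_not_found",
                     "pattern not found at any candidate offset; consider lowering the pattern frequency"))
  }
  ord <- ok[order(series$mse[ok], abs(series$offset_um[ok]), series$offset_um[ok])]
  best <- series$offset_um[ord[1]]
  attr(best, "series") <- series
  best
}

#' Fine focal search by SE-DCT maximisation
#'
#' Acquires uniform images over `center_offset +/- fine_range_um` at
#' `fine_step_um` spacing and returns the offset maximising the SE-DCT.
#' Ties break toward the smallest absolute offset; equal maxima at both
#' range ends trigger a warning and the maximum nearer the centre is
#' returned.
#'
#' @param acquire_fn function of one offset returning a uniform image
#'   matrix.
#' @param center_offset centre of the fine window (the coarse pick),
#'   micrometres.
#' @param fine_range_um half-width of the window, micrometres.
#' @param fine_step_um candidate spacing, micrometres.
#' @param median_size,lowpass_radius_frac passed to [se_dct()].
#' @return the refined offset (scalar) with the metric table in attribute
#'   `"series"`.
#' @export
fine_focus_search <- function(acquire_fn, center_offset, fine_range_um = 45,
                              fine_step_um = 3, median_size = 3L,
                              lowpass_radius_frac = NULL) {
  offsets <- center_offset + seq(-fine_range_um, fine_range_um, by = fine_step_um)
  vals <- vapply(offsets, function(off) {
    img <- acquire_fn(off)
    se_dct(img, median_size = median_size,
           lowpass_radius_frac = lowpass_radius_frac)
  }, numeric(1))
  series <- tibble::tibble(offset_um = offsets, sedct = vals)
  mx <- max(vals)
  at_max <- which(vals >= mx - abs(mx) * 1e-12)
  ends <- c(1L, length(offsets))
  if (all(ends %in% at_max)) {
    # non-unimodal metric with maxima at both window ends
    warning("fine search metric has equal maxima at both range ends; ",
            "returning the maximum nearer the centre", call. = FALSE)
    at_max <- at_max[which.min(abs(offsets[at_max] - center_offset))]
  }
  pick <- at_max[order(abs(offsets[at_max]), offsets[at_max])][1]
  best <- offsets[pick]
  attr(best, "series") <- series
  best
}

#' Excitation sweep limits from edge-row sums
#'
#' For each image in a sweep of the excitation focus (ETL-1), sums the
#' three pixel columns orthogonal to the propagation direction at the far
#' left, centre and far right of the field. The returned limits are the
#' sweep values maximising the far-left and far-right sums — the settings
#' that park the excitation waist at each edge of the field — ordered
#' low/high. Uniform images without waist contrast give degenerate equal
#' limits with a warning.
#'
#' @param sweep_images list of image matrices, one per sweep value.
#' @param sweep_values at least three numeric sweep values.
#' @return named numeric vector `c(low, high)` with the per-value sum
#'   table in attribute `"series"`.
#' @export
determine_etl1_limits <- function(sweep_images, sweep_values) {
  if (length(sweep_values) < 3L) {
    stop("need at least 3 sweep values", call. = FALSE)
  }
  if (length(sweep_images) != length(sweep_values)) {
    stop("one image per sweep value required", call. = FALSE)
  }
  sums <- purrr::map(sweep_images, function(img) {
    nc <- ncol(img)
    c(left = sum(img[, 1L]), centre = sum(img[, (nc + 1L) %/% 2L]),
      right = sum(img[, nc]))
  })
  s <- do.call(rbind, sums)
  series <- tibble::tibble(sweep_value = sweep_values,
                           left = s[, "left"], centre = s[, "centre"],
                           right = s[, "right"])
  spread <- function(v) diff(range(v))
  scale0 <- max(abs(s), 1e-300)
  if (spread(s[, "left"]) <= 1e-9 * scale0 && spread(s[, "right"]) <= 1e-9 * scale0) {
    warning("no waist contrast in sweep images; returning degenerate equal limits",
            call. = FALSE)
    mid <- sweep_values[(length(sweep_values) + 1L) %/% 2L]
    out <- c(low = mid, high = mid)
    attr(out, "series") <- series
    return(out)
  }
  lo <- sweep_values[which.max(s[, "left"])]
  hi <- sweep_values[which.max(s[, "right"])]
  out <- sort(c(lo, hi))
  names(out) <- c("low", "high")
  attr(out, "series") <- series
  out
}

new_calibration_curve <- function(points, interpolation_step_um = NA_real_) {
  stopifnot(is.data.frame(points), nrow(points) >= 2L)
  points <- dplyr::arrange(points, .data$sheet_z_um)
  if (any(diff(points$sheet_z_um) <= 0)) {
    stop("calibration sheet_z positions must be strictly increasing", call. = FALSE)
  }
  if (any(points$etl1_low_um > points$etl1_high_um, na.rm = TRUE)) {
    stop("etl1 limits must satisfy low <= high", call. = FALSE)
  }
  structure(list(points = tibble::as_tibble(points),
                 interpolation_step_um = interpolation_step_um),
            class = "cdslm_calibration")
}

#' Build a calibration curve
#'
#' Construct the reference curve of co-planar sheet/detection positions:
#' at each requested sheet position runs the coarse (frequency-MSE) then
#' fine (SE-DCT) focal search and determines the excitation sweep limits.
#' The coarse window is centred on a linear extrapolation of the points
#' already calibrated (0 for the first point). Positions where the pattern
#' cannot be detected are excluded with a warning; at least two must
#' survive.
#'
#' @param scope a [virtual_scope()].
#' @param positions_um sheet positions to calibrate (4–10 recommended).
#' @param config a [search_config()].
#' @param seed base seed for acquisition noise.
#' @param noise logical; simulate noise?
#' @param etl_sweep_n number of waist positions swept for the ETL-1
#'   limits.
#' @return an object of class `cdslm_calibration` whose `points` tibble
#'   has columns `sheet_z_um`, `focus_offset_um`, `etl1_low_um`,
#'   `etl1_high_um`.
#' @export
build_calibration <- function(scope, positions_um, config = search_config(),
                              seed = NULL, noise = TRUE, etl_sweep_n = 9L) {
  stopifnot(inherits(scope, "cdslm_scope"), inherits(config, "cdslm_search_config"))
  if (length(positions_um) < 2L) {
    stop("need at least 2 calibration positions", call. = FALSE)
  }
  positions_um <- sort(positions_um)
  kf <- config$known_modulation_frequency %||%
    (scope$volume$voxel_size_um[["x"]] / scope$sheet$modulation_period_um)
  if (!is_scalar_number(kf)) {
    stop("no known modulation frequency: the sheet model is unmodulated",
         call. = FALSE)
  }
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    derive_seed(seed, counter)
  }
  xs <- volume_x_um(scope$volume)
  sweep_values <- seq(min(xs), max(xs), length.out = etl_sweep_n)
  done <- list()
  for (z in positions_um) {
    centre <- if (length(done) >= 2L) {
      n <- length(done)
      p1 <- done[[n - 1L]]; p2 <- done[[n]]
      p2$focus_offset_um + (p2$focus_offset_um - p1$focus_offset_um) /
        (p2$sheet_z_um - p1$sheet_z_um) * (z - p2$sheet_z_um)
    } else if (length(done) == 1L) {
      done[[1L]]$focus_offset_um
    } else 0
    candidates <- centre + seq(-config$coarse_range_um, config$coarse_range_um,
                               by = config$coarse_step_um)
    coarse <- tryCatch(
      coarse_focus_search(
        function(off) acquire_plane(scope, z, off, seed = next_seed(),
                                    noise = noise)$structured,
        candidates, kf
      ),
      cdslm_pattern_not_found = function(e) NULL
    )
    if (is.null(coarse)) {
      warning("calibration position z = ", z,
              " um excluded: pattern not found", call. = FALSE)
      next
    }
    fine <- fine_focus_search(
      function(off) acquire_plane(scope, z, off, seed = next_seed(),
                                  noise = noise)$uniform,
      as.numeric(coarse), config$fine_range_um, config$fine_step_um
    )
    sweep_imgs <- purrr::map(sweep_values, function(wx) {
      acquire_plane(scope, z, as.numeric(fine), seed = next_seed(),
                    noise = noise, waist_x_um = wx)$uniform
    })
    limits <- suppressWarnings(determine_etl1_limits(sweep_imgs, sweep_values))
    done[[length(done) + 1L]] <- list(sheet_z_um = z,
                                      focus_offset_um = as.numeric(fine),
                                      etl1_low_um = limits[["low"]],
                                      etl1_high_um = limits[["high"]])
  }
  if (length(done) < 2L) {
    stop("fewer than 2 calibration positions succeeded", call. = FALSE)
  }
  new_calibration_curve(dplyr::bind_rows(purrr::map(done, tibble::as_tibble)),
                        interpolation_step_um = config$fine_step_um)
}

#' Interpolate a calibration curve
#'
#' Piecewise-linear interpolation of the focus offset and both excitation
#' sweep limits at the queried sheet positions; queries beyond the first
#' or last calibration point clamp to the end values.
#'
#' @param curve a `cdslm_calibration`.
#' @param query_z_um sheet positions to interpolate at (vectorised).
#' @return a tibble with one row per query and columns `sheet_z_um`,
#'   `focus_offset_um`, `etl1_low_um`, `etl1_high_um`.
#' @export
interpolate_calibration <- function(curve, query_z_um) {
  stopifnot(inherits(curve, "cdslm_calibration"))
  p <- curve$points
  interp <- function(y) approx(p$sheet_z_um, y, xout = query_z_um,
                               method = "linear", rule = 2)$y
  tibble::tibble(
    sheet_z_um = query_z_um,
    focus_offset_um = interp(p$focus_offset_um),
    etl1_low_um = interp(p$etl1_low_um),
    etl1_high_um = interp(p$etl1_high_um)
  )
}

run_scan <- function(scope, z_planes, applied, mode, seed, noise, metrics) {
  pairs <- vector("list", length(z_planes))
  rows <- vector("list", length(z_planes))
  for (i in seq_along(z_planes)) {
    acq <- acquire_plane(scope, z_planes[i], applied[i],
                         seed = derive_seed(seed, i), noise = noise)
    pairs[[i]] <- acq
    rows[[i]] <- tibble::tibble(
      plane = i,
      sheet_z_um = z_planes[i],
      applied_offset_um = applied[i],
      true_offset_um = acq$true_focus_offset_um,
      residual_um = abs(applied[i] - acq$true_focus_offset_um),
      sedct = if (metrics) se_dct(acq$uniform) else NA_real_
    )
  }
  structure(list(pairs = pairs, report = dplyr::bind_rows(rows), mode = mode),
            class = "cdslm_scan")
}

#' Calibrated (C-DSLM) volumetric scan
#'
#' Steps the light-sheet through the requested axial range, applying at
#' each plane the detection-focus offset interpolated from the
#' calibration curve, and records the per-plane residual
#' `|applied - true|` together with the SE-DCT of the uniform image.
#'
#' @param scope a [virtual_scope()].
#' @param curve a `cdslm_calibration` covering the range (clamping at the
#'   ends is the defined behaviour).
#' @param z_start_um,z_stop_um,z_step_um scan range and axial step,
#'   micrometres; the step must be positive.
#' @param seed base seed for acquisition noise.
#' @param noise logical; simulate noise?
#' @param metrics logical; compute the per-plane SE-DCT?
#' @return an object of class `cdslm_scan`: list with `pairs` (the
#'   acquisitions), `report` (tibble: plane, sheet_z_um,
#'   applied_offset_um, true_offset_um, residual_um, sedct) and `mode`.
#' @export
cdslm_scan <- function(scope, curve, z_start_um, z_stop_um, z_step_um,
                       seed = NULL, noise = TRUE, metrics = TRUE) {
  stopifnot(inherits(scope, "cdslm_scope"), inherits(curve, "cdslm_calibration"))
  if (!is_scalar_number(z_step_um) || z_step_um <= 0) {
    stop("`z_step_um` must be positive", call. = FALSE)
  }
  z_planes <- seq(z_start_um, z_stop_um, by = z_step_um)
  applied <- interpolate_calibration(curve, z_planes)$focus_offset_um
  run_scan(scope, z_planes, applied, "cdslm", seed, noise, metrics)
}

#' Constant-offset (standard LSFM) volumetric scan
#'
#' Emulates standard LSFM acquisition: a single constant detection-focus
#' offset (optionally an initial refractive-index matching offset) is
#' applied for every plane, so the residual defocus grows with depth in
#' index-mismatched media.
#'
#' @inheritParams cdslm_scan
#' @param initial_offset_um the constant applied offset, micrometres.
#' @return an object of class `cdslm_scan` with `mode = "standard"`.
#' @export
standard_scan <- function(scope, z_start_um, z_stop_um, z_step_um,
                          initial_offset_um = 0, seed = NULL, noise = TRUE,
                          metrics = TRUE) {
  stopifnot(inherits(scope, "cdslm_scope"))
  if (!is_scalar_number(z_step_um) || z_step_um <= 0) {
    stop("`z_step_um` must be positive", call. = FALSE)
  }
  z_planes <- seq(z_start_um, z_stop_um, by = z_step_um)
  run_scan(scope, z_planes, rep(initial_offset_um, length(z_planes)),
           "standard", seed, noise, metrics)
}

#' Write / read a calibration curve as CSV
#'
#' Round-trips the calibration points through a plain CSV file with
#' columns `sheet_z_um`, `focus_offset_um`, `etl1_low_um`, `etl1_high_um`.
#'
#' @param curve a `cdslm_calibration`.
#' @param path file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a `cdslm_calibration`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "cdslm_calibration"))
  write.csv(curve$points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- read.csv(path)
  need <- c("sheet_z_um", "focus_offset_um", "etl1_low_um", "etl1_high_um")
  if (!all(need %in% names(p))) {
    stop("calibration CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  new_calibration_curve(p[, need])
}

#' @export
print.cdslm_calibration <- function(x, ...) {
  cat("<cdslm_calibration> ", nrow(x$points), " points over z = [",
      min(x$points$sheet_z_um), ", ", max(x$points$sheet_z_um), "] um\n",
      sep = "")
  print(x$points)
  invisible(x)
}

#' @export
print.cdslm_scan <- function(x, ...) {
  cat("<cdslm_scan> mode = ", x$mode, ", ", nrow(x$report), " planes, ",
      "max residual = ", signif(max(x$report$residual_um), 4), " um\n",
      sep = "")
  invisible(x)
}
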