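#' Gaussian-beam light-sheet description
#'
#' Describes the excitation sheet: a Gaussian beam propagating along the
#' image x axis, characterised by its intensity FWHM at the waist, with an
#' optional sinusoidal intensity modulation along x (the HiLo pattern) and
#' an optional entrance-angle tilt. The 1/e^2 waist radius is
#' `w0 = FWHM / sqrt(2 ln 2)` and the Rayleigh length
#' `z_R = pi n w0^2 / lambda`.
#'
#' @param wavelength_um excitation wavelength, micrometres.
#' @param waist_fwhm_um intensity full width at half maximum of the sheet
#'   at its waist, micrometres.
#' @param refractive_index_medium index of the propagation medium.
#' @param modulation_amplitude modulation depth M in \[0, 1\].
#' @param modulation_period_um spatial period of the sinusoidal pattern
#'   along x, micrometres (NA when unmodulated).
#' @param modulation_phase_rad phase of the pattern, radians.
#' @param tilt_rad entrance-angle tilt of the sheet; realised as a linear
#'   ramp of the sheet centre across x.
#' @return an object of class `cdslm_sheet`.
#' @export
light_sheet_model <- function(wavelength_um = 0.488,
                              waist_fwhm_um = 10,
                              refractive_index_medium = 1.45,
                              modulation_amplitude = 1,
                              modulation_period_um = NA_real_,
                              modulation_phase_rad = 0,
                              tilt_rad = 0) {
  assert_positive(wavelength_um, "wavelength_um")
  assert_positive(waist_fwhm_um, "waist_fwhm_um")
  assert_positive(refractive_index_medium, "refractive_index_medium")
  if (!is_scalar_number(modulation_amplitude) ||
      modulation_amplitude < 0 || modulation_amplitude > 1) {
    stop("`modulation_amplitude` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(modulation_period_um)) assert_positive(modulation_period_um, "modulation_period_um")
  w0 <- waist_fwhm_um / sqrt(2 * log(2))
  structure(
    list(
      wavelength_um = wavelength_um,
      waist_fwhm_um = waist_fwhm_um,
      refractive_index_medium = refractive_index_medium,
      modulation_amplitude = modulation_amplitude,
      modulation_period_um = modulation_period_um,
      modulation_phase_rad = modulation_phase_rad,
      tilt_rad = tilt_rad,
      waist_radius_um = w0,
      rayleigh_length_um = pi * refractive_index_medium * w0^2 / wavelength_um
    ),
    class = "cdslm_sheet"
  )
}

#' Sheet thickness away from the waist
#'
#' Gaussian-beam divergence: `w(z) = w0 sqrt(1 + (z/z_R)^2)`, returned as
#' an intensity FWHM. Symmetric in the propagation distance.
#'
#' @param sheet a [light_sheet_model()].
#' @param axial_dist_um distance along the propagation axis from the
#'   waist, micrometres (vectorised).
#' @return intensity FWHM of the sheet, micrometres.
#' @export
sheet_width <- function(sheet, axial_dist_um) {
  stopifnot(inherits(sheet, "cdslm_sheet"))
  sheet$waist_fwhm_um * sqrt(1 + (axial_dist_um / sheet$rayleigh_length_um)^2)
}

#' Refractive-index depth profile
#'
#' The index of the cleared specimen / immersion column as a function of
#' axial depth, together with the index the detection optics assume.
#' Supports a homogeneous index, a piecewise-constant profile (exact
#' integration), or an arbitrary function of depth (trapezoidal
#' integration).
#'
#' @param n_immersion index assumed by the detection optics.
#' @param n homogeneous specimen index (ignored when `breaks`/`fn` given).
#' @param breaks,values piecewise-constant profile: `values[i]` applies on
#'   `[breaks[i-1], breaks[i])` with implicit outer breaks at the ends of
#'   `z_range`; `length(values) == length(breaks) + 1`.
#' @param fn function of depth (micrometres) returning the local index.
#' @param z_range axial domain `c(zmin, zmax)` over which the profile is
#'   defined, micrometres.
#' @return an object of class `cdslm_ri_profile`.
#' @export
ri_profile <- function(n_immersion = 1.0, n = NULL, breaks = NULL,
                       values = NULL, fn = NULL, z_range = c(0, 5000)) {
  stopifnot(length(z_range) == 2L, z_range[1] < z_range[2])
  check_n <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 1.0) || any(x > 1.6)) {
      stop("`", what, "` must lie in [1.0, 1.6]", call. = FALSE)
    }
  }
  check_n(n_immersion, "n_immersion")
  type <- if (!is.null(fn)) "function" else if (!is.null(breaks)) "step" else "constant"
  if (type == "constant") {
    n <- n %||% n_immersion
    check_n(n, "n")
  } else if (type == "step") {
    if (is.null(values) || length(values) != length(breaks) + 1L) {
      stop("`values` must have one more element than `breaks`", call. = FALSE)
    }
    if (is.unsorted(breaks, strictly = TRUE)) stop("`breaks` must be strictly increasing", call. = FALSE)
    check_n(values, "values")
  }
  structure(
    list(n_immersion = n_immersion, type = type, n = n, breaks = breaks,
         values = values, fn = fn, z_range = z_range),
    class = "cdslm_ri_profile"
  )
}

#' First-order defocus accumulated to a depth
#'
#' The detection-focus displacement needed at depth `z` under an index
#' mismatch: the line integral of `n(z') - n_immersion` from the domain
#' origin to `z`. For a homogeneous medium this reduces to
#' `(n - n_immersion) * depth`; for a matched medium it is identically 0.
#'
#' @param profile a [ri_profile()].
#' @param depth_um depth(s) within the profile domain, micrometres.
#' @return focus offset(s), micrometres.
#' @export
required_focus_offset <- function(profile, depth_um) {
  stopifnot(inherits(profile, "cdslm_ri_profile"))
  zr <- profile$z_range
  if (any(depth_um < zr[1] - 1e-9) || any(depth_um > zr[2] + 1e-9)) {
    stop("`depth_um` outside the profile domain [", zr[1], ", ", zr[2], "]",
         call. = FALSE)
  }
  one <- function(d) {
    switch(profile$type,
      constant = (profile$n - profile$n_immersion) * (d - zr[1]),
      step = {
        edges <- c(zr[1], profile$breaks, zr[2])
        lo <- pmin(pmax(edges[-length(edges)], zr[1]), d)
        hi <- pmin(edges[-1], d)
        sum(pmax(hi - lo, 0) * (profile$values - profile$n_immersion))
      },
      `function` = {
        if (d <= zr[1]) return(0)
        np <- max(65L, 2L * ceiling((d - zr[1]) / 1) + 1L)
        z <- seq(zr[1], d, length.out = np)
        y <- vapply(z, profile$fn, numeric(1)) - profile$n_immersion
        sum((y[-1] + y[-np]) / 2 * diff(z))
      }
    )
  }
  vapply(depth_um, one, numeric(1))
}

#' Detection-arm model
#'
#' Abstracts the detection objective: depth of field, in-focus lateral
#' blur, camera pixel size, and read noise. Defocus is modelled as an
#' isotropic Gaussian blur whose width grows with focal mismatch `m` as
#' `sigma(m) = sqrt(sigma0^2 + (sigma0 |m| / DOF)^2)`.
#'
#' @param depth_of_field_um depth of field, micrometres.
#' @param base_blur_sigma_um in-focus lateral blur sigma, micrometres.
#' @param pixel_size_um camera pixel size in sample space, micrometres.
#' @param image_shape optional `(rows, cols)`; when NULL the image grid is
#'   taken from the specimen volume at acquisition time.
#' @param read_noise_sd standard deviation of the additive Gaussian read
#'   noise, counts (default 2).
#' @return an object of class `cdslm_detection`.
#' @export
detection_model <- function(depth_of_field_um = 15,
                            base_blur_sigma_um = 1.5,
                            pixel_size_um = 2,
                            image_shape = NULL,
                            read_noise_sd = 2) {
  assert_positive(depth_of_field_um, "depth_of_field_um")
  assert_positive(base_blur_sigma_um, "base_blur_sigma_um")
  assert_positive(pixel_size_um, "pixel_size_um")
  if (!is_scalar_number(read_noise_sd) || read_noise_sd < 0) {
    stop("`read_noise_sd` must be a non-negative number", call. = FALSE)
  }
  structure(
    list(depth_of_field_um = depth_of_field_um,
         base_blur_sigma_um = base_blur_sigma_um,
         pixel_size_um = pixel_size_um,
         image_shape = image_shape,
         read_noise_sd = read_noise_sd),
    class = "cdslm_detection"
  )
}

#' Defocus blur width
#'
#' @param det a [detection_model()].
#' @param focal_mismatch_um applied minus required focus offset,
#'   micrometres (vectorised).
#' @return blur sigma in micrometres; even in the mismatch and strictly
#'   increasing in its magnitude.
#' @export
blur_sigma <- function(det, focal_mismatch_um) {
  stopifnot(inherits(det, "cdslm_detection"))
  s0 <- det$base_blur_sigma_um
  kd <- s0 / det$depth_of_field_um
  sqrt(s0^2 + (kd * abs(focal_mismatch_um))^2)
}

#' Specimen volume
#'
#' A 3D non-negative fluorophore-density grid with voxel geometry. Axis
#' order is fixed as `(z, y, x)` with z the illumination-stepping axis
#' and x the sheet-propagation / modulation axis.
#'
#' @param density numeric 3D array `(z, y, x)`, all values >= 0.
#' @param voxel_size_um voxel edge lengths `c(x, y, z)`, micrometres.
#' @param origin_um physical coordinate of voxel `(1,1,1)` as `c(x, y, z)`,
#'   micrometres.
#' @return an object of class `cdslm_volume`.
#' @export
specimen_volume <- function(density, voxel_size_um, origin_um = c(0, 0, 0)) {
  if (!is.array(density) || length(dim(density)) != 3L) {
    stop("`density` must be a 3D array (z, y, x)", call. = FALSE)
  }
  if (any(density < 0)) stop("densities must be non-negative", call. = FALSE)
  voxel_size_um <- rep_len(voxel_size_um, 3L)
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(
    list(density = density,
         voxel_size_um = c(x = voxel_size_um[1], y = voxel_size_um[2], z = voxel_size_um[3]),
         origin_um = c(x = origin_um[1], y = origin_um[2], z = origin_um[3])),
    class = "cdslm_volume"
  )
}

# Physical z coordinates of the volume's z planes.
volume_z_um <- function(vol) {
  vol$origin_um[["z"]] + (seq_len(dim(vol$density)[1]) - 1L) * vol$voxel_size_um[["z"]]
}

volume_x_um <- function(vol) {
  vol$origin_um[["x"]] + (seq_len(dim(vol$density)[3]) - 1L) * vol$voxel_size_um[["x"]]
}

#' Virtual light-sheet microscope
#'
#' Bundles a specimen volume, sheet model, detection model and
#' refractive-index profile into one object that the acquisition,
#' autofocus and scan functions operate on.
#'
#' @param volume a [specimen_volume()].
#' @param sheet a [light_sheet_model()].
#' @param detection a [detection_model()].
#' @param profile a [ri_profile()].
#' @return an object of class `cdslm_scope`.
#' @export
virtual_scope <- function(volume, sheet, detection, profile) {
  stopifnot(inherits(volume, "cdslm_volume"), inherits(sheet, "cdslm_sheet"),
            inherits(detection, "cdslm_detection"), inherits(profile, "cdslm_ri_profile"))
  if (!is.null(detection$image_shape)) {
    d <- dim(volume$density)
    if (!identical(as.integer(detection$image_shape), as.integer(d[2:3]))) {
      stop("detection image_shape does not match the specimen (y, x) grid",
           call. = FALSE)
    }
  }
  structure(list(volume = volume, sheet = sheet, detection = detection,
                 profile = profile),
            class = "cdslm_scope")
}

#' Acquire one uniform/structured image pair
#'
#' Renders the fluorescence image of a single light-sheet position.
#' Excitation at each voxel is a Gaussian axial profile centred on the
#' (possibly tilted) sheet plane, with the thickness given by the
#' Gaussian-beam width at that column's distance from the excitation
#' waist and the amplitude scaled so each column carries constant beam
#' energy (peak intensity falls as the sheet thickens). The structured
#' exposure multiplies the excitation by
#' `(1 + M cos(2 pi x / period + phase)) / 2`. Detection focuses on the
#' plane displaced from the sheet by the focal mismatch
#' `applied_offset - required_focus_offset(sheet_z)`: every excited z
#' slice is blurred laterally by its own distance to that focal plane
#' (blurred light is lost at the field edges), the slices are summed,
#' and Poisson noise plus Gaussian read noise is applied, all driven by
#' `seed`.
#'
#' @param scope a [virtual_scope()].
#' @param sheet_z_um commanded axial sheet position, micrometres; must lie
#'   within the volume's z extent.
#' @param applied_offset_um detection focus offset actually applied,
#'   micrometres.
#' @param seed integer seed for the noise (NULL with `noise = FALSE` for
#'   ground truth).
#' @param noise logical; apply Poisson + read noise?
#' @param waist_x_um x position of the excitation waist (default: centre
#'   of the field).
#' @return an object of class `cdslm_acquisition`: a list with `uniform`
#'   and `structured` image matrices `(y, x)`, the commanded `sheet_z_um`,
#'   `applied_focus_offset_um`, ground-truth `true_focus_offset_um`,
#'   `modulation_frequency` (cycles/pixel) and `seed`.
#' @export
acquire_plane <- function(scope, sheet_z_um, applied_offset_um = 0,
                          seed = NULL, noise = TRUE, waist_x_um = NULL) {
  stopifnot(inherits(scope, "cdslm_scope"))
  vol <- scope$volume; sheet <- scope$sheet; det <- scope$detection
  zs <- volume_z_um(vol)
  if (sheet_z_um < min(zs) - 1e-9 || sheet_z_um > max(zs) + 1e-9) {
    stop("`sheet_z_um` lies outside the specimen volume", call. = FALSE)
  }
  d <- dim(vol$density); ny <- d[2]; nx <- d[3]
  xs <- volume_x_um(vol)
  waist_x_um <- waist_x_um %||% mean(range(xs))
  # Per-column sheet geometry: centre (tilt ramp), Gaussian sigma, and an
  # energy-conserving amplitude factor (waist sigma / local sigma).
  centre <- sheet_z_um + tan(sheet$tilt_rad) * (xs - waist_x_um)
  sig_z <- sheet_width(sheet, xs - waist_x_um) / (2 * sqrt(2 * log(2)))
  sig_ref <- sheet$waist_fwhm_um / (2 * sqrt(2 * log(2)))
  amp <- sig_ref / sig_z
  vz <- vol$voxel_size_um[["z"]]
  # Restrict the z integration to slices within 5 sigma of the sheet.
  reach <- 5 * max(sig_z) + max(abs(centre - sheet_z_um))
  kidx <- which(zs >= sheet_z_um - reach & zs <= sheet_z_um + reach)
  M <- sheet$modulation_amplitude
  period <- sheet$modulation_period_um
  if (is.na(period)) {
    pat <- rep(0.5, nx)
    modulation_frequency <- NA_real_
  } else {
    pat <- (1 + M * cos(2 * pi * xs / period + sheet$modulation_phase_rad)) / 2
    modulation_frequency <- vol$voxel_size_um[["x"]] / period
  }
  true_offset <- required_focus_offset(scope$profile, sheet_z_um)
  mismatch <- applied_offset_um - true_offset
  focal_z <- sheet_z_um + mismatch  # the z slice detection renders sharply
  uniform <- matrix(0, ny, nx)
  structured <- matrix(0, ny, nx)
  for (k in kidx) {
    w <- amp * exp(-(zs[k] - centre)^2 / (2 * sig_z^2))  # length nx
    slice_u <- vol$density[k, , ] * rep(w, each = ny)
    slice_s <- slice_u * rep(pat, each = ny)
    s_px <- blur_sigma(det, zs[k] - focal_z) / det$pixel_size_um
    if (s_px > 1e-6) {
      slice_u <- gaussian_blur(slice_u, s_px, boundary = "zero")
      slice_s <- gaussian_blur(slice_s, s_px, boundary = "zero")
    }
    uniform <- uniform + slice_u
    structured <- structured + slice_s
  }
  uniform <- uniform * vz
  structured <- structured * vz
  if (noise) {
    out <- with_seed(seed, {
      u <- matrix(rpois(length(uniform), pmax(uniform, 0)), ny, nx) +
        rnorm(length(uniform), 0, det$read_noise_sd)
      s <- matrix(rpois(length(structured), pmax(structured, 0)), ny, nx) +
        rnorm(length(structured), 0, det$read_noise_sd)
      list(u = u, s = s)
    })
    uniform <- out$u
    structured <- out$s
  }
  structure(
    list(uniform = uniform, structured = structured,
         sheet_z_um = sheet_z_um,
         applied_focus_offset_um = applied_offset_um,
         true_focus_offset_um = true_offset,
         modulation_frequency = modulation_frequency,
         pixel_size_um = det$pixel_size_um,
         seed = seed, noise = noise),
    class = "cdslm_acquisition"
  )
}

#' @export
print.cdslm_acquisition <- function(x, ...) {
  cat("<cdslm_acquisition> ", nrow(x$uniform), "x", ncol(x$uniform),
      " pair at z = ", x$sheet_z_um, " um (applied offset ",
      x$applied_focus_offset_um, " um, true ",
      signif(x$true_focus_offset_um, 6), " um)\n", sep = "")
  invisible(x)
}
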