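#' Estimate the modulation frequency of a structured image
#'
#' Sums the image along the non-modulated axis into a 1-D profile, removes
#' the mean, takes its discrete Fourier transform, and returns the
#' frequency of the largest-magnitude non-DC bin refined by three-point
#' parabolic interpolation of the log-magnitude. A peak is only accepted
#' when it clearly exceeds the spectral floor; otherwise a
#' "no modulation detected" error (class `cdslm_no_modulation`) is raised.
#'
#' @param image numeric matrix `(y, x)`.
#' @param axis modulated axis, `"x"` (columns, default) or `"y"`.
#' @param known_frequency optional commanded frequency (cycles/pixel) used
#'   to fill the `mse_vs_known` field.
#' @param min_peak_ratio detectability requirement: the peak magnitude
#'   must exceed this multiple of the median non-DC magnitude.
#' @return an object of class `cdslm_modulation`: a list with
#'   `frequency_cyc_per_px`, `power` and `mse_vs_known`.
#' @export
estimate_modulation_frequency <- function(image, axis = c("x", "y"),
                                          known_frequency = NULL,
                                          min_peak_ratio = 6) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(image))
  profile <- if (axis == "x") colSums(image) else rowSums(image)
  n <- length(profile)
  if (n < 8L) stop("need at least 8 pixels along the modulated axis", call. = FALSE)
  profile <- profile - mean(profile)
  if (max(abs(profile)) <= .Machine$double.eps * n * max(abs(image), 1)) {
    stop(structure(class = c("cdslm_no_modulation", "error", "condition"),
                   list(message = "no modulation detected: constant profile",
                        call = NULL)))
  }
  sp <- Mod(fft(profile))
  half <- sp[2:(n %/% 2 + 1L)]                     # bins 1 .. n/2
  b <- which.max(half)
  floor_mag <- median(half)
  if (half[b] <= min_peak_ratio * floor_mag) {
    stop(structure(class = c("cdslm_no_modulation", "error", "condition"),
                   list(message = "no modulation detected: peak below spectral floor",
                        call = NULL)))
  }
  # Parabolic sub-bin refinement on log magnitude.
  delta <- 0
  if (b > 1L && b < length(half)) {
    lm1 <- log(half[b - 1L] + 1e-300)
    l0 <- log(half[b] + 1e-300)
    lp1 <- log(half[b + 1L] + 1e-300)
    denom <- lm1 - 2 * l0 + lp1
    if (abs(denom) > 1e-12) delta <- max(-0.5, min(0.5, 0.5 * (lm1 - lp1) / denom))
  }
  freq <- (b + delta) / n
  freq <- max(min(freq, 0.5), 1 / n)
  structure(
    list(frequency_cyc_per_px = freq,
         power = half[b],
         mse_vs_known = if (is.null(known_frequency)) NA_real_ else
           (freq - known_frequency)^2),
    class = "cdslm_modulation"
  )
}

#' Squared error of an estimated modulation frequency
#'
#' @param estimate a [estimate_modulation_frequency()] result or a bare
#'   frequency in cycles/pixel.
#' @param known_frequency commanded pattern frequency, cycles/pixel.
#' @return `(f_hat - f)^2`.
#' @export
modulation_mse <- function(estimate, known_frequency) {
  f <- if (inherits(estimate, "cdslm_modulation")) estimate$frequency_cyc_per_px else estimate
  if (!is_scalar_number(f) || f <= 0 || f > 0.5 ||
      !is_scalar_number(known_frequency) || known_frequency <= 0 ||
      known_frequency > 0.5) {
    stop("frequencies must lie in (0, 0.5] cycles/pixel", call. = FALSE)
  }
  (f - known_frequency)^2
}

#' Shannon entropy of the discrete cosine transform (SE-DCT)
#'
#' Image-sharpness metric: median-filters the image, takes the 2-D
#' orthonormal DCT-II, optionally discards coefficients beyond a radial
#' index cutoff, normalises the absolute coefficients to a probability
#' vector and returns its Shannon entropy in bits. Sharper images spread
#' energy over more coefficients and score higher; a constant (or
#' all-zero) image scores 0. The metric is invariant to positive scaling
#' of the image.
#'
#' @param image numeric matrix, at least 8 x 8.
#' @param median_size median prefilter window (default 3; 1 disables).
#' @param lowpass_radius_frac optional radial cutoff: coefficients with
#'   radial index greater than `lowpass_radius_frac * min(dim(image))` are
#'   dropped before normalisation. Default NULL keeps the full spectrum.
#' @return entropy in bits.
#' @export
se_dct <- function(image, median_size = 3L, lowpass_radius_frac = NULL) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 8L || ncol(image) < 8L) {
    stop("`image` must be at least 8 x 8", call. = FALSE)
  }
  if (median_size > 1L) image <- median_filter(image, median_size)
  co <- dct_2d(image)
  if (!is.null(lowpass_radius_frac)) {
    r <- sqrt(outer((seq_len(nrow(co)) - 1L)^2, (seq_len(ncol(co)) - 1L)^2, `+`))
    co[r > lowpass_radius_frac * min(dim(co))] <- 0
  }
  a <- abs(co)
  a[a < max(a) * 1e-12] <- 0  # numerical floor
  s <- sum(a)
  if (s <= 0) return(0)
  p <- a[a > 0] / s
  -sum(p * log2(p))
}

#' Mean image brightness
#'
#' @param image non-empty numeric matrix or array.
#' @return arithmetic mean of the pixel values.
#' @export
brightness <- function(image) {
  if (length(image) == 0L) stop("`image` must be non-empty", call. = FALSE)
  mean(image)
}

#' Sweep focus metrics over candidate offsets
#'
#' Convenience wrapper producing the metric table the autofocus searches
#' operate on: for each candidate detection-focus offset, acquires a pair
#' from the virtual scope and records the frequency-MSE of the structured
#' image and the SE-DCT and brightness of the uniform image.
#'
#' @param scope a [virtual_scope()].
#' @param sheet_z_um sheet position, micrometres.
#' @param offsets_um strictly increasing candidate offsets, micrometres.
#' @param seed base seed for acquisition noise.
#' @param noise logical; simulate noise?
#' @return a tibble with columns `offset_um`, `mse`, `sedct`,
#'   `brightness`.
#' @export
focus_metric_sweep <- function(scope, sheet_z_um, offsets_um, seed = NULL,
                               noise = TRUE) {
  if (is.unsorted(offsets_um, strictly = TRUE)) {
    stop("`offsets_um` must be strictly increasing", call. = FALSE)
  }
  kf <- scope$volume$voxel_size_um[["x"]] / scope$sheet$modulation_period_um
  rows <- purrr::imap(offsets_um, function(off, i) {
    acq <- acquire_plane(scope, sheet_z_um, off, seed = derive_seed(seed, i),
                         noise = noise)
    est <- tryCatch(estimate_modulation_frequency(acq$structured),
                    cdslm_no_modulation = function(e) NULL)
    tibble::tibble(
      offset_um = off,
      mse = if (is.null(est) || is.na(kf)) NA_real_ else modulation_mse(est, kf),
      sedct = se_dct(acq$uniform),
      brightness = brightness(acq$uniform)
    )
  })
  dplyr::bind_rows(rows)
}
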