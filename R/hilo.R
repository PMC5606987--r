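#' Uniform/structured reconstruction pair
#'
#' Co-registered uniform image U and structured image S for one plane,
#' plus the modulation frequency of the sinusoidal pattern along x.
#'
#' @param uniform,structured numeric matrices of identical shape.
#' @param modulation_frequency pattern frequency in cycles/pixel, in
#'   (0, 0.5].
#' @return an object of class `cdslm_pair`.
#' @export
reconstruction_pair <- function(uniform, structured, modulation_frequency) {
  if (!is.matrix(uniform) || !is.matrix(structured) ||
      !identical(dim(uniform), dim(structured))) {
    stop("`uniform` and `structured` must be matrices of identical shape",
         call. = FALSE)
  }
  if (!is_scalar_number(modulation_frequency) || modulation_frequency <= 0 ||
      modulation_frequency > 0.5) {
    stop("`modulation_frequency` must lie in (0, 0.5] cycles/pixel",
         call. = FALSE)
  }
  structure(list(uniform = uniform, structured = structured,
                 modulation_frequency = modulation_frequency),
            class = "cdslm_pair")
}

#' Coerce an acquisition to a reconstruction pair
#'
#' @param acquisition a [acquire_plane()] result.
#' @return a [reconstruction_pair()].
#' @export
as_reconstruction_pair <- function(acquisition) {
  stopifnot(inherits(acquisition, "cdslm_acquisition"))
  if (is.na(acquisition$modulation_frequency)) {
    stop("acquisition has no modulation pattern", call. = FALSE)
  }
  reconstruction_pair(acquisition$uniform, acquisition$structured,
                      acquisition$modulation_frequency)
}

#' HiLo fusion parameters
#'
#' @param eta fusion weight for the low-passed demodulated image; NULL
#'   defaults to the theoretical value `pi / (2 M)`.
#' @param cutoff_frequency low-/high-pass crossover in cycles/pixel; NULL
#'   defaults to half the pair's modulation frequency at reconstruction
#'   time.
#' @param modulation_amplitude modulation depth M in (0, 1].
#' @return an object of class `cdslm_hilo_params`.
#' @export
hilo_params <- function(eta = NULL, cutoff_frequency = NULL,
                        modulation_amplitude = 1) {
  if (!is_scalar_number(modulation_amplitude) || modulation_amplitude <= 0 ||
      modulation_amplitude > 1) {
    stop("`modulation_amplitude` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(eta) && (!is_scalar_number(eta) || eta < 0)) {
    stop("`eta` must be a non-negative number", call. = FALSE)
  }
  if (!is.null(cutoff_frequency) &&
      (!is_scalar_number(cutoff_frequency) || cutoff_frequency <= 0)) {
    stop("`cutoff_frequency` must be positive", call. = FALSE)
  }
  structure(list(eta = eta, cutoff_frequency = cutoff_frequency,
                 modulation_amplitude = modulation_amplitude),
            class = "cdslm_hilo_params")
}

#' Partial demodulation
#'
#' `D(x) = |U(x) - 2 S(x)|` pixelwise. For a perfectly structured
#' exposure `S = U (1 + M cos) / 2` this equals `U M |cos|`; out-of-focus
#' content, whose pattern has washed out to `S = U / 2`, cancels.
#'
#' @param pair a [reconstruction_pair()] (or any list with matching
#'   `uniform` and `structured` matrices).
#' @return non-negative matrix D.
#' @export
demodulate <- function(pair) {
  u <- pair$uniform; s <- pair$structured
  if (!identical(dim(u), dim(s))) {
    stop("uniform and structured images must share a shape", call. = FALSE)
  }
  abs(u - 2 * s)
}

#' Theoretical HiLo fusion weight
#'
#' @param M modulation amplitude in (0, 1].
#' @return `pi / (2 M)`.
#' @export
eta_theoretical <- function(M) {
  if (!is_scalar_number(M) || M <= 0 || M > 1) {
    stop("`M` must lie in (0, 1]", call. = FALSE)
  }
  pi / (2 * M)
}

hilo_sigma_px <- function(cutoff) sqrt(2 * log(2)) / (2 * pi * cutoff)

#' HiLo reconstruction of one plane
#'
#' `I = eta * G_LP(D) + (U - G_LP(U))` where `G_LP` is a Gaussian
#' low-pass whose kernel width is set from the crossover frequency
#' (`sigma = sqrt(2 ln 2) / (2 pi cutoff)`, half amplitude at the
#' cutoff) and the high-pass is its exact complement, so the
#' reconstruction returns U exactly when `eta * D_LP = U_LP`. The output
#' is floating point and not clamped.
#'
#' @param pair a [reconstruction_pair()].
#' @param params a [hilo_params()].
#' @return reconstructed image matrix.
#' @export
hilo_reconstruct <- function(pair, params = hilo_params()) {
  stopifnot(inherits(pair, "cdslm_pair"), inherits(params, "cdslm_hilo_params"))
  k <- pair$modulation_frequency
  cutoff <- params$cutoff_frequency %||% (k / 2)
  if (cutoff >= k) {
    warning("cutoff frequency >= modulation frequency: demodulated signal ",
            "leaks into the high-pass band", call. = FALSE)
  }
  eta <- params$eta %||% eta_theoretical(params$modulation_amplitude)
  s_px <- hilo_sigma_px(cutoff)
  d_lp <- gaussian_blur(demodulate(pair), s_px)
  u_lp <- gaussian_blur(pair$uniform, s_px)
  eta * d_lp + (pair$uniform - u_lp)
}

default_eta_grid <- function(n = 16L) {
  exp(seq(log(pi / 16), log(4 * pi), length.out = n))
}

#' Automatic selection of the HiLo fusion weight
#'
#' Reconstructs a subset of planes at each candidate eta and selects the
#' candidate that simultaneously maximises sharpness and brightness
#' recovery: the score is the mean over planes of the product of the
#' min-max normalised SE-DCT and a brightness-restoration term
#' `min(B_I/B_U, B_U/B_I)` comparing the reconstruction's mean intensity
#' with the uniform image's. Raw mean brightness grows without bound in
#' eta, so "maximising brightness" is scored as restoring the uniform
#' brightness level; for a well-demodulated pair this term peaks at
#' `eta = pi/(2 M)` where the fused low-pass band matches the uniform
#' image. The full per-candidate metric table is attached so alternative
#' scalarisations can be audited. Ties break toward the smaller eta.
#'
#' @param pairs a [reconstruction_pair()] or list of them (the stack
#'   subset).
#' @param candidate_etas at least two candidate weights (a single
#'   candidate is returned as-is).
#' @param params a [hilo_params()]; its `eta` field is ignored.
#' @return the selected eta (scalar) with the per-candidate score table
#'   in attribute `"scores"`.
#' @export
auto_eta <- function(pairs, candidate_etas = default_eta_grid(),
                     params = hilo_params()) {
  if (inherits(pairs, "cdslm_pair")) pairs <- list(pairs)
  if (length(pairs) < 1L) stop("need at least one pair", call. = FALSE)
  if (length(candidate_etas) == 1L) return(candidate_etas)
  etas <- sort(candidate_etas)
  sed <- matrix(NA_real_, length(pairs), length(etas))
  bri <- matrix(NA_real_, length(pairs), length(etas))
  bmatch <- matrix(NA_real_, length(pairs), length(etas))
  any_signal <- FALSE
  for (i in seq_along(pairs)) {
    b_u <- brightness(pairs[[i]]$uniform)
    for (j in seq_along(etas)) {
      p2 <- params
      p2$eta <- etas[j]
      rec <- hilo_reconstruct(pairs[[i]], p2)
      if (any(rec != 0)) any_signal <- TRUE
      sed[i, j] <- se_dct(rec)
      bri[i, j] <- brightness(rec)
      bmatch[i, j] <- if (b_u <= 0 || bri[i, j] <= 0) 0 else
        min(bri[i, j] / b_u, b_u / bri[i, j])
    }
  }
  if (!any_signal) {
    stop("all reconstructions are identically zero", call. = FALSE)
  }
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) <= 0) rep(1, length(v)) else (v - r[1]) / diff(r)
  }
  score_rows <- t(apply(sed, 1, norm01)) * bmatch
  score <- colMeans(score_rows)
  best <- etas[order(-score, etas)][1]
  attr(best, "scores") <- tibble::tibble(
    eta = etas,
    sedct = colMeans(sed),
    brightness = colMeans(bri),
    brightness_match = colMeans(bmatch),
    score = score
  )
  best
}

#' HiLo reconstruction of a stack
#'
#' Applies [hilo_reconstruct()] plane by plane. When the pairs carry no
#' modulation frequency it is estimated once from the first structured
#' plane. Per-plane failures are re-raised with the plane index.
#'
#' @param stack_pairs list of [reconstruction_pair()] /
#'   [acquire_plane()] objects.
#' @param params a [hilo_params()].
#' @return list of reconstructed image matrices.
#' @export
hilo_stack <- function(stack_pairs, params = hilo_params()) {
  if (inherits(stack_pairs, "cdslm_pair") ||
      inherits(stack_pairs, "cdslm_acquisition")) {
    stack_pairs <- list(stack_pairs)
  }
  if (length(stack_pairs) == 0L) stop("empty stack", call. = FALSE)
  k_fallback <- NULL
  purrr::imap(stack_pairs, function(p, i) {
    tryCatch({
      if (inherits(p, "cdslm_acquisition")) {
        p <- if (is.na(p$modulation_frequency)) {
          if (is.null(k_fallback)) {
            k_fallback <<- estimate_modulation_frequency(
              stack_pairs[[1L]]$structured)$frequency_cyc_per_px
          }
          reconstruction_pair(p$uniform, p$structured, k_fallback)
        } else {
          as_reconstruction_pair(p)
        }
      }
      hilo_reconstruct(p, params)
    }, error = function(e) {
      stop("plane ", i, ": ", conditionMessage(e), call. = FALSE)
    })
  })
}
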