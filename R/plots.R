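#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_histogram
#'   facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a calibration curve
#'
#' Focus offset against sheet position with the interpolated line
#' overlaid on the calibrated points.
#'
#' @param object a `cdslm_calibration`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cdslm_calibration <- function(object, ...) {
  p <- object$points
  zq <- seq(min(p$sheet_z_um), max(p$sheet_z_um), length.out = 200)
  line <- interpolate_calibration(object, zq)
  ggplot(p, aes(x = .data$sheet_z_um, y = .data$focus_offset_um)) +
    geom_line(data = line, colour = "grey50") +
    geom_point(size = 2) +
    labs(x = "sheet position (µm)",
         y = "detection focus offset (µm)",
         title = "Calibration curve") +
    theme_minimal()
}

#' Plot a volumetric scan report
#'
#' Residual defocus and SE-DCT as a function of depth.
#'
#' @param object a `cdslm_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cdslm_scan <- function(object, ...) {
  r <- object$report
  long <- dplyr::bind_rows(
    tibble::tibble(sheet_z_um = r$sheet_z_um, metric = "residual (µm)",
                   value = r$residual_um),
    tibble::tibble(sheet_z_um = r$sheet_z_um, metric = "SE-DCT (bits)",
                   value = r$sedct)
  )
  ggplot(long, aes(x = .data$sheet_z_um, y = .data$value)) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "depth (µm)", y = NULL,
         title = paste0("Scan report (", object$mode, " mode)")) +
    theme_minimal()
}

#' Plot a chord-length population
#'
#' Histogram of airspace chord lengths by line axis.
#'
#' @param object a `cdslm_mli`.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cdslm_mli <- function(object, bins = 30, ...) {
  ggplot(object$chords_um, aes(x = .data$chord_um, fill = .data$axis)) +
    geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    labs(x = "chord length (µm)", y = "count",
         title = sprintf("Mean linear intercept: L_m = %.1f µm (SD %.1f)",
                         object$lm_um, object$sd_um)) +
    theme_minimal()
}

#' Plot detected object sizes
#'
#' Histogram of connected-object sizes with the single-cell size range.
#'
#' @param object a `cdslm_cell_counts`.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cdslm_cell_counts <- function(object, bins = 30, ...) {
  ggplot(object$object_sizes, aes(x = .data$size_px)) +
    geom_histogram(bins = bins) +
    labs(x = "object size (px)", y = "count",
         title = sprintf("%d cells in %d objects (%d multi-cellular)",
                         object$count, nrow(object$object_sizes),
                         object$multi_cell_splits)) +
    theme_minimal()
}
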