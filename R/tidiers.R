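#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a calibration curve
#'
#' @param x a `cdslm_calibration`.
#' @param ... unused.
#' @return the calibration points as a tibble (`sheet_z_um`,
#'   `focus_offset_um`, `etl1_low_um`, `etl1_high_um`).
#' @export
tidy.cdslm_calibration <- function(x, ...) x$points

#' @rdname tidy.cdslm_calibration
#' @return for `glance()`: a one-row tibble summarising the curve.
#' @export
glance.cdslm_calibration <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$points),
    z_min_um = min(x$points$sheet_z_um),
    z_max_um = max(x$points$sheet_z_um),
    offset_min_um = min(x$points$focus_offset_um),
    offset_max_um = max(x$points$focus_offset_um),
    interpolation_step_um = x$interpolation_step_um
  )
}

#' Tidy a volumetric scan
#'
#' @param x a `cdslm_scan`.
#' @param ... unused.
#' @return the per-plane report tibble (`plane`, `sheet_z_um`,
#'   `applied_offset_um`, `true_offset_um`, `residual_um`, `sedct`).
#' @export
tidy.cdslm_scan <- function(x, ...) x$report

#' @rdname tidy.cdslm_scan
#' @return for `glance()`: a one-row summary of the scan.
#' @export
glance.cdslm_scan <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_planes = nrow(x$report),
    mean_residual_um = mean(x$report$residual_um),
    max_residual_um = max(x$report$residual_um),
    mean_sedct = mean(x$report$sedct)
  )
}

#' Tidy a mean-linear-intercept result
#'
#' @param x a `cdslm_mli`.
#' @param ... unused.
#' @return the chord population tibble (`axis`, `chord_um`).
#' @export
tidy.cdslm_mli <- function(x, ...) x$chords_um

#' @rdname tidy.cdslm_mli
#' @return for `glance()`: a one-row tibble with `lm_um`, `sd_um`,
#'   `n_chords`, `n_lines`.
#' @export
glance.cdslm_mli <- function(x, ...) {
  tibble::tibble(lm_um = x$lm_um, sd_um = x$sd_um,
                 n_chords = x$n_chords, n_lines = x$n_lines)
}

#' Tidy a cell-count result
#'
#' @param x a `cdslm_cell_counts`.
#' @param ... unused.
#' @return the per-object tibble (`label`, `size_px`, `cells`).
#' @export
tidy.cdslm_cell_counts <- function(x, ...) x$object_sizes

#' @rdname tidy.cdslm_cell_counts
#' @return for `glance()`: a one-row tibble with `count`, `n_objects`,
#'   `multi_cell_splits`, `threshold`.
#' @export
glance.cdslm_cell_counts <- function(x, ...) {
  tibble::tibble(count = x$count, n_objects = nrow(x$object_sizes),
                 multi_cell_splits = x$multi_cell_splits,
                 threshold = x$threshold)
}
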