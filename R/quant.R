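#' Sampling-line grid specification
#'
#' Lattice of axis-aligned sample lines for mean-linear-intercept
#' measurements: lines run along each requested axis, placed every
#' `spacing_px` voxels in the orthogonal directions.
#'
#' @param spacing_px distance between parallel lines, voxels (>= 1).
#' @param axes non-empty subset of `c("x", "y", "z")`.
#' @param offset_px lattice offset, voxels (>= 0).
#' @return an object of class `cdslm_grid`.
#' @export
grid_spec <- function(spacing_px = 1L, axes = c("x", "y"), offset_px = 0L) {
  spacing_px <- as.integer(spacing_px)
  offset_px <- as.integer(offset_px)
  if (spacing_px < 1L) stop("`spacing_px` must be >= 1", call. = FALSE)
  if (offset_px < 0L) stop("`offset_px` must be >= 0", call. = FALSE)
  axes <- unique(match.arg(axes, c("x", "y", "z"), several.ok = TRUE))
  structure(list(spacing_px = spacing_px, axes = axes, offset_px = offset_px),
            class = "cdslm_grid")
}

# axis -> array dimension index. 2D matrices are (y, x); 3D arrays (z, y, x).
axis_dim <- function(axis, ndim) {
  if (ndim == 2L) {
    switch(axis, y = 1L, x = 2L,
           stop("axis `z` is undefined for 2D inputs", call. = FALSE))
  } else {
    switch(axis, z = 1L, y = 2L, x = 3L)
  }
}

# Chords of one 1-D line: maximal air runs fully inside the region,
# bounded on both ends by tissue that is itself inside the region.
line_chords <- function(air, reg) {
  state <- ifelse(!reg, 0L, ifelse(air, 1L, 2L))
  r <- rle(state)
  n <- length(r$values)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  keep <- i[r$values[i] == 1L & r$values[i - 1L] == 2L & r$values[i + 1L] == 2L]
  r$lengths[keep]
}

#' Airspace chords along a line grid
#'
#' Extracts, for every lattice line of the grid, the maximal runs of
#' airspace voxels that lie wholly inside the region mask and are bounded
#' on both ends by in-region tissue. Runs touching the image border or
#' the region border are discarded (uncensored chords only). Chord
#' lengths are reported in micrometres using the voxel size along each
#' line's axis.
#'
#' @param mask logical matrix `(y, x)` or array `(z, y, x)`; TRUE =
#'   airspace.
#' @param region_mask same shape; TRUE = inside the specimen. NULL means
#'   the whole image.
#' @param grid a [grid_spec()].
#' @param voxel_size_um voxel edge lengths `c(x, y, z)` (scalar recycled),
#'   micrometres.
#' @return a tibble with columns `axis` and `chord_um`, with the number
#'   of lines visited in attribute `"n_lines"`.
#' @export
chords_along_lines <- function(mask, region_mask = NULL, grid = grid_spec(),
                               voxel_size_um = 1) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% 2:3)) {
    stop("`mask` must be a 2D matrix or 3D array", call. = FALSE)
  }
  region_mask <- region_mask %||% array(TRUE, d)
  if (!identical(dim(region_mask), d)) {
    stop("`region_mask` must match the mask shape", call. = FALSE)
  }
  if (!any(region_mask)) stop("empty region", call. = FALSE)
  ndim <- length(d)
  vox <- rep_len(voxel_size_um, 3L)
  names(vox) <- c("x", "y", "z")
  out <- list()
  n_lines <- 0L
  for (axis in grid$axes) {
    ad <- axis_dim(axis, ndim)
    odims <- setdiff(seq_len(ndim), ad)
    pos <- lapply(odims, function(k) seq(1L + grid$offset_px, d[k],
                                         by = grid$spacing_px))
    combos <- expand.grid(pos, KEEP.OUT.ATTRS = FALSE)
    chords <- integer(0)
    for (r in seq_len(nrow(combos))) {
      idx <- vector("list", ndim)
      idx[[ad]] <- seq_len(d[ad])
      for (j in seq_along(odims)) idx[[odims[j]]] <- combos[r, j]
      air <- do.call(`[`, c(list(mask), idx))
      reg <- do.call(`[`, c(list(region_mask), idx))
      chords <- c(chords, line_chords(as.logical(air), as.logical(reg)))
      n_lines <- n_lines + 1L
    }
    if (length(chords)) {
      out[[axis]] <- tibble::tibble(axis = axis,
                                    chord_um = chords * vox[[axis]])
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(axis = character(0), chord_um = numeric(0))
  attr(res, "n_lines") <- n_lines
  res
}

new_mli_result <- function(chords, n_lines) {
  if (nrow(chords) == 0L) {
    stop("no tissue-bounded chords found", call. = FALSE)
  }
  per_axis <- chords |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(lm_um = mean(.data$chord_um),
                     sd_um = sd(.data$chord_um),
                     n_chords = dplyr::n(), .groups = "drop")
  structure(
    list(chords_um = chords,
         lm_um = mean(chords$chord_um),
         sd_um = sd(chords$chord_um),
         n_chords = nrow(chords),
         n_lines = n_lines,
         per_axis = per_axis),
    class = "cdslm_mli"
  )
}

#' Two-dimensional mean linear intercept
#'
#' Classic planar MLI: pools airspace chords from evenly spaced
#' horizontal and vertical line families over a 2D section and reports
#' the mean chord length L_m with its SD.
#'
#' @param mask logical matrix, TRUE = airspace.
#' @param region_mask logical matrix, TRUE = inside the specimen
#'   (NULL = everywhere).
#' @param grid_spacing_px spacing of the line lattice, voxels.
#' @param voxel_size_um pixel size, micrometres.
#' @param offset_px lattice offset, voxels.
#' @return an object of class `cdslm_mli`: chord population, `lm_um`,
#'   `sd_um`, `n_chords`, `n_lines` and a per-axis summary.
#' @export
mli_2d <- function(mask, region_mask = NULL, grid_spacing_px = 1L,
                   voxel_size_um = 1, offset_px = 0L) {
  if (!is.matrix(mask)) stop("`mask` must be a 2D matrix", call. = FALSE)
  g <- grid_spec(grid_spacing_px, axes = c("x", "y"), offset_px = offset_px)
  ch <- chords_along_lines(mask, region_mask, g, voxel_size_um)
  new_mli_result(ch, attr(ch, "n_lines"))
}

#' Three-dimensional mean linear intercept
#'
#' Volumetric MLI: imposes a 3D lattice of axis-aligned lines (any subset
#' of the x, y, z families) over a volume mask, pools the chords across
#' all families for L_m, and retains per-axis sub-results for anisotropy
#' inspection.
#'
#' @param volume_mask logical array `(z, y, x)`, TRUE = airspace.
#' @param region_mask logical array, TRUE = inside the specimen
#'   (NULL = everywhere).
#' @param grid a [grid_spec()] (use `axes = c("x","y","z")` for the full
#'   volumetric grid).
#' @param voxel_size_um voxel edge lengths `c(x, y, z)`, micrometres.
#' @return an object of class `cdslm_mli`.
#' @export
mli_3d <- function(volume_mask, region_mask = NULL,
                   grid = grid_spec(axes = c("x", "y", "z")),
                   voxel_size_um = 1) {
  if (length(dim(volume_mask)) != 3L) {
    stop("`volume_mask` must be a 3D array", call. = FALSE)
  }
  ch <- chords_along_lines(volume_mask, region_mask, grid, voxel_size_um)
  new_mli_result(ch, attr(ch, "n_lines"))
}

#' @export
print.cdslm_mli <- function(x, ...) {
  cat("<cdslm_mli> L_m = ", signif(x$lm_um, 6), " um (SD ",
      signif(x$sd_um, 6), "), ", x$n_chords, " chords on ", x$n_lines,
      " lines\n", sep = "")
  invisible(x)
}

#' Label connected components
#'
#' Connected-component labelling of a logical mask with selectable
#' connectivity: 4/8 neighbours in 2D, 6/26 in 3D (built on an igraph
#' adjacency decomposition).
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4 or 8 (2D); 6 or 26 (3D).
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  ndim <- length(d)
  if (!(ndim %in% 2:3)) stop("`mask` must be 2D or 3D", call. = FALSE)
  connectivity <- connectivity %||% if (ndim == 2L) 8L else 26L
  offsets <- if (ndim == 2L) {
    if (connectivity == 4L) list(c(0, 1), c(1, 0))
    else if (connectivity == 8L) list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    else stop("2D connectivity must be 4 or 8", call. = FALSE)
  } else {
    if (connectivity == 6L) list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    else if (connectivity == 26L) {
      all_o <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
      all_o <- all_o[!(all_o$dz == 0 & all_o$dy == 0 & all_o$dx == 0), ]
      # keep one of each +/- pair (lexicographically positive)
      keep <- all_o$dz > 0 | (all_o$dz == 0 & (all_o$dy > 0 |
                (all_o$dy == 0 & all_o$dx > 0)))
      lapply(which(keep), function(i) as.numeric(all_o[i, ]))
    } else stop("3D connectivity must be 6 or 26", call. = FALSE)
  }
  ids <- array(0L, d)
  n_fg <- sum(mask)
  if (n_fg == 0L) return(ids)
  ids[mask] <- seq_len(n_fg)
  edges <- list()
  for (off in offsets) {
    src <- lapply(seq_len(ndim), function(k) {
      if (off[k] >= 0) seq_len(d[k] - off[k]) else seq(1 - off[k], d[k])
    })
    dst <- lapply(seq_len(ndim), function(k) src[[k]] + off[k])
    a <- do.call(`[`, c(list(ids), src, list(drop = FALSE)))
    b <- do.call(`[`, c(list(ids), dst, list(drop = FALSE)))
    both <- a > 0L & b > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- rbind(a[both], b[both])
  }
  memb <- if (length(edges)) {
    e <- do.call(cbind, edges)
    g <- igraph::graph_from_edgelist(t(e), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_fg - igraph::vcount(g)))
    igraph::components(g)$membership
  } else {
    seq_len(n_fg)
  }
  out <- array(0L, d)
  out[mask] <- as.integer(memb)
  out
}

#' Cell-counting configuration
#'
#' @param background_sigma_px sigma of the Gaussian background estimate
#'   subtracted before thresholding (0 disables; default 10x an expected
#'   cell diameter is sensible).
#' @param threshold user-defined positive-pixel cutoff applied to the
#'   background-subtracted image.
#' @param size_range_px object size range `c(min, max)` (pixels 2D /
#'   voxels 3D) accepted as a single cell body; `min < max`.
#' @param connectivity component connectivity: 8 (2D) / 26 (3D) by
#'   default.
#' @return an object of class `cdslm_count_config`.
#' @export
cell_count_config <- function(background_sigma_px = 50, threshold,
                              size_range_px = c(20, 200),
                              connectivity = NULL) {
  if (!is_scalar_number(background_sigma_px) || background_sigma_px < 0) {
    stop("`background_sigma_px` must be non-negative", call. = FALSE)
  }
  if (!is_scalar_number(threshold)) stop("`threshold` must be a number", call. = FALSE)
  if (length(size_range_px) != 2L || size_range_px[1] >= size_range_px[2]) {
    stop("`size_range_px` must satisfy min < max", call. = FALSE)
  }
  structure(list(background_sigma_px = background_sigma_px,
                 threshold = threshold,
                 size_range_px = size_range_px,
                 connectivity = connectivity),
            class = "cdslm_count_config")
}

#' Count fluorescent cells
#'
#' Subtracts a Gaussian-smoothed background, thresholds positive pixels,
#' labels connected components, and counts: objects whose size falls in
#' the configured single-cell range count as one cell; larger objects are
#' treated as multi-cellular and count as `round(size / median
#' single-cell size)` (at least 1), the median taken over the in-range
#' objects; smaller objects are discarded. If only oversize objects are
#' present the single-cell size cannot be estimated and an error is
#' raised.
#'
#' @param image numeric matrix (2D) or array (3D).
#' @param cfg a [cell_count_config()].
#' @return an object of class `cdslm_cell_counts`: list with `count`,
#'   `object_sizes` (tibble: label, size_px, cells),
#'   `multi_cell_splits`, and the threshold used.
#' @export
count_cells <- function(image, cfg) {
  stopifnot(inherits(cfg, "cdslm_count_config"))
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% 2:3)) {
    stop("`image` must be 2D or 3D", call. = FALSE)
  }
  if (cfg$threshold > max(image) || cfg$threshold < min(image) - diff(range(image))) {
    warning("threshold lies outside the image dynamic range", call. = FALSE)
  }
  work <- image
  if (cfg$background_sigma_px > 0) {
    work <- image - gaussian_blur(image, cfg$background_sigma_px)
  }
  pos <- work > cfg$threshold
  lab <- label_components(pos, cfg$connectivity)
  n_obj <- max(lab)
  if (n_obj == 0L) {
    return(structure(list(count = 0L,
                          object_sizes = tibble::tibble(label = integer(0),
                                                        size_px = integer(0),
                                                        cells = integer(0)),
                          multi_cell_splits = 0L,
                          threshold = cfg$threshold),
                     class = "cdslm_cell_counts"))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = n_obj)
  lo <- cfg$size_range_px[1]; hi <- cfg$size_range_px[2]
  in_range <- which(sizes >= lo & sizes <= hi)
  over <- which(sizes > hi)
  keep <- c(in_range, over)
  if (length(in_range) == 0L && length(over) > 0L) {
    stop("cannot estimate single-cell size: no in-range objects but ",
         length(over), " oversize object(s)", call. = FALSE)
  }
  med <- if (length(in_range)) median(sizes[in_range]) else NA_real_
  cells <- integer(length(keep))
  cells[seq_along(in_range)] <- 1L
  if (length(over)) {
    cells[seq_along(over) + length(in_range)] <-
      pmax(1L, as.integer(round(sizes[over] / med)))
  }
  ord <- order(keep)
  tab <- tibble::tibble(label = keep[ord], size_px = sizes[keep][ord],
                        cells = cells[ord])
  structure(list(count = sum(tab$cells),
                 object_sizes = tab,
                 multi_cell_splits = sum(tab$cells > 1L),
                 threshold = cfg$threshold),
            class = "cdslm_cell_counts")
}

#' @export
print.cdslm_cell_counts <- function(x, ...) {
  cat("<cdslm_cell_counts> ", x$count, " cells in ", nrow(x$object_sizes),
      " objects (", x$multi_cell_splits, " multi-cellular)\n", sep = "")
  invisible(x)
}
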