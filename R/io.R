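#' Stack metadata
#'
#' Plain-text sidecar metadata accompanying every written stack: voxel
#' geometry, axial step, modulation period, seed and scan mode.
#'
#' @param voxel_size_um voxel edge lengths `c(x, y, z)`, micrometres.
#' @param axial_step_um axial step between planes, micrometres.
#' @param modulation_period_um HiLo pattern period, micrometres (NA when
#'   unmodulated).
#' @param seed integer acquisition seed (NA if none).
#' @param scan_mode `"cdslm"`, `"standard"` or NA.
#' @param notes free-text provenance notes.
#' @return a named list of class `cdslm_metadata`.
#' @export
stack_metadata <- function(voxel_size_um = c(1, 1, 1), axial_step_um = 1,
                           modulation_period_um = NA_real_, seed = NA_integer_,
                           scan_mode = NA_character_, notes = "") {
  voxel_size_um <- rep_len(voxel_size_um, 3L)
  if (any(voxel_size_um <= 0) || axial_step_um <= 0) {
    stop("geometry values must be positive", call. = FALSE)
  }
  if (!is.na(scan_mode) && !scan_mode %in% c("cdslm", "standard")) {
    stop("`scan_mode` must be \"cdslm\" or \"standard\"", call. = FALSE)
  }
  structure(list(voxel_size_x_um = voxel_size_um[1],
                 voxel_size_y_um = voxel_size_um[2],
                 voxel_size_z_um = voxel_size_um[3],
                 axial_step_um = axial_step_um,
                 modulation_period_um = modulation_period_um,
                 seed = seed, scan_mode = scan_mode, notes = notes),
            class = "cdslm_metadata")
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.txt")

write_keyvalue <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    paste0(k, "=", if (is.null(v) || length(v) == 0L) "" else as.character(v)[1])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) != 2L) next
    key <- trimws(p[1]); val <- trimws(p[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num) || val %in% c("NA", "NaN")) num else val
  }
  out
}

#' Write / read configuration files
#'
#' Flat `key=value` plain-text configuration; numeric-looking values are
#' coerced to numbers on read.
#'
#' @param config named list.
#' @param path file path.
#' @return `write_config()` returns the path invisibly; `read_config()` a
#'   named list.
#' @export
write_config <- function(config, path) write_keyvalue(config, path)

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  read_keyvalue(path)
}

#' Write an image stack as multi-page TIFF
#'
#' Writes a `(z, y, x)` array (or list of `(y, x)` matrices) as an
#' uncompressed little-endian multi-page TIFF plus a plain-text
#' `key=value` sidecar. `dtype = "uint16"` stores rounded integer counts
#' in 0..65535 bit-exactly; `dtype = "float32"` min-max normalises to
#' 32-bit storage and records `data_min` / `data_max` in the sidecar so
#' the values are restored on read (within 32-bit representation).
#'
#' @param stack numeric 3D array `(z, y, x)` or list of matrices.
#' @param path output `.tif` path.
#' @param metadata a [stack_metadata()] (or named list merged over its
#'   defaults).
#' @param dtype `"uint16"` or `"float32"`.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path, metadata = stack_metadata(),
                        dtype = c("uint16", "float32")) {
  dtype <- match.arg(dtype)
  if (is.list(stack)) {
    pages <- stack
  } else if (is.array(stack) && length(dim(stack)) == 3L) {
    pages <- purrr::map(seq_len(dim(stack)[1]), function(k) stack[k, , ])
  } else if (is.matrix(stack)) {
    pages <- list(stack)
  } else {
    stop("`stack` must be a (z, y, x) array, matrix, or list of matrices",
         call. = FALSE)
  }
  if (!inherits(metadata, "cdslm_metadata")) {
    metadata <- do.call(stack_metadata, metadata)
  }
  meta <- unclass(metadata)
  meta$dtype <- dtype
  meta$n_pages <- length(pages)
  if (dtype == "uint16") {
    pages <- purrr::map(pages, function(p) {
      q <- round(p)
      if (any(q < 0) || any(q > 65535)) {
        stop("uint16 stacks require values in 0..65535 after rounding",
             call. = FALSE)
      }
      q / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    rng <- range(unlist(purrr::map(pages, range)))
    span <- diff(rng)
    meta$data_min <- rng[1]
    meta$data_max <- rng[2]
    pages <- purrr::map(pages, function(p) {
      if (span > 0) (p - rng[1]) / span else p * 0
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  write_keyvalue(meta, sidecar_path(path))
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path `.tif` path.
#' @return list with `stack` (numeric `(z, y, x)` array) and `metadata`
#'   (named list). A missing sidecar yields default metadata with a
#'   warning.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("stack not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop("malformed TIFF `", path, "`: ", conditionMessage(e),
                           call. = FALSE)
                    })
  if (is.matrix(pages)) pages <- list(pages)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- read_keyvalue(sp)
  } else {
    warning("missing sidecar metadata for ", path, "; using defaults",
            call. = FALSE)
    meta <- c(unclass(stack_metadata()), list(dtype = "uint16"))
  }
  dtype <- meta$dtype %||% "uint16"
  pages <- purrr::map(pages, function(p) {
    if (identical(dtype, "uint16")) {
      round(p * 65535)
    } else {
      mn <- meta$data_min %||% 0
      mx <- meta$data_max %||% 1
      mn + p * (mx - mn)
    }
  })
  d <- dim(pages[[1]])
  stack <- array(0, c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) stack[k, , ] <- pages[[k]]
  list(stack = stack, metadata = meta)
}

#' Tiled-acquisition layout
#'
#' Regular tile grid with fractional overlap: tile origins advance by
#' `tile_size_um * (1 - overlap_fraction)` in each in-plane direction.
#'
#' @param grid_rows,grid_cols tile grid dimensions.
#' @param tile_size_um in-plane tile extent `c(v, h)`, micrometres
#'   (scalar recycled).
#' @param overlap_fraction fractional overlap in `[0, 1)` (typically
#'   0.20–0.30).
#' @return an object of class `cdslm_tile_layout` whose `tiles` tibble
#'   holds per-tile row, col and origin coordinates in micrometres.
#' @export
tile_layout <- function(grid_rows, grid_cols, tile_size_um = 1300,
                        overlap_fraction = 0.25) {
  if (grid_rows < 1L || grid_cols < 1L) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must lie in [0, 1)", call. = FALSE)
  }
  tile_size_um <- rep_len(tile_size_um, 2L)
  stride <- tile_size_um * (1 - overlap_fraction)
  tiles <- expand.grid(row = seq_len(grid_rows) - 1L,
                       col = seq_len(grid_cols) - 1L)
  tiles <- tibble::as_tibble(tiles[order(tiles$row, tiles$col), ])
  tiles$origin_v_um <- tiles$row * stride[1]
  tiles$origin_h_um <- tiles$col * stride[2]
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 tile_size_um = tile_size_um,
                 overlap_fraction = overlap_fraction,
                 tiles = tiles),
            class = "cdslm_tile_layout")
}

coord_token <- function(um) sprintf("%06d", as.integer(round(um * 10)))

#' Write tiles in the TeraStitcher two-level directory convention
#'
#' Lays the tiles out as `root/V/V_H/V_H_D.tif` where V, H and D are the
#' vertical, horizontal and axial origin coordinates in tenths of
#' micrometres, zero-padded to six digits — the classic two-level volume
#' layout TeraStitcher ingests directly.
#'
#' @param tiles list of stacks (arrays or lists of matrices), row-major
#'   over the tile grid.
#' @param layout a [tile_layout()] consistent with `length(tiles)`.
#' @param root output directory (created if needed).
#' @param metadata a [stack_metadata()] applied to every tile.
#' @param depth_origin_um axial origin D of the stacks, micrometres.
#' @return tibble manifest of the files written, invisibly.
#' @export
write_terastitcher_layout <- function(tiles, layout, root,
                                      metadata = stack_metadata(),
                                      depth_origin_um = 0) {
  stopifnot(inherits(layout, "cdslm_tile_layout"))
  tl <- layout$tiles
  if (length(tiles) != nrow(tl)) {
    stop("need exactly one tile per layout position", call. = FALSE)
  }
  shapes <- purrr::map(tiles, function(t) {
    if (is.list(t)) dim(t[[1]]) else dim(t)[-1]
  })
  if (length(unique(purrr::map_chr(shapes, paste, collapse = "x"))) > 1L) {
    stop("all tiles must share one shape", call. = FALSE)
  }
  v_tok <- coord_token(tl$origin_v_um)
  h_tok <- coord_token(tl$origin_h_um)
  d_tok <- coord_token(depth_origin_um)
  key <- paste(v_tok, h_tok, sep = "_")
  if (anyDuplicated(key)) stop("tile coordinate collision", call. = FALSE)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(tiles))
  for (i in seq_along(tiles)) {
    dir2 <- file.path(root, v_tok[i], paste0(v_tok[i], "_", h_tok[i]))
    dir.create(dir2, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(dir2, paste0(v_tok[i], "_", h_tok[i], "_", d_tok, ".tif"))
    write_stack(tiles[[i]], paths[i], metadata = metadata, dtype = "uint16")
  }
  invisible(tibble::tibble(row = tl$row, col = tl$col,
                           origin_v_um = tl$origin_v_um,
                           origin_h_um = tl$origin_h_um, path = paths))
}

#' Validate a TeraStitcher two-level layout
#'
#' Structural check of the directory convention written by
#' [write_terastitcher_layout()]: six-digit folder names, `V_H`
#' second-level names whose V matches the parent, `V_H_D.tif` file names
#' whose prefix matches the folder, and strictly increasing distinct
#' coordinates at each level.
#'
#' @param root layout root directory.
#' @return TRUE if the layout conforms, FALSE otherwise, with the
#'   problems recorded in attribute `"problems"`.
#' @export
validate_terastitcher_layout <- function(root) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  if (!dir.exists(root)) {
    note("root does not exist: ", root)
  } else {
    l1 <- list.dirs(root, recursive = FALSE, full.names = FALSE)
    if (length(l1) == 0L) note("no first-level row folders")
    bad1 <- l1[!grepl("^\\d{6}$", l1)]
    if (length(bad1)) note("bad row folder name(s): ", paste(bad1, collapse = ", "))
    good1 <- setdiff(l1, bad1)
    if (anyDuplicated(good1)) note("duplicate row coordinates")
    for (v in good1) {
      l2 <- list.dirs(file.path(root, v), recursive = FALSE, full.names = FALSE)
      if (length(l2) == 0L) note("row ", v, " has no column folders")
      ok2 <- grepl("^\\d{6}_\\d{6}$", l2) & startsWith(l2, paste0(v, "_"))
      if (any(!ok2)) note("bad column folder(s) under ", v, ": ",
                          paste(l2[!ok2], collapse = ", "))
      h_coords <- sub("^\\d{6}_", "", l2[ok2])
      if (anyDuplicated(h_coords)) note("duplicate column coordinates under ", v)
      for (vh in l2[ok2]) {
        fl <- list.files(file.path(root, v, vh), pattern = "\\.tif$")
        if (length(fl) == 0L) note("no TIFF in ", vh)
        okf <- grepl("^\\d{6}_\\d{6}_\\d{6}\\.tif$", fl) &
          startsWith(fl, paste0(vh, "_"))
        if (any(!okf)) note("bad tile file name(s) in ", vh, ": ",
                            paste(fl[!okf], collapse = ", "))
      }
    }
  }
  out <- length(problems) == 0L
  attr(out, "problems") <- problems
  out
}
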