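# Seeded specimen phantoms: beads, fibers and alveolar foam. All return
# specimen_volume() objects on the (z, y, x) axis convention.

check_shape <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L)) {
    stop("`shape` must be three positive integers (nz, ny, nx)", call. = FALSE)
  }
  shape
}

# Accumulate point impulses at (fractional) voxel-space centres (z, y, x)
# into a zero array by nearest-voxel binning; out-of-grid points are
# dropped. One Gaussian blur then turns impulses into blobs/tubes.
deposit_impulses <- function(shape, centres, value = 1) {
  k <- round(centres)
  ok <- k[, 1] >= 1 & k[, 1] <= shape[1] &
    k[, 2] >= 1 & k[, 2] <= shape[2] &
    k[, 3] >= 1 & k[, 3] <= shape[3]
  k <- k[ok, , drop = FALSE]
  lin <- k[, 1] + (k[, 2] - 1) * shape[1] + (k[, 3] - 1) * shape[1] * shape[2]
  den <- array(0, shape)
  if (nrow(k)) {
    counts <- tabulate(lin, nbins = prod(shape))
    den[counts > 0] <- counts[counts > 0] * value
  }
  den
}

# Peak of the separable discrete Gaussian kernel with per-axis sigma
# (voxels); used to convert impulse weights into blob peak amplitudes.
kernel_peak <- function(sig_vox) {
  prod(vapply(sig_vox, function(s) max(gaussian_kernel(s)), numeric(1)))
}

#' Bead phantom
#'
#' Fluorescent microsphere phantom: `n_beads` Gaussian beads at uniform
#' random positions.
#'
#' @param n_beads number of beads (0 gives an all-zero volume).
#' @param shape grid size `c(nz, ny, nx)` in voxels.
#' @param voxel_size_um voxel edge lengths `c(x, y, z)`, micrometres.
#' @param seed integer seed; the same seed reproduces the volume exactly.
#' @param bead_sigma_um Gaussian radius of a bead, micrometres.
#' @param amplitude peak density of one bead (arbitrary fluorophore units;
#'   expected photon counts in the simulator are this integrated along z).
#' @return a [specimen_volume()].
#' @export
make_bead_volume <- function(n_beads, shape, voxel_size_um = c(2, 2, 2),
                             seed = 1, bead_sigma_um = 3, amplitude = 400) {
  shape <- check_shape(shape)
  if (!is_scalar_number(n_beads) || n_beads < 0) {
    stop("`n_beads` must be a non-negative count", call. = FALSE)
  }
  voxel_size_um <- rep_len(voxel_size_um, 3L)
  r_vox <- pmax(bead_sigma_um / voxel_size_um[c(3, 2, 1)], 0.3)  # (z, y, x)
  den <- array(0, shape)
  if (n_beads > 0) {
    ctrs <- with_seed(seed, cbind(runif(n_beads, 1, shape[1]),
                                  runif(n_beads, 1, shape[2]),
                                  runif(n_beads, 1, shape[3])))
    den <- deposit_impulses(shape, ctrs, amplitude / kernel_peak(r_vox))
    den <- gaussian_blur(den, r_vox)
  }
  specimen_volume(den, voxel_size_um)
}

#' Fiber phantom
#'
#' Straight fluorescent fibers (myelin-track-like tubes) with random
#' positions and orientations, painted as max-combined Gaussian tubes.
#'
#' @param n_fibers number of fibers.
#' @inheritParams make_bead_volume
#' @param fiber_sigma_um Gaussian radius of the fiber cross-section,
#'   micrometres.
#' @return a [specimen_volume()].
#' @export
make_fiber_volume <- function(n_fibers, shape, voxel_size_um = c(2, 2, 2),
                              seed = 1, fiber_sigma_um = 2, amplitude = 400) {
  shape <- check_shape(shape)
  if (!is_scalar_number(n_fibers) || n_fibers < 0) {
    stop("`n_fibers` must be a non-negative count", call. = FALSE)
  }
  voxel_size_um <- rep_len(voxel_size_um, 3L)
  r_vox <- pmax(fiber_sigma_um / voxel_size_um[c(3, 2, 1)], 0.3)
  den <- array(0, shape)
  if (n_fibers > 0) {
    pts <- with_seed(seed, {
      acc <- list()
      for (f in seq_len(n_fibers)) {
        p0 <- c(runif(1, 1, shape[1]), runif(1, 1, shape[2]), runif(1, 1, shape[3]))
        v <- rnorm(3); v <- v / sqrt(sum(v^2))
        span <- sum(abs(v) * shape)  # generous traversal length
        t <- seq(-span, span, by = 0.5)
        acc[[f]] <- cbind(p0[1] + t * v[1], p0[2] + t * v[2], p0[3] + t * v[3])
      }
      do.call(rbind, acc)
    })
    den <- gaussian_blur(deposit_impulses(shape, pts), r_vox)
    mx <- max(den)
    if (mx > 0) den <- den * (amplitude / mx)
  }
  specimen_volume(den, voxel_size_um)
}

#' Alveolar foam phantom
#'
#' Emulates distal-lung airspaces: a binary air mask whose complement
#' (the tissue walls) carries the fluorophore density. `geometry =
#' "random"` thresholds a smoothed Gaussian random field so that the
#' characteristic airspace diameter scales with `mean_airspace_um`;
#' `geometry = "slab"` builds parallel air gaps of exactly
#' `round(mean_airspace_um / voxel)` voxels separated by walls of
#' `round(wall_um / voxel)` voxels along `slab_axis` (exact ground truth
#' for chord-length checks). The returned air mask is the exact mask the
#' density was built from.
#'
#' @inheritParams make_bead_volume
#' @param mean_airspace_um target mean airspace size, micrometres.
#' @param wall_um tissue wall thickness (slab geometry), micrometres.
#' @param geometry `"random"` or `"slab"`.
#' @param air_fraction air volume fraction for the random geometry.
#' @param slab_axis axis of the slab normal: `"z"`, `"y"` or `"x"`.
#' @param amplitude wall fluorophore density.
#' @return list with elements `volume` (a [specimen_volume()]) and
#'   `air_mask` (logical array, TRUE = airspace).
#' @export
make_foam_volume <- function(shape, mean_airspace_um = 60, wall_um = 10,
                             voxel_size_um = c(2, 2, 2), seed = 1,
                             geometry = c("random", "slab"),
                             air_fraction = 0.6, slab_axis = "z",
                             amplitude = 400) {
  shape <- check_shape(shape)
  geometry <- match.arg(geometry)
  voxel_size_um <- rep_len(voxel_size_um, 3L)
  assert_positive(mean_airspace_um, "mean_airspace_um")
  assert_positive(wall_um, "wall_um")
  vox_zyx <- voxel_size_um[c(3, 2, 1)]
  if (geometry == "slab") {
    ax <- match(slab_axis, c("z", "y", "x"))
    if (is.na(ax)) stop("`slab_axis` must be one of z, y, x", call. = FALSE)
    gap <- max(1L, round(mean_airspace_um / vox_zyx[ax]))
    wall <- max(1L, round(wall_um / vox_zyx[ax]))
    period <- gap + wall
    # Start with a wall so air runs are tissue-bounded away from borders.
    pos <- seq_len(shape[ax]) - 1L
    line_air <- (pos %% period) >= wall
    air <- array(FALSE, shape)
    perm <- c(ax, setdiff(1:3, ax))
    airp <- array(rep(line_air, times = prod(shape[perm[2:3]])),
                  dim = shape[perm])
    air <- aperm(airp, order(perm))
  } else {
    sig_vox <- pmax(mean_airspace_um / 4 / vox_zyx, 0.5)
    field <- with_seed(seed, array(rnorm(prod(shape)), shape))
    field <- gaussian_blur(field, sig_vox)
    thr <- quantile(field, 1 - air_fraction)
    air <- field > thr
  }
  den <- array(0, shape)
  den[!air] <- amplitude
  list(volume = specimen_volume(den, voxel_size_um), air_mask = air)
}
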