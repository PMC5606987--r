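#' @importFrom rlang %||% .data
#' @importFrom stats approx fft median mvfft quantile rnorm rpois runif sd
#' @importFrom utils modifyList read.csv write.csv
NULL

# Half-sample symmetric reflection of 1-based indices into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p  # 0-based, period 2n
  ifelse(j < n, j + 1L, p - j)
}

gaussian_kernel <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  radius <- radius %||% max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k / sum(k)
}

# Dense band matrix K (n x n) such that K %*% x convolves x with `kernel`.
# boundary "reflect": half-sample symmetric padding (intensity-preserving);
# boundary "zero": out-of-range taps are dropped (light leaves the field).
conv_matrix <- function(n, kernel, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (d in -r:r) {
    w <- kernel[d + r + 1L]
    if (boundary == "reflect") {
      j <- reflect_index(idx + d, n)
      K[cbind(idx, j)] <- K[cbind(idx, j)] + w
    } else {
      keep <- idx + d >= 1L & idx + d <= n
      K[cbind(idx[keep], idx[keep] + d)] <-
        K[cbind(idx[keep], idx[keep] + d)] + w
    }
  }
  K
}

#' Gaussian blur with reflective border handling
#'
#' Separable Gaussian convolution of a matrix (or 3D array, blurred along
#' every axis) using half-sample symmetric (reflective) padding. `sigma_px`
#' may be a scalar or one value per array dimension; a value of 0 leaves
#' that axis untouched.
#'
#' @param x numeric matrix or 3D array.
#' @param sigma_px Gaussian standard deviation(s) in pixels.
#' @param boundary `"reflect"` (half-sample symmetric, intensity
#'   preserving; the default used by the reconstruction filters) or
#'   `"zero"` (blurred light leaves the field, as at a detector edge).
#' @return blurred array of the same shape.
#' @export
gaussian_blur <- function(x, sigma_px, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  d <- dim(x)
  if (is.null(d)) stop("`x` must be a matrix or array", call. = FALSE)
  nd <- length(d)
  sigma_px <- rep_len(sigma_px, nd)
  if (nd == 2L) {
    if (sigma_px[1] > 0) {
      k <- gaussian_kernel(sigma_px[1], radius = min(ceiling(3 * sigma_px[1]), d[1] - 1L))
      x <- conv_matrix(d[1], k, boundary) %*% x
    }
    if (sigma_px[2] > 0) {
      k <- gaussian_kernel(sigma_px[2], radius = min(ceiling(3 * sigma_px[2]), d[2] - 1L))
      x <- x %*% t(conv_matrix(d[2], k, boundary))
    }
    return(x)
  }
  if (nd != 3L) stop("`x` must be 2- or 3-dimensional", call. = FALSE)
  for (ax in 1:3) {
    if (sigma_px[ax] <= 0) next
    k <- gaussian_kernel(sigma_px[ax], radius = min(ceiling(3 * sigma_px[ax]), d[ax] - 1L))
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    dm <- dim(xp)
    m <- conv_matrix(dm[1], k, boundary) %*% matrix(xp, nrow = dm[1])
    xp <- array(m, dim = dm)
    x <- aperm(xp, order(perm))
  }
  x
}

# Elementwise median across a list of equal-shape numeric objects, via a
# full pairwise min/max sorting network (exact, vectorised).
elementwise_median <- function(vals) {
  m <- length(vals)
  for (i in seq_len(m - 1L)) {
    for (j in seq_len(m - i)) {
      lo <- pmin(vals[[j]], vals[[j + 1L]])
      hi <- pmax(vals[[j]], vals[[j + 1L]])
      vals[[j]] <- lo
      vals[[j + 1L]] <- hi
    }
  }
  if (m %% 2L == 1L) {
    vals[[(m + 1L) %/% 2L]]
  } else {
    (vals[[m %/% 2L]] + vals[[m %/% 2L + 1L]]) / 2
  }
}

#' Median filter with reflective border handling
#'
#' Square median filter of odd size applied to a numeric matrix, using
#' half-sample symmetric padding at the borders.
#'
#' @param x numeric matrix.
#' @param size odd window edge length in pixels (default 3).
#' @return filtered matrix of the same shape.
#' @export
median_filter <- function(x, size = 3L) {
  stopifnot(is.matrix(x))
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    stop("`size` must be a positive odd integer", call. = FALSE)
  }
  if (size == 1L) return(x)
  r <- size %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  shifts <- vector("list", size * size)
  s <- 1L
  for (dy in -r:r) {
    ri <- reflect_index(seq_len(nr) + dy, nr)
    for (dx in -r:r) {
      ci <- reflect_index(seq_len(nc) + dx, nc)
      shifts[[s]] <- x[ri, ci, drop = FALSE]
      s <- s + 1L
    }
  }
  elementwise_median(shifts)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed runs `expr` unmodified.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-event sub-seed derived from a base seed and a counter,
# kept inside the 32-bit signed integer range.
derive_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 2654435.0 + as.double(counter) * 97.0) %% 2147483629)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_positive <- function(x, what) {
  if (!is_scalar_number(x) || x <= 0) {
    stop("`", what, "` must be a positive finite number", call. = FALSE)
  }
  invisible(x)
}
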