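# Orthonormal type-II discrete cosine transforms, computed with the
# even/odd reordering FFT factorisation (no O(N^2) cosine sums).

# DCT-II of every column of a matrix, orthonormal scaling.
dct_cols <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m)
  ev <- seq(1L, n, by = 2L)
  od <- seq(2L, n, by = 2L)
  v <- m[c(ev, rev(od)), , drop = FALSE]
  V <- mvfft(v)
  ph <- exp(-1i * pi * (0:(n - 1)) / (2 * n))
  X <- Re(ph * V)
  X[1, ] <- X[1, ] / sqrt(n)
  X[-1, ] <- X[-1, , drop = FALSE] * sqrt(2 / n)
  X
}

#' Two-dimensional orthonormal DCT-II
#'
#' @param x numeric matrix.
#' @return matrix of DCT-II coefficients, same shape, with the DC
#'   coefficient at `[1, 1]`.
#' @export
dct_2d <- function(x) {
  stopifnot(is.matrix(x))
  t(dct_cols(t(dct_cols(x))))
}

dct_1d <- function(x) drop(dct_cols(matrix(x, ncol = 1L)))
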