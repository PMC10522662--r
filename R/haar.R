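#' Orthonormal full-depth Haar matrix
#'
#' Builds the n x n orthonormal matrix of the fully decomposed 1-D Haar
#' wavelet transform, defined recursively: averages of adjacent pairs feed
#' the half-size transform, differences become the finest-scale wavelets.
#' `H %*% t(H)` is the identity, and the first row is the constant
#' \eqn{1/\sqrt{n}} (so a constant signal has a single nonzero coefficient).
#'
#' @param n Side length, a power of 2.
#' @return An n x n orthonormal matrix.
#' @export
#' @examples
#' haar_matrix(2)  # 1/sqrt(2) * [1 1; 1 -1]
haar_matrix <- function(n) {
  stopifnot(n >= 1, bitwAnd(n, n - 1L) == 0)
  if (n == 1) return(matrix(1, 1, 1))
  H <- haar_matrix(n / 2)
  rbind(
    kronecker(H, matrix(c(1, 1) / sqrt(2), 1, 2)),
    kronecker(diag(n / 2), matrix(c(1, -1) / sqrt(2), 1, 2))
  )
}

#' Orthogonal 2-D Haar wavelet transform
#'
#' Separable full-depth transform \eqn{W = H X H^T} with `H` from
#' [haar_matrix()]; as a linear map on vectorised images it is the
#' orthogonal matrix \eqn{\Psi = H \otimes H}, so
#' `inverse_haar_2d(haar_2d(x))` returns `x` exactly (up to round-off).
#'
#' @param image Square numeric matrix, side a power of 2.
#' @return Coefficient matrix of the same dimensions.
#' @export
#' @examples
#' haar_2d(matrix(c(1, 3, 2, 4), 2, 2))
haar_2d <- function(image) {
  image <- as.matrix(image)
  n <- nrow(image)
  stopifnot(ncol(image) == n, bitwAnd(n, n - 1L) == 0)
  H <- haar_matrix(n)
  H %*% image %*% t(H)
}

#' @rdname haar_2d
#' @param coefficients Square coefficient matrix, side a power of 2.
#' @export
inverse_haar_2d <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  n <- nrow(coefficients)
  stopifnot(ncol(coefficients) == n, bitwAnd(n, n - 1L) == 0)
  H <- haar_matrix(n)
  t(H) %*% coefficients %*% H
}
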