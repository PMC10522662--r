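#' Random k-space sampling mask
#'
#' Uniform random selection, without replacement, of
#' `floor(rate * side^2)` points of the side x side Fourier (k-space) grid.
#' At `side = 64, rate = 0.4` this keeps 1638 points; at
#' `side = 128, rate = 0.3`, 4915 points.
#'
#' @param side Image side length.
#' @param rate Sampling (compression) rate in (0, 1].
#' @param seed Optional integer seed.
#' @param include_dc If `TRUE`, the k-space origin is always among the
#'   sampled points (the remaining points stay uniform). The image mean
#'   lives entirely in that single coefficient and is unrecoverable by
#'   any sparsity prior when unobserved, so the reconstruction pipeline
#'   samples it deterministically; the total count is unchanged.
#' @return Sorted integer vector of sampled linear (column-major) k-space
#'   indices in `1:side^2`.
#' @export
make_sampling_mask <- function(side, rate, seed = NULL, include_dc = FALSE) {
  stopifnot(side >= 1, rate > 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- floor(rate * side^2)
  if (include_dc && m >= 1) {
    sort(c(1L, sample(2:side^2, m - 1)))
  } else {
    sort(sample.int(side^2, m))
  }
}

#' Sparsify an image in the Haar wavelet domain
#'
#' Transforms the image with the orthogonal 2-D Haar transform, zeroes the
#' `floor(zero_fraction * side^2)` coefficients of smallest magnitude, and
#' transforms back. The returned sparseness is the fraction of nonzero
#' coefficients remaining (equal to `1 - zero_fraction` up to rounding when
#' no further coefficients happen to be exactly zero).
#'
#' @param image Square numeric matrix, side a power of 2.
#' @param zero_fraction Fraction of coefficients to zero, in \[0, 1\].
#' @return A list with elements `image` (the sparsified image),
#'   `coefficients` (its Haar coefficients) and `sparseness`.
#' @export
#' @examples
#' sp <- sparsify_image(matrix(rnorm(16), 4, 4), zero_fraction = 0.75)
#' sp$sparseness
sparsify_image <- function(image, zero_fraction) {
  stopifnot(zero_fraction >= 0, zero_fraction <= 1)
  w <- haar_2d(image)
  k <- floor(zero_fraction * length(w))
  if (k > 0) {
    drop <- order(abs(w))[seq_len(k)]
    w[drop] <- 0
  }
  list(
    image = inverse_haar_2d(w),
    coefficients = w,
    sparseness = mean(w != 0)
  )
}

#' Synthetic piecewise-smooth phantom, sparse in the Haar basis
#'
#' Generates a random grayscale phantom: overlapping ellipses and
#' rectangles of random intensity on a blank canvas, plus a faint texture
#' so no Haar coefficient is exactly zero, then hard-thresholded with
#' [sparsify_image()] so the Haar sparseness equals `target_sparseness`
#' (to within one coefficient, i.e. `1/side^2`). Pixel values are rescaled
#' to \[0, 1\]; the affine rescale only touches the constant (DC)
#' coefficient, so the sparseness is preserved. A stand-in for a real
#' anatomical image made sparse in the wavelet basis.
#'
#' @param side Image side, a power of 2.
#' @param target_sparseness Desired fraction of nonzero Haar coefficients.
#' @param seed Optional integer seed.
#' @param n_shapes Number of random shapes (default 8).
#' @return A `side` x `side` numeric matrix in \[0, 1\].
#' @export
#' @examples
#' ph <- generate_phantom(32, target_sparseness = 0.25, seed = 1)
#' range(ph)
generate_phantom <- function(side, target_sparseness = 0.212, seed = NULL,
                             n_shapes = 8) {
  stopifnot(side >= 2, bitwAnd(side, side - 1L) == 0,
            target_sparseness > 0, target_sparseness <= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- (seq_len(side) - 0.5) / side
  xg <- matrix(u, side, side)
  yg <- t(xg)
  canvas <- matrix(0, side, side)
  for (s in seq_len(n_shapes)) {
    cx <- runif(1, 0.15, 0.85); cy <- runif(1, 0.15, 0.85)
    ax <- runif(1, 0.06, 0.35); ay <- runif(1, 0.06, 0.35)
    val <- runif(1, -1, 1)
    th <- runif(1, 0, pi)
    xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
    yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
    inside <- if (runif(1) < 0.5) {
      (xr / ax)^2 + (yr / ay)^2 <= 1          # ellipse
    } else {
      abs(xr) <= ax & abs(yr) <= ay           # rectangle
    }
    canvas <- canvas + val * inside
  }
  # scale-decaying texture, synthesised directly in the Haar domain:
  # coefficient s.d. halves per finer level, emulating the ~1/f wavelet
  # spectra of natural images (and guaranteeing no coefficient is exactly
  # zero, so the subsequent hard threshold meets the target count exactly)
  lev <- c(0, ceiling(log2(seq_len(side)[-1])))
  sd_mat <- 0.2 * sd(canvas) * 2^(-pmax(outer(lev, lev, pmax), 1))
  texture <- inverse_haar_2d(matrix(rnorm(side^2), side, side) * sd_mat)
  canvas <- canvas + texture
  img <- sparsify_image(canvas, zero_fraction = 1 - target_sparseness)$image
  rng <- range(img)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, side, side))
  (img - rng[1]) / diff(rng)
}

#' Measured Haar sparseness of an image
#'
#' Fraction of Haar coefficients whose magnitude exceeds a relative
#' numerical threshold (transform round-trips leave O(1e-16) residue in
#' coefficients that are exactly zero in the construction).
#'
#' @param image Square numeric matrix, side a power of 2.
#' @param tol Relative magnitude threshold (default 1e-10).
#' @return Scalar in \[0, 1\].
#' @export
haar_sparseness <- function(image, tol = 1e-10) {
  w <- abs(haar_2d(image))
  m <- max(w)
  if (m == 0) return(0)
  mean(w > tol * m)
}

#' Unitary 2-D discrete Fourier transform
#'
#' `fft(x)/side` (forward) and `fft(x, inverse = TRUE)/side` (inverse), so
#' that with full sampling the k-space Gram operator is the identity.
#'
#' @param x Square numeric or complex matrix.
#' @return Complex matrix of the same dimensions.
#' @export
dft_2d <- function(x) stats::fft(x) / nrow(x)

#' @rdname dft_2d
#' @export
inverse_dft_2d <- function(x) stats::fft(x, inverse = TRUE) / nrow(x)

#' Sample the k-space of an image
#'
#' @param image Square numeric matrix.
#' @param mask Integer vector of sampled k-space indices
#'   (see [make_sampling_mask()]).
#' @return Complex vector of sampled unitary-DFT values, one per mask entry.
#' @export
sample_kspace <- function(image, mask) {
  ks <- dft_2d(image)
  ks[mask]
}

# Eigenvalues of the periodic second-difference operators Dv^T Dv + Dh^T Dh
# on the side x side grid, laid out to match fft() output ordering.
laplacian_eigenvalues <- function(side) {
  lam <- (2 * cos(2 * pi * (seq_len(side) - 1) / side) - 2)^2
  outer(lam, rep(1, side)) + outer(rep(1, side), lam)
}

#' Build the sparse-MRI QUBO operators
#'
#' Assembles the mutual-interaction operator and Zeeman vector of the
#' wavelet-domain reconstruction problem
#' \deqn{\tilde J = \Psi F^H S^T S F \Psi^T
#'   + \gamma\,\Psi(\Delta_v^T\Delta_v + \Delta_h^T\Delta_h)\Psi^T,\qquad
#'   h^z = \mathrm{Re}(\Psi F^H S^T y),}
#' with \eqn{\Psi} the orthogonal 2-D Haar transform, `F` the unitary 2-D
#' DFT, `S` the k-space sampling matrix and \eqn{\Delta_{v,h}} periodic
#' second-difference smoothness operators. The observation matrix of the
#' equivalent compressed-sensing problem is \eqn{A = S F \Psi^T}. Both the
#' sampling indicator and the smoothness term are diagonal in Fourier
#' space, so \eqn{\tilde J} is applied via fast transforms (never
#' materialised), and its exact diagonal follows in O(side^3) from the
#' Kronecker structure \eqn{F\Psi^T = G \otimes G}.
#'
#' @param y_sampled Complex vector of sampled k-space data (same order as
#'   `mask`).
#' @param mask Integer vector of sampled k-space indices.
#' @param side Image side, a power of 2.
#' @param gamma L2 smoothness weight (default 1e-4).
#' @return An object of classes `mri_qubo` and `qubo_operator`: fields
#'   `op` (implicit \eqn{\tilde J} matrix-vector product on real
#'   coefficient vectors), `dg` (exact diagonal), `z` (Zeeman vector),
#'   `N = side^2`, plus `mask`, `side`, `gamma`.
#' @export
build_mri_qubo <- function(y_sampled, mask, side, gamma = 1e-4) {
  stopifnot(bitwAnd(side, side - 1L) == 0, length(y_sampled) == length(mask),
            all(mask >= 1), all(mask <= side^2), gamma >= 0)
  N <- side^2
  H <- haar_matrix(side)
  D <- matrix(0, side, side)
  D[mask] <- 1
  D <- D + gamma * laplacian_eigenvalues(side)

  op <- function(v) {
    V <- matrix(v, side, side)
    ks <- stats::fft(t(H) %*% V %*% H) / side
    img <- stats::fft(D * ks, inverse = TRUE) / side
    as.vector(Re(H %*% img %*% t(H)))
  }

  # exact diagonal: |G|^2-weighted quadratic form, G = f H^T / sqrt(side)
  f <- stats::mvfft(diag(side))            # dense 1-D DFT matrix
  P <- Mod(f %*% t(H))^2 / side
  dg <- as.vector(t(P) %*% D %*% P)

  ks_full <- matrix(0 + 0i, side, side)
  ks_full[mask] <- y_sampled
  z <- as.vector(Re(H %*% (stats::fft(ks_full, inverse = TRUE) / side) %*% t(H)))

  structure(
    list(op = op, dg = dg, z = z, N = N,
         mask = mask, side = side, gamma = gamma),
    class = c("mri_qubo", "qubo_operator")
  )
}

#' @export
print.mri_qubo <- function(x, ...) {
  cat(sprintf(
    "<mri_qubo> side = %d (N = %d spins), %d sampled k-space points (rate %.3g), gamma = %.3g\n",
    x$side, x$N, length(x$mask), length(x$mask) / x$N, x$gamma
  ))
  invisible(x)
}
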