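#' Generate a random Gaussian compressed-sensing instance
#'
#' Draws an instance of the observation model
#' \deqn{y = A(\xi \circ x) + w,\qquad A^k_r \sim N(0, 1/M),\quad
#'   x_r \sim N(0,1),\quad w^k \sim N(0,\nu^2),}
#' where exactly `round(a * N)` randomly chosen entries of the true support
#' \eqn{\xi \in \{0,1\}^N} are 1. With `M = alpha * N` measurements the
#' columns of `A` have unit expected squared norm, so signal and
#' measurement scales match.
#'
#' @param N Number of unknowns (source-signal length).
#' @param alpha Compression ratio `M/N` in (0, 1]; `M = round(alpha * N)`.
#' @param a Sparseness: fraction of nonzero source entries in \[0, 1\].
#' @param nu Observation-noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#'
#' @return An object of class `cs_problem`: a list with observation matrix
#'   `A` (M x N), observations `y`, ground truth `x_true` and `xi_true`,
#'   and the parameters `nu`, `alpha`, `a`.
#' @export
#' @examples
#' prob <- generate_random_cs(100, alpha = 0.6, a = 0.2, seed = 1)
#' sum(prob$xi_true)   # 20 active entries
generate_random_cs <- function(N, alpha, a, nu = 0, seed = NULL) {
  stopifnot(N >= 1, alpha > 0, alpha <= 1, a >= 0, a <= 1, nu >= 0)
  if (!is.null(seed)) set.seed(seed)
  M <- max(1L, as.integer(round(alpha * N)))
  A <- matrix(rnorm(M * N, sd = sqrt(1 / M)), M, N)
  x <- rnorm(N)
  xi <- numeric(N)
  k <- as.integer(round(a * N))
  if (k > 0) xi[sample.int(N, k)] <- 1
  y <- as.vector(A %*% (xi * x)) + if (nu > 0) rnorm(M, sd = nu) else 0
  structure(
    list(A = A, y = y, x_true = x, xi_true = xi, nu = nu,
         alpha = alpha, a = a, N = N, M = M),
    class = "cs_problem"
  )
}

#' @export
print.cs_problem <- function(x, ...) {
  cat(sprintf(
    "<cs_problem> N = %d, M = %d (alpha = %.3g), sparseness a = %.3g, nu = %.3g\n",
    x$N, x$M, x$alpha, x$a, x$nu
  ))
  invisible(x)
}

#' Quadratic (QUBO) operator view of a problem
#'
#' Internal common interface consumed by the machine models, the classical
#' least-squares stage, the annealer and the Hamiltonian: a list with
#' `op(v)` applying the Gram (mutual-interaction) matrix, its diagonal
#' `dg`, the Zeeman (matched-filter) vector `z = A^T y`, and the size `N`.
#'
#' @param x A `cs_problem`, an `mri_qubo`, or a bare list already carrying
#'   `op`, `dg`, `z`, `N`.
#' @param ... Unused.
#' @return A list of class `qubo_operator`.
#' @export
as_qubo <- function(x, ...) UseMethod("as_qubo")

#' @export
as_qubo.qubo_operator <- function(x, ...) x

#' @export
as_qubo.cs_problem <- function(x, ...) {
  A <- x$A
  structure(
    list(
      op = function(v) as.vector(crossprod(A, A %*% v)),
      dg = colSums(A^2),
      z = as.vector(crossprod(A, x$y)),
      N = ncol(A)
    ),
    class = "qubo_operator"
  )
}

#' @export
as_qubo.list <- function(x, ...) {
  stopifnot(all(c("op", "dg", "z", "N") %in% names(x)))
  structure(x, class = "qubo_operator")
}

#' Dense Gram matrix of a quadratic operator
#'
#' Materialises the N x N mutual-interaction matrix by applying the
#' implicit operator to the canonical basis. Intended for small problems
#' (oracle checks, exhaustive search, simulated annealing).
#'
#' @param qubo Anything accepted by [as_qubo()].
#' @param max_n Guard against accidental huge materialisations.
#' @return A dense symmetric matrix.
#' @export
dense_gram <- function(qubo, max_n = 4096) {
  q <- as_qubo(qubo)
  stopifnot(q$N <= max_n)
  vapply(seq_len(q$N), function(r) {
    e <- numeric(q$N); e[r] <- 1
    q$op(e)
  }, numeric(q$N))
}
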