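#' Direction cosine between true and estimated supports
#'
#' \deqn{\cos\theta = \frac{\sum_r \xi_r\sigma_r}
#'   {\sqrt{\sum_r \xi_r \sum_r \sigma_r}} \in [0, 1],}
#' the overlap statistic of two 0/1 vectors: 1 for perfect support
#' recovery, 0 for disjoint supports. Convention for degenerate cases:
#' 1 when both supports are empty, 0 when exactly one is.
#'
#' @param xi True support (0/1 vector).
#' @param sigma Estimated support (0/1 vector, same length).
#' @return Scalar in \[0, 1\]; symmetric in its arguments.
#' @export
#' @examples
#' direction_cosine(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
direction_cosine <- function(xi, sigma) {
  stopifnot(length(xi) == length(sigma),
            all(xi %in% c(0, 1)), all(sigma %in% c(0, 1)))
  n1 <- sum(xi); n2 <- sum(sigma)
  if (n1 == 0 && n2 == 0) return(1)
  if (n1 == 0 || n2 == 0) return(0)
  sum(xi * sigma) / sqrt(n1 * n2)
}

#' Root-mean-square error of a masked signal estimate
#'
#' \deqn{\mathrm{RMSE} = \sqrt{\tfrac1N \sum_r
#'   (R_r\sigma_r - x_r\xi_r)^2},}
#' comparing the supported estimate against the supported truth.
#'
#' @param R Signal estimate.
#' @param sigma Estimated support (0/1).
#' @param x True signal values.
#' @param xi True support (0/1).
#' @return Non-negative scalar.
#' @export
recovery_rmse <- function(R, sigma, x, xi) {
  stopifnot(length(R) == length(sigma), length(x) == length(xi),
            length(R) == length(x))
  sqrt(mean((R * sigma - x * xi)^2))
}

#' QUBO Hamiltonian of the L0-regularised problem
#'
#' \deqn{\mathscr{H} = \sum_{r<r'}\sum_k A^k_r A^k_{r'} R_r R_{r'}
#'   \sigma_r\sigma_{r'} - \sum_r\sum_k y^k A^k_r R_r\sigma_r
#'   + \lambda\sum_r \sigma_r,}
#' which equals \eqn{\frac12\|y - A(\sigma\circ R)\|^2 +
#' \lambda\|\sigma\|_0 - \frac12\|y\|^2} minus the quadratic-form
#' diagonal \eqn{\frac12\sum_r (\sum_k (A^k_r)^2) R_r^2\sigma_r}
#' (the pairwise sum excludes self-interactions). The threshold of the
#' machine models maps onto the penalty through the Maxwell rule
#' \eqn{\lambda = \eta^2/2}.
#'
#' @param R Signal values.
#' @param sigma 0/1 support vector.
#' @param A Observation matrix (M x N) or anything accepted by
#'   [as_qubo()].
#' @param y Observations (ignored when `A` is a quadratic operator).
#' @param lambda L0 penalty (>= 0).
#' @return Scalar energy.
#' @export
qubo_hamiltonian <- function(R, sigma, A, y = NULL, lambda) {
  q <- if (is.matrix(A)) as_qubo(structure(list(A = A, y = y), class = "cs_problem")) else as_qubo(A)
  stopifnot(length(R) == q$N, length(sigma) == q$N, all(sigma %in% c(0, 1)),
            lambda >= 0)
  v <- R * sigma
  0.5 * (sum(v * q$op(v)) - sum(q$dg * v^2)) - sum(q$z * v) +
    lambda * sum(sigma)
}
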