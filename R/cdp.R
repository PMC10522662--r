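# --- classical digital processor: restricted least squares at frozen support

cdp_check_support <- function(q, sigma) {
  stopifnot(length(sigma) == q$N, all(sigma %in% c(0, 1)))
  bad <- which(sigma == 1 & q$dg <= .Machine$double.eps)
  if (length(bad) > 0) {
    stop("zero column norm on active support index ", bad[1])
  }
}

#' Jacobi relaxation for the restricted least-squares stage
#'
#' Simultaneous (Jacobi-type) relaxation towards the stationarity system
#' \eqn{R_r \sum_k (A^k_r)^2 = \sigma_r \mathbb{H}_r}: each sweep applies
#' \deqn{R \leftarrow R + \Delta t_c\,(\sigma \circ \mathbb{H}(R) -
#'   \mathrm{diag}(A^TA)\circ R),}
#' an explicit-Euler gradient flow whose fixed point solves the normal
#' equations restricted to the active support. Inactive entries decay to
#' zero and are exactly zero on return. The support is frozen throughout.
#'
#' @param A Observation matrix (M x N) or anything accepted by
#'   [as_qubo()].
#' @param y Observations (ignored when `A` is a quadratic operator).
#' @param sigma 0/1 support vector (length N).
#' @param dt_c Relaxation step (default 0.1).
#' @param iters Number of sweeps (default 100).
#' @param R_init Optional warm start (masked to the support).
#' @return Signal estimate of class `cdp_solution`: list with `R` (zeros
#'   off-support), `residual` (max norm of the stationarity residual on
#'   the support) and `iters`.
#' @export
solve_jacobi <- function(A, y = NULL, sigma, dt_c = 0.1, iters = 100,
                         R_init = NULL) {
  q <- if (is.matrix(A)) as_qubo(structure(list(A = A, y = y), class = "cs_problem")) else as_qubo(A)
  cdp_check_support(q, sigma)
  R <- if (is.null(R_init)) numeric(q$N) else R_init * sigma
  for (it in seq_len(iters)) {
    H <- local_field_op(q, R * sigma, q$z)
    R <- R + dt_c * (sigma * H - q$dg * R)
  }
  R <- R * sigma
  H <- local_field_op(q, R, q$z)
  structure(
    list(R = R, residual = max(abs(sigma * (q$dg * R - H))), iters = iters),
    class = "cdp_solution"
  )
}

#' Conjugate-gradient solve of the restricted normal equations
#'
#' Solves \eqn{(A^TA)_{SS} R_S = (A^Ty)_S} on the active support `S` by
#' conjugate gradients, using only operator applications, so it accepts
#' either an explicit matrix or an implicit operator (MRI scale). The
#' support is frozen; inactive entries are exactly zero on return.
#'
#' @inheritParams solve_jacobi
#' @param tol Relative residual tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 10000); a warning reports the
#'   final residual if it is reached.
#' @param history If `TRUE`, record the quadratic objective
#'   \eqn{\frac12 R^T J R - z^T R} after every iteration.
#' @return A `cdp_solution` list with `R`, `residual` (relative), `iters`
#'   and optionally `objective` (numeric vector).
#' @export
solve_cgd <- function(A, y = NULL, sigma, tol = 1e-10, max_iter = 10000,
                      R_init = NULL, history = FALSE) {
  q <- if (is.matrix(A)) as_qubo(structure(list(A = A, y = y), class = "cs_problem")) else as_qubo(A)
  cdp_check_support(q, sigma)
  Mv <- function(v) sigma * q$op(sigma * v)
  b <- sigma * q$z
  bnorm <- sqrt(sum(b^2))
  x <- if (is.null(R_init)) numeric(q$N) else R_init * sigma
  if (bnorm == 0) {
    return(structure(list(R = numeric(q$N), residual = 0, iters = 0L),
                     class = "cdp_solution"))
  }
  r <- b - Mv(x)
  p <- r
  rs <- sum(r^2)
  obj <- if (history) numeric(0) else NULL
  it <- 0L
  while (it < max_iter && sqrt(rs) / bnorm > tol) {
    it <- it + 1L
    Mp <- Mv(p)
    denom <- sum(p * Mp)
    if (denom <= 0) break   # semidefinite direction exhausted
    alpha <- rs / denom
    x <- x + alpha * p
    r <- r - alpha * Mp
    rs_new <- sum(r^2)
    if (history) obj <- c(obj, 0.5 * sum(x * Mv(x)) - sum(b * x))
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  rel <- sqrt(rs) / bnorm
  if (rel > tol && it >= max_iter) {
    warning(sprintf("conjugate gradient stopped at max_iter with relative residual %.3g", rel))
  }
  structure(
    list(R = x * sigma, residual = rel, iters = it, objective = obj),
    class = "cdp_solution"
  )
}

#' @export
print.cdp_solution <- function(x, ...) {
  cat(sprintf("<cdp_solution> %d active entries, residual %.3g after %d iterations\n",
              sum(x$R != 0), x$residual, x$iters))
  invisible(x)
}
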