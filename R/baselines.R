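#' Single-flip Metropolis annealer for the L0-regularised QUBO
#'
#' Simulated-annealing baseline: single-spin-flip Metropolis dynamics on
#' the support \eqn{\sigma \in \{0,1\}^N} against the QUBO Hamiltonian at
#' fixed signal values `R`, with one uniformly random proposed flip per
#' Monte-Carlo step. The energy change of a flip is maintained
#' incrementally in O(N) by caching the Gram-matrix product with the
#' current masked signal. At zero temperature moves are accepted iff the
#' energy decreases (ties with probability 1/2); the exponential schedule
#' interpolates the temperature geometrically.
#'
#' @param problem A [generate_random_cs()] instance or anything accepted
#'   by [as_qubo()] (the Gram matrix is materialised; intended for
#'   moderate N).
#' @param R Signal values held fixed.
#' @param lam L0 penalty \eqn{\lambda} (use \eqn{\eta^2/2} to match the
#'   machine models).
#' @param schedule An [anneal_schedule()].
#' @param seed Optional integer seed.
#' @param sigma_init Optional initial support (default: uniform random).
#' @param history If `TRUE`, record the energy after every step.
#' @return List of class `sa_run`: `sigma`, `hamiltonian`, and optionally
#'   `energy_trace`.
#' @export
sa_metropolis <- function(problem, R, lam, schedule = anneal_schedule(),
                          seed = NULL, sigma_init = NULL, history = FALSE) {
  q <- as_qubo(problem)
  N <- q$N
  stopifnot(length(R) == N, lam >= 0)
  if (!is.null(seed)) set.seed(seed)
  J <- if (inherits(problem, "cs_problem")) crossprod(problem$A) else dense_gram(q)
  dJ <- diag(J)
  z <- q$z

  sigma <- if (is.null(sigma_init)) {
    as.numeric(runif(N) < 0.5)
  } else {
    stopifnot(length(sigma_init) == N, all(sigma_init %in% c(0, 1)))
    sigma_init
  }
  v <- R * sigma
  f <- as.vector(J %*% v)          # cached Gram product, updated per flip
  energy <- 0.5 * (sum(v * f) - sum(dJ * v^2)) - sum(z * v) + lam * sum(sigma)

  temps <- schedule_temperatures(schedule)
  n_steps <- schedule$n_steps
  flips <- sample.int(N, n_steps, replace = TRUE)
  us <- runif(n_steps)
  trace <- if (history) numeric(n_steps) else NULL

  for (k in seq_len(n_steps)) {
    r <- flips[k]
    delta <- if (sigma[r] == 0) R[r] else -R[r]
    dH <- delta * (f[r] - dJ[r] * v[r]) - z[r] * delta +
      lam * (1 - 2 * sigma[r])
    Tk <- temps[k]
    accept <- if (dH < 0) {
      TRUE
    } else if (Tk > 0) {
      us[k] < exp(-dH / Tk)
    } else {
      dH == 0 && us[k] < 0.5
    }
    if (accept) {
      sigma[r] <- 1 - sigma[r]
      v[r] <- v[r] + delta
      f <- f + delta * J[, r]
      energy <- energy + dH
    }
    if (history) trace[k] <- energy
  }

  structure(list(sigma = sigma, hamiltonian = energy, energy_trace = trace,
                 schedule = schedule),
            class = "sa_run")
}

#' @export
print.sa_run <- function(x, ...) {
  cat(sprintf("<sa_run> |support| = %d, Hamiltonian %.6g (%s schedule, %d steps)\n",
              sum(x$sigma), x$hamiltonian, x$schedule$kind, x$schedule$n_steps))
  invisible(x)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' LASSO by accelerated proximal gradient (FISTA)
#'
#' Minimises \eqn{\frac12\|y - Ax\|^2 + \lambda_1\|x\|_1} by proximal
#' gradient with Nesterov momentum and objective-based restart. Accepts
#' either an explicit observation matrix or an implicit quadratic
#' operator (the MRI Gram/Zeeman pair), in which case the equivalent
#' objective \eqn{\frac12 x^TJx - z^Tx + \lambda_1\|x\|_1} is minimised.
#' The gradient Lipschitz constant is estimated by power iteration.
#'
#' @param A Observation matrix (M x N) or anything accepted by
#'   [as_qubo()].
#' @param y Observations (ignored when `A` is a quadratic operator).
#' @param lam1 L1 penalty (>= 0).
#' @param tol Relative-change stopping tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 5000); a warning is raised on
#'   non-convergence.
#' @param x_init Optional warm start.
#' @return List of class `lasso_fit`: `x` (the estimate), `objective`
#'   (per-iteration values of the penalised objective, up to a constant
#'   for operator input), `iters`, `converged`.
#' @export
lasso_fista <- function(A, y = NULL, lam1, tol = 1e-8, max_iter = 5000,
                        x_init = NULL) {
  stopifnot(lam1 >= 0)
  q <- if (is.matrix(A)) as_qubo(structure(list(A = A, y = y), class = "cs_problem")) else as_qubo(A)
  N <- q$N
  # Lipschitz constant: largest Gram eigenvalue via power iteration
  u <- rnorm(N); u <- u / sqrt(sum(u^2))
  L <- 1
  for (k in 1:30) {
    w <- q$op(u)
    L <- sqrt(sum(w^2))
    if (L == 0) break
    u <- w / L
  }
  L <- max(L, .Machine$double.eps) * 1.05

  fobj <- function(x) 0.5 * sum(x * q$op(x)) - sum(q$z * x) + lam1 * sum(abs(x))
  x <- if (is.null(x_init)) numeric(N) else x_init
  xm <- x
  tmom <- 1
  obj <- numeric(0)
  obj_prev <- fobj(x)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    zv <- x + ((tmom - 1) / (tmom + 2)) * (x - xm)  # momentum extrapolation
    grad <- q$op(zv) - q$z
    x_new <- soft_threshold(zv - grad / L, lam1 / L)
    o <- fobj(x_new)
    if (o > obj_prev) {               # restart: plain proximal step
      grad <- q$op(x) - q$z
      x_new <- soft_threshold(x - grad / L, lam1 / L)
      o <- fobj(x_new)
      tmom <- 1
    }
    xm <- x
    x <- x_new
    tmom <- tmom + 1
    obj <- c(obj, o)
    if (abs(obj_prev - o) <= tol * (abs(obj_prev) + 1e-12)) {
      obj_prev <- o
      converged <- TRUE
      break
    }
    obj_prev <- o
  }
  if (!converged) {
    warning(sprintf("FISTA stopped at max_iter = %d without meeting tol", max_iter))
  }
  structure(list(x = x, objective = obj, iters = length(obj),
                 converged = converged, lam1 = lam1),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lam1 = %.4g, %d nonzero of %d, %d iterations%s\n",
              x$lam1, sum(x$x != 0), length(x$x), x$iters,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
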