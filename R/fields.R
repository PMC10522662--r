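#' Heaviside binarisation of amplitudes into a support vector
#'
#' \eqn{\sigma_r = 1} if the amplitude is strictly positive, else 0 (the
#' boundary value 0 maps to 0).
#'
#' @param v Finite numeric vector.
#' @return Numeric 0/1 vector.
#' @export
#' @examples
#' binarise(c(0.3, -0.3, 0))  # 1 0 0
binarise <- function(v) {
  stopifnot(all(is.finite(v)))
  as.numeric(v > 0)
}

# Shared local-field kernel: h = -(J v - diag(J) v) + zeeman, with the
# r' != r exclusion done as a full Gram matvec minus the diagonal term
# (O(NM) instead of O(N^2 M)).
local_field_op <- function(qubo, v, zeeman) {
  -(qubo$op(v) - qubo$dg * v) + zeeman
}

#' Local field of the open-loop machine
#'
#' \deqn{h_r = -\sum_{r'\ne r}\sum_k A^k_r A^k_{r'} R_{r'} H(c_{r'})
#'   + \sum_k A^k_r y^k,}
#' the gradient of the QUBO Hamiltonian at the binarised in-phase
#' amplitudes: cross-talk removal plus the matched-filter (Zeeman) drive.
#'
#' @param c In-phase amplitudes (length N).
#' @param R Current signal estimate (length N).
#' @param A Observation matrix (M x N), or anything accepted by
#'   [as_qubo()] (in which case `y` is ignored).
#' @param y Observations (length M).
#' @return Local field vector (length N).
#' @export
ol_local_field <- function(c, R, A, y = NULL) {
  q <- if (is.matrix(A)) as_qubo(structure(list(A = A, y = y), class = "cs_problem")) else as_qubo(A)
  stopifnot(length(c) == q$N, length(R) == q$N)
  local_field_op(q, R * binarise(c), q$z)
}

#' Open-loop injection field
#'
#' \eqn{(dc/dt)_{inj,r} = |h_r| - \eta}: amplitudes whose local field
#' exceeds the threshold in magnitude are driven positive (into the
#' support), the rest negative.
#'
#' @param h Local field vector.
#' @param eta Support threshold (>= 0).
#' @return Injection vector.
#' @export
ol_injection <- function(h, eta) {
  stopifnot(eta >= 0)
  abs(h) - eta
}

#' Local field of the CAC machine
#'
#' \deqn{h_r = -\sum_{r'\ne r}\sum_k A^k_r A^k_{r'} R_{r'}
#'   \tfrac12\big(\tilde\mu_{r'} + \sqrt{\tau/g^2}\big)
#'   + \sqrt{\tau/g^2}\sum_k A^k_r y^k.}
#' The measured amplitudes are stabilised near \eqn{\pm\sqrt{\tau/g^2}}
#' by the amplitude-control loop, so the bracket takes values near 0 or
#' \eqn{\sqrt{\tau/g^2}} and the interaction and Zeeman terms stay
#' balanced.
#'
#' @param mu_tilde Measured amplitudes (length N).
#' @param R Current signal estimate.
#' @param A Observation matrix (M x N) or anything accepted by [as_qubo()].
#' @param y Observations (ignored when `A` is a quadratic operator).
#' @param tau Target squared amplitude (> 0).
#' @param g2 Saturation parameter (> 0).
#' @return Local field vector (length N).
#' @export
cac_local_field <- function(mu_tilde, R, A, y = NULL, tau, g2) {
  stopifnot(tau > 0, g2 > 0)
  q <- if (is.matrix(A)) as_qubo(structure(list(A = A, y = y), class = "cs_problem")) else as_qubo(A)
  stopifnot(length(mu_tilde) == q$N, length(R) == q$N)
  s <- sqrt(tau / g2)
  local_field_op(q, R * (mu_tilde + s) / 2, s * q$z)
}

#' CAC injection field
#'
#' \deqn{(d\mu_r/dt)_{inj,r} = j e_r\big(R_r h_r -
#'   \tfrac{\eta^2}{2}\sqrt{\tau/g^2}\big),}
#' the local-field drive gated by the error-feedback gain \eqn{e_r}; the
#' threshold term is the L0 penalty \eqn{\lambda = \eta^2/2} expressed on
#' the amplitude scale.
#'
#' @param h Local field vector.
#' @param R Signal estimate.
#' @param e Error-feedback variables (positive).
#' @param eta Support threshold.
#' @param tau,g2,j Machine parameters (see [cim_config()]).
#' @return Injection vector.
#' @export
cac_injection <- function(h, R, e, eta, tau, g2, j) {
  stopifnot(tau > 0, g2 > 0, j > 0, eta >= 0)
  j * e * (R * h - (eta^2 / 2) * sqrt(tau / g2))
}

#' Local field of the classical least-squares stage
#'
#' \deqn{\mathbb{H}_r = -\sum_{r'\ne r}\sum_k A^k_r A^k_{r'} R_{r'}
#'   \sigma_{r'} + \sum_k A^k_r y^k,}
#' the stationarity field of the restricted least-squares problem at
#' frozen support.
#'
#' @param R Signal estimate.
#' @param sigma 0/1 support vector.
#' @param A Observation matrix (M x N) or anything accepted by [as_qubo()].
#' @param y Observations (ignored when `A` is a quadratic operator).
#' @return Field vector (length N).
#' @export
cdp_local_field <- function(R, sigma, A, y = NULL) {
  q <- if (is.matrix(A)) as_qubo(structure(list(A = A, y = y), class = "cs_problem")) else as_qubo(A)
  stopifnot(length(R) == q$N, length(sigma) == q$N, all(sigma %in% c(0, 1)))
  local_field_op(q, R * sigma, q$z)
}
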