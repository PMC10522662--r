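#' Pump-rate schedule for CAC feedback runs
#'
#' Sigmoidal ramp of the normalised pump rate used while integrating the
#' CAC (chaotic amplitude control) machine models:
#' \deqn{p(t) = (p_{thr} - d) + \frac{2d}{1 + e^{-(t-4)/2}}.}
#' The schedule starts just below `p_thr - d`, crosses `p_thr` at `t = 4`
#' photon lifetimes and saturates at `p_thr + d`.
#'
#' @param t Time in photon-lifetime units (scalar or vector, `t >= 0`).
#' @param p_thr Pump threshold value (default 1, the oscillation threshold).
#' @param d Pump modulation depth; 0.6 for random Gaussian instances,
#'   0.4 for the MRI pipeline.
#'
#' @return Pump rate `p(t)`, same shape as `t`.
#' @seealso [pump_schedule_ol()], [threshold_schedule()]
#' @export
#' @examples
#' pump_schedule_cac(4)            # equals p_thr at the sigmoid midpoint
#' pump_schedule_cac(c(0, 10, 20))
pump_schedule_cac <- function(t, p_thr = 1, d = 0.6) {
  stopifnot(all(t >= 0))
  (p_thr - d) + 2 * d / (1 + exp(-(t - 4) / 2))
}

#' Pump-rate schedule for open-loop runs
#'
#' Quadratic pump ramp \eqn{p(t) = 1.5 (t/5)^2} used while integrating the
#' open-loop Wigner model; the pump reaches 1.5 at `t = 5` photon lifetimes.
#'
#' @param t Time in photon-lifetime units (`t >= 0`).
#' @return Pump rate `p(t)`.
#' @export
#' @examples
#' pump_schedule_ol(5)   # 1.5
pump_schedule_ol <- function(t) {
  stopifnot(all(t >= 0))
  1.5 * (t / 5)^2
}

#' Injection-threshold schedule over alternating iterations
#'
#' Linear annealing of the support threshold \eqn{\eta} as the alternating
#' minimisation proceeds:
#' \deqn{\eta_i = \max[\eta_{init}(1 - i/velo),\ \eta_{end}].}
#' The threshold maps onto the L0 penalty through the Maxwell rule
#' \eqn{\lambda = \eta^2/2}, so lowering \eqn{\eta} gradually relaxes the
#' sparsity pressure towards its final value.
#'
#' @param i Alternating-iteration index, starting at 0 (scalar or vector).
#' @param eta_init,eta_end Schedule endpoints, `eta_init >= eta_end >= 0`.
#' @param velo Schedule denominator (iterations to reach zero in the linear
#'   term); 51 for random Gaussian instances, 31/11 for the MRI pipeline.
#'
#' @return Threshold \eqn{\eta_i}, same shape as `i`.
#' @export
#' @examples
#' threshold_schedule(0:5, 0.6, 0.18, velo = 51)
threshold_schedule <- function(i, eta_init, eta_end, velo) {
  stopifnot(all(i >= 0), velo >= 1, eta_init >= eta_end, eta_end >= 0)
  pmax(eta_init * (1 - i / velo), eta_end)
}
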