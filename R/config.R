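#' Configuration for the CIM stochastic differential equations
#'
#' Collects every tunable of the machine models and their schedules in one
#' validated list. Defaults reproduce the random-Gaussian-instance setting
#' (CAC models: `dt = 0.02` over 1000 steps, i.e. 20 photon lifetimes);
#' use [cim_preset()] for the per-experiment parameter sets.
#'
#' @param g2 Nonlinear saturation parameter \eqn{g^2} (> 0). Sets the
#'   oscillation photon-number scale \eqn{\tau/g^2} and the relative size of
#'   quantum noise; `1e-7` approaches classical dynamics.
#' @param j Normalised out-coupling rate for homodyne measurement (> 0).
#' @param K Feedback strength of the CAC injection. The default 0.1 was
#'   chosen by a rough search so that amplitudes stabilise at the target
#'   within the 20-lifetime integration window on random Gaussian
#'   instances; the MRI preset uses 0.01.
#' @param K_tilde Feedback strength of the open-loop injection.
#' @param beta Error-feedback rate of the CAC loop, per photon lifetime.
#'   The default 1 makes the error gain strong enough to drive every
#'   pulse to the target amplitude within the integration window.
#' @param tau Target squared amplitude (in units of \eqn{1/g^2}) the CAC
#'   loop stabilises towards.
#' @param dt Time increment in photon-lifetime units.
#' @param n_steps Number of Euler-Maruyama steps per CIM call.
#' @param p_thr,d Pump threshold and modulation depth of the CAC pump
#'   schedule ([pump_schedule_cac()]).
#' @param eta_init,eta_end Endpoints of the threshold schedule
#'   ([threshold_schedule()]).
#' @param velo Threshold-schedule denominator (integer >= 1).
#' @param seed Optional integer seed applied at the start of each run that
#'   consumes this configuration.
#'
#' @return An object of class `cim_config` (a named list).
#' @export
#' @examples
#' cfg <- cim_config(eta_init = 0.6, eta_end = 0.18)
#' cfg$tau
cim_config <- function(g2 = 1e-7, j = 1, K = 0.1, K_tilde = 0.25,
                       beta = 1, tau = 1, dt = 0.02, n_steps = 1000,
                       p_thr = 1, d = 0.6, eta_init = 0.05, eta_end = 0.05,
                       velo = 51, seed = NULL) {
  stopifnot(
    g2 > 0, j > 0, dt > 0, n_steps >= 1, tau > 0, beta > 0,
    eta_init >= eta_end, eta_end >= 0, velo >= 1
  )
  structure(
    list(
      g2 = g2, j = j, K = K, K_tilde = K_tilde, beta = beta, tau = tau,
      dt = dt, n_steps = as.integer(n_steps), p_thr = p_thr, d = d,
      eta_init = eta_init, eta_end = eta_end, velo = as.integer(velo),
      seed = seed
    ),
    class = "cim_config"
  )
}

#' @export
print.cim_config <- function(x, ...) {
  cat("<cim_config>\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  cat(paste0("  ", names(flds), " = ", unlist(flds), collapse = "\n"), "\n")
  invisible(x)
}

#' Per-experiment configuration presets
#'
#' Returns a [cim_config()] pre-filled for one of the two study settings:
#' random Gaussian instances (`"artificial"`: pump depth 0.6, threshold
#' annealed over `velo = 51` iterations) or the sparse-MRI pipeline
#' (`"mri"`: pump depth 0.4, constant threshold, `velo` 11 for CAC models
#' and 31 for the open-loop model). Open-loop models integrate 50 steps of
#' `dt = 0.1` (5 lifetimes); CAC models 1000 steps of `dt = 0.02`
#' (20 lifetimes).
#'
#' @param model One of `"cac_wigner"`, `"positive_p"`, `"wigner_ol"`.
#' @param experiment `"artificial"` or `"mri"`.
#' @param ... Overrides passed on to [cim_config()].
#' @return A `cim_config`.
#' @export
#' @examples
#' cim_preset("wigner_ol", "artificial")$n_steps  # 50
cim_preset <- function(model = c("cac_wigner", "positive_p", "wigner_ol"),
                       experiment = c("artificial", "mri"), ...) {
  model <- match.arg(model)
  experiment <- match.arg(experiment)
  args <- list()
  if (model == "wigner_ol") {
    args$dt <- 0.1
    args$n_steps <- 50
  }
  if (experiment == "mri") {
    args$d <- 0.4
    args$K <- 0.01
    args$velo <- if (model == "wigner_ol") 31L else 11L
  }
  do.call(cim_config, modifyList(args, list(...)))
}

#' Annealing schedule for the simulated-annealing baseline
#'
#' @param kind `"zero_temperature"` (greedy descent, ties accepted with
#'   probability 1/2) or `"exponential"` (geometric interpolation of the
#'   temperature from `T_start` down to `T_end` over `n_steps`).
#' @param T_start,T_end Temperatures, `T_start >= T_end >= 0`; both must be
#'   positive for the exponential kind. Defaults follow the cooling range
#'   0.02 to 0.00002.
#' @param n_steps Number of Monte-Carlo steps (one proposed single-spin
#'   flip per step).
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(kind = c("exponential", "zero_temperature"),
                            T_start = 0.02, T_end = 2e-5, n_steps = 10000) {
  kind <- match.arg(kind)
  stopifnot(T_start >= T_end, T_end >= 0, n_steps >= 1)
  if (kind == "exponential") stopifnot(T_start > 0, T_end > 0)
  structure(
    list(kind = kind, T_start = T_start, T_end = T_end,
         n_steps = as.integer(n_steps)),
    class = "anneal_schedule"
  )
}

#' Temperature at each Monte-Carlo step of an annealing schedule
#'
#' @param schedule An [anneal_schedule()].
#' @return Numeric vector of length `n_steps`.
#' @export
schedule_temperatures <- function(schedule) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  n <- schedule$n_steps
  if (schedule$kind == "zero_temperature") return(rep(0, n))
  if (n == 1) return(schedule$T_start)
  schedule$T_start * (schedule$T_end / schedule$T_start)^((seq_len(n) - 1) / (n - 1))
}
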