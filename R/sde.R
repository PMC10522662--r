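#' One Euler-Maruyama step of the open-loop Wigner model
#'
#' Updates the in-phase and quadrature amplitudes of each degenerate
#' optical parametric oscillator pulse:
#' \deqn{dc_r = [(-1 + p - (c_r^2+s_r^2))c_r + \tilde K\,inj_r]\,dt
#'   + g\sqrt{c_r^2+s_r^2+\tfrac12}\,dW_1,}
#' and the analogous damped equation for \eqn{s_r} (pump sign reversed, no
#' injection). With noise and injection off, \eqn{c^* = \sqrt{p-1}, s^*=0}
#' is a fixed point above threshold.
#'
#' @param state List with numeric vectors `c` and `s` (length N).
#' @param p Pump rate (scalar).
#' @param injection Injection vector (length N), see [ol_injection()].
#' @param cfg A [cim_config()] (uses `g2`, `K_tilde`, `dt`).
#' @param noise_c,noise_s Standard-normal vectors of length N (the
#'   Wiener increments are `sqrt(dt)` times these).
#' @return Updated state list.
#' @export
step_wigner_ol <- function(state, p, injection, cfg, noise_c, noise_s) {
  g <- sqrt(cfg$g2); dt <- cfg$dt
  amp2 <- state$c^2 + state$s^2
  nse <- g * sqrt(amp2 + 0.5) * sqrt(dt)
  list(
    c = state$c + ((-1 + p - amp2) * state$c + cfg$K_tilde * injection) * dt +
      nse * noise_c,
    s = state$s + ((-1 - p - amp2) * state$s) * dt + nse * noise_s
  )
}

# Measured amplitude: the homodyne record shares the Gaussian draw with the
# drift noise; on the Euler grid the white-noise realisation is
# w / sqrt(dt), hence the 1 / sqrt(4 j dt) scaling.
measured_amplitude <- function(mu, noise, j, dt) {
  mu + sqrt(1 / (4 * j * dt)) * noise
}

#' One Euler-Maruyama step of the CAC Wigner model
#'
#' Mean amplitude, variance and error-feedback update:
#' \deqn{d\mu_r = [-(1-p+j)\mu_r - g^2\mu_r^3 + K\,inj_r]\,dt
#'   + \sqrt{j}(V_r - \tfrac12)\,dW,}
#' a deterministic Euler step of the variance equation, and the
#' multiplicative error update \eqn{de_r = -\beta(g^2\tilde\mu_r^2 -
#' \tau)e_r\,dt} integrated exactly (geometric step), which keeps
#' \eqn{e_r > 0} for any step size. The measured amplitude
#' \eqn{\tilde\mu_r} reuses the same standard-normal draw as the drift
#' noise.
#'
#' @param state List with numeric vectors `mu`, `V`, `e` (length N,
#'   `e > 0`).
#' @param p Pump rate (scalar).
#' @param injection Injection vector, see [cac_injection()].
#' @param cfg A [cim_config()] (uses `g2`, `j`, `K`, `beta`, `tau`, `dt`).
#' @param noise Standard-normal vector of length N.
#' @return List with the updated `state` and the `measured` amplitudes
#'   used in the error update.
#' @export
step_cac_wigner <- function(state, p, injection, cfg, noise) {
  g2 <- cfg$g2; j <- cfg$j; dt <- cfg$dt
  mu <- state$mu; V <- state$V
  mu_t <- measured_amplitude(mu, noise, j, dt)
  mu_new <- mu + (-(1 - p + j) * mu - g2 * mu^3 + cfg$K * injection) * dt +
    sqrt(j) * (V - 0.5) * sqrt(dt) * noise
  V_new <- V + (-2 * (1 - p + j) * V - 6 * g2 * mu^2 * V + 1 + j +
                  2 * g2 * mu^2 - 2 * j * (V - 0.5)^2) * dt
  e_new <- state$e * exp(-cfg$beta * (g2 * mu_t^2 - cfg$tau) * dt)
  list(state = list(mu = mu_new, V = V_new, e = e_new), measured = mu_t)
}

#' One Euler-Maruyama step of the positive-P model
#'
#' Mean amplitude with multiplicative quantum noise
#' \eqn{\sqrt{j}(m_r+n_r)\,dW}, deterministic Euler steps of the two
#' fluctuation-variance equations, and the same measured-amplitude /
#' error-feedback update as [step_cac_wigner()].
#'
#' @param state List with numeric vectors `mu`, `n`, `m`, `e` (length N,
#'   `e > 0`).
#' @inheritParams step_cac_wigner
#' @return List with the updated `state` and the `measured` amplitudes.
#' @export
step_positive_p <- function(state, p, injection, cfg, noise) {
  g2 <- cfg$g2; j <- cfg$j; dt <- cfg$dt
  mu <- state$mu; n <- state$n; m <- state$m
  mu_t <- measured_amplitude(mu, noise, j, dt)
  mu_new <- mu + (-(1 - p + j) * mu - g2 * mu * (mu^2 + 2 * n + m) +
                    cfg$K * injection) * dt +
    sqrt(j) * (m + n) * sqrt(dt) * noise
  n_new <- n + (-2 * (1 + j) * n + 2 * p * m - 2 * g2 * mu^2 * (2 * n + m) -
                  j * (m + n)^2) * dt
  m_new <- m + (-2 * (1 + j) * m + 2 * p * n - 2 * g2 * mu^2 * (2 * m + n) +
                  p - g2 * (mu^2 + m) - j * (m + n)^2) * dt
  e_new <- state$e * exp(-cfg$beta * (g2 * mu_t^2 - cfg$tau) * dt)
  list(state = list(mu = mu_new, n = n_new, m = m_new, e = e_new),
       measured = mu_t)
}

cim_initial_state <- function(model, N) {
  switch(model,
    wigner_ol  = list(c = numeric(N), s = numeric(N)),
    cac_wigner = list(mu = numeric(N), V = rep(0.5, N), e = rep(1, N)),
    positive_p = list(mu = numeric(N), n = numeric(N), m = numeric(N),
                      e = rep(1, N))
  )
}

#' Integrate one CIM trajectory and read out the support
#'
#' Runs `cfg$n_steps` Euler-Maruyama steps of the chosen machine model at
#' a fixed signal estimate `R` and threshold `eta`, recomputing the local
#' field and injection at every step, with the model-appropriate pump
#' schedule (sigmoidal for CAC models, quadratic for the open-loop model;
#' the schedule clock restarts at every call). The support is the
#' Heaviside binarisation of the final measured amplitudes (CAC models)
#' or final in-phase amplitudes (open-loop). Vacuum initial conditions:
#' `c = s = mu = 0`, `V = 1/2`, `n = m = 0`, `e = 1`.
#'
#' @param model `"cac_wigner"`, `"positive_p"` or `"wigner_ol"`.
#' @param problem A [generate_random_cs()] instance, [build_mri_qubo()]
#'   operator set, or anything accepted by [as_qubo()].
#' @param R Signal estimate held fixed during the run (length N).
#' @param eta Support threshold.
#' @param cfg A [cim_config()].
#' @param trajectory If `TRUE`, record per-step summaries (mean
#'   normalised squared amplitude, mean error gain) and, for
#'   `trajectory = "full"`, the full amplitude matrix.
#' @param seed Optional integer seed (defaults to `cfg$seed`).
#' @return An object of class `cim_run`: list with `sigma` (0/1 support),
#'   `amplitudes` (final `mu_tilde` or `c`), `state`, `model`, and
#'   optionally `trace` (a tibble with columns `step`, `time`, `pump`,
#'   `mean_g2mu2`, `mean_e`).
#' @export
run_cim <- function(model = c("cac_wigner", "positive_p", "wigner_ol"),
                    problem, R, eta, cfg = cim_config(),
                    trajectory = FALSE, seed = cfg$seed) {
  model <- match.arg(model)
  q <- as_qubo(problem)
  N <- q$N
  stopifnot(length(R) == N, eta >= 0)
  if (!is.null(seed)) set.seed(seed)

  g2 <- cfg$g2; tau <- cfg$tau; dt <- cfg$dt
  s_amp <- sqrt(tau / g2)
  scaled_z <- s_amp * q$z
  state <- cim_initial_state(model, N)
  keep_trace <- !isFALSE(trajectory)
  full_trace <- identical(trajectory, "full")
  if (keep_trace) {
    tr_g2mu2 <- tr_e <- tr_p <- numeric(cfg$n_steps)
    if (full_trace) tr_amp <- matrix(NA_real_, cfg$n_steps, N)
  }
  amplitudes <- numeric(N)

  for (step in seq_len(cfg$n_steps)) {
    t_now <- (step - 1) * dt
    if (model == "wigner_ol") {
      p <- pump_schedule_ol(t_now)
      h <- local_field_op(q, R * binarise(state$c), q$z)
      inj <- ol_injection(h, eta)
      state <- step_wigner_ol(state, p, inj, cfg, rnorm(N), rnorm(N))
      amplitudes <- state$c
      if (keep_trace) {
        tr_g2mu2[step] <- mean(state$c^2); tr_e[step] <- NA_real_
        tr_p[step] <- p
        if (full_trace) tr_amp[step, ] <- state$c
      }
    } else {
      p <- pump_schedule_cac(t_now, cfg$p_thr, cfg$d)
      w <- rnorm(N)
      mu_t <- measured_amplitude(state$mu, w, cfg$j, dt)
      h <- local_field_op(q, R * (mu_t + s_amp) / 2, scaled_z)
      inj <- cac_injection(h, R, state$e, eta, tau, g2, cfg$j)
      stepped <- if (model == "cac_wigner") {
        step_cac_wigner(state, p, inj, cfg, w)
      } else {
        step_positive_p(state, p, inj, cfg, w)
      }
      state <- stepped$state
      amplitudes <- stepped$measured
      if (keep_trace) {
        tr_g2mu2[step] <- mean(g2 * stepped$measured^2)
        tr_e[step] <- mean(state$e)
        tr_p[step] <- p
        if (full_trace) tr_amp[step, ] <- sqrt(g2) * stepped$measured
      }
    }
    if (!all(vapply(state, function(v) all(is.finite(v)), logical(1)))) {
      stop("CIM integration diverged at step ", step)
    }
  }

  out <- list(sigma = binarise(amplitudes), amplitudes = amplitudes,
              state = state, model = model, eta = eta, cfg = cfg)
  if (keep_trace) {
    out$trace <- tibble::tibble(
      step = seq_len(cfg$n_steps), time = (seq_len(cfg$n_steps) - 1) * dt,
      pump = tr_p, mean_g2mu2 = tr_g2mu2, mean_e = tr_e
    )
    if (full_trace) out$amplitude_trace <- tr_amp
  }
  structure(out, class = "cim_run")
}

#' @export
print.cim_run <- function(x, ...) {
  cat(sprintf("<cim_run> model = %s, N = %d, |support| = %d, eta = %.4g\n",
              x$model, length(x$sigma), sum(x$sigma), x$eta))
  invisible(x)
}

#' Trajectory plot of a CIM run
#'
#' Plots the per-step mean normalised squared measured amplitude
#' \eqn{g^2\tilde\mu^2} (with the CAC target \eqn{\tau} as a reference
#' line) and, for CAC models, the mean error gain, against time. Requires
#' the run to have been made with `trajectory = TRUE`.
#'
#' @param object A `cim_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cim_run <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("run_cim() must be called with trajectory = TRUE to plot traces")
  }
  df <- tidyr::pivot_longer(object$trace, c("mean_g2mu2", "mean_e"),
                            names_to = "series", values_to = "value")
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::geom_hline(
      data = data.frame(series = "mean_g2mu2", tau = object$cfg$tau),
      ggplot2::aes(yintercept = .data$tau), linetype = "dashed"
    ) +
    ggplot2::labs(x = "time (photon lifetimes)", y = NULL,
                  title = paste("CIM trajectory:", object$model))
}
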