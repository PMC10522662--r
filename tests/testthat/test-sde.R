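test_that("noise-free open-loop Wigner dynamics sit at and converge to c = sqrt(p-1)", {
  cfg <- cim_config(dt = 0.02, n_steps = 1)
  # exact fixed point is unchanged by one deterministic step
  st <- list(c = 1, s = 0)
  out <- step_wigner_ol(st, p = 2, injection = 0, cfg, noise_c = 0, noise_s = 0)
  expect_equal(out$c, 1)
  expect_equal(out$s, 0)
  # pure injection drift from the origin
  out <- step_wigner_ol(list(c = 0, s = 0), p = 0, injection = 3, cfg, 0, 0)
  expect_equal(out$c, cfg$K_tilde * 3 * cfg$dt)
  # convergence from a generic start, long deterministic integration
  st <- list(c = 0.05, s = 0.3)
  for (k in 1:4000) st <- step_wigner_ol(st, p = 2, injection = 0, cfg, 0, 0)
  expect_equal(st$c, 1, tolerance = 1e-6)
  expect_equal(abs(st$s), 0, tolerance = 1e-6)
})

test_that("one open-loop step reproduces an independent elementwise evaluation", {
  cfg <- cim_config(g2 = 4e-2, K_tilde = 0.25, dt = 0.1)
  st <- list(c = c(0.3, -0.2), s = c(0.1, 0.4))
  out <- step_wigner_ol(st, p = 1.2, injection = c(0.5, -0.1), cfg,
                        noise_c = c(0.7, -1.1), noise_s = c(0.2, 0.9))
  for (r in 1:2) {
    amp2 <- st$c[r]^2 + st$s[r]^2
    expect_equal(out$c[r],
      st$c[r] + ((-1 + 1.2 - amp2) * st$c[r] + 0.25 * c(0.5, -0.1)[r]) * 0.1 +
        0.2 * sqrt(amp2 + 0.5) * sqrt(0.1) * c(0.7, -1.1)[r],
      tolerance = 1e-14)
    expect_equal(out$s[r],
      st$s[r] + ((-1 - 1.2 - amp2) * st$s[r]) * 0.1 +
        0.2 * sqrt(amp2 + 0.5) * sqrt(0.1) * c(0.2, 0.9)[r],
      tolerance = 1e-14)
  }
})

test_that("CAC Wigner step matches the update formulas and error-feedback sign", {
  cfg <- cim_config(g2 = 1e-2, j = 2, K = 0.3, beta = 0.5, tau = 1.5, dt = 0.05)
  st <- list(mu = c(2, -4), V = c(0.6, 0.45), e = c(1, 3))
  w <- c(0.8, -0.3)
  out <- step_cac_wigner(st, p = 0.9, injection = c(1, -2), cfg, noise = w)
  for (r in 1:2) {
    mu_t <- st$mu[r] + sqrt(1 / (4 * 2 * 0.05)) * w[r]
    expect_equal(out$measured[r], mu_t, tolerance = 1e-14)
    expect_equal(out$state$mu[r],
      st$mu[r] + (-(1 - 0.9 + 2) * st$mu[r] - 1e-2 * st$mu[r]^3 +
                    0.3 * c(1, -2)[r]) * 0.05 +
        sqrt(2) * (st$V[r] - 0.5) * sqrt(0.05) * w[r],
      tolerance = 1e-13)
    expect_equal(out$state$V[r],
      st$V[r] + (-2 * (1 - 0.9 + 2) * st$V[r] - 6e-2 * st$mu[r]^2 * st$V[r] +
                   1 + 2 + 2e-2 * st$mu[r]^2 - 2 * 2 * (st$V[r] - 0.5)^2) * 0.05,
      tolerance = 1e-13)
    expect_equal(out$state$e[r],
      st$e[r] * exp(-0.5 * (1e-2 * mu_t^2 - 1.5) * 0.05),
      tolerance = 1e-13)
  }
  # amplitude exactly at target: error gain unchanged
  cfg2 <- cim_config(g2 = 1, j = 1, tau = 4, dt = 0.1)
  st2 <- list(mu = 2, V = 0.5, e = 7)
  out2 <- step_cac_wigner(st2, p = 1, injection = 0, cfg2, noise = 0)
  expect_equal(out2$state$e, 7)
  # amplitude below target: error grows strictly (noise-free)
  st3 <- list(mu = 0.5, V = 0.5, e = 7)
  expect_gt(step_cac_wigner(st3, 1, 0, cfg2, 0)$state$e, 7)
})

test_that("positive-P step matches the update formulas and preserves the origin", {
  cfg <- cim_config(g2 = 1e-2, j = 1, K = 0.2, beta = 0.4, tau = 1, dt = 0.05)
  # origin with p = 0 is a fixed point of the deterministic flow
  st0 <- list(mu = 0, n = 0, m = 0, e = 1)
  out0 <- step_positive_p(st0, p = 0, injection = 0, cfg, noise = 0)
  expect_equal(out0$state$mu, 0)
  expect_equal(out0$state$n, 0)
  expect_equal(out0$state$m, 0)
  # generic one-step check against elementwise evaluation
  st <- list(mu = c(1.5, -2), n = c(0.2, 0.05), m = c(0.1, 0.3), e = c(2, 0.5))
  w <- c(-0.4, 1.2)
  out <- step_positive_p(st, p = 1.1, injection = c(0.3, -0.6), cfg, noise = w)
  for (r in 1:2) {
    mu <- st$mu[r]; n <- st$n[r]; m <- st$m[r]
    expect_equal(out$state$mu[r],
      mu + (-(1 - 1.1 + 1) * mu - 1e-2 * mu * (mu^2 + 2 * n + m) +
              0.2 * c(0.3, -0.6)[r]) * 0.05 +
        1 * (m + n) * sqrt(0.05) * w[r],
      tolerance = 1e-13)
    expect_equal(out$state$n[r],
      n + (-2 * 2 * n + 2 * 1.1 * m - 2e-2 * mu^2 * (2 * n + m) -
             (m + n)^2) * 0.05,
      tolerance = 1e-13)
    expect_equal(out$state$m[r],
      m + (-2 * 2 * m + 2 * 1.1 * n - 2e-2 * mu^2 * (2 * m + n) + 1.1 -
             1e-2 * (mu^2 + m) - (m + n)^2) * 0.05,
      tolerance = 1e-13)
  }
  # symmetric fluctuations: d(n - m) = -(2(1+j) + 2p)(n - m) - (p - g2(mu^2+m))
  st_nm <- list(mu = c(1), n = c(0.2), m = c(0.2), e = 1)
  out_nm <- step_positive_p(st_nm, p = 0.8, injection = 0, cfg, noise = 0)
  dn_dm <- (out_nm$state$n - out_nm$state$m) / 0.05
  expect_equal(dn_dm, -(0.8 - 1e-2 * (1 + 0.2)), tolerance = 1e-12)
})

test_that("error gains stay strictly positive along stochastic runs", {
  p <- generate_random_cs(40, 0.6, 0.4, seed = 21)
  R <- p$x_true * p$xi_true
  for (model in c("cac_wigner", "positive_p")) {
    cfg <- cim_preset(model, "artificial", n_steps = 300)
    run <- run_cim(model, p, R, eta = 0.05, cfg, seed = 22)
    expect_true(all(run$state$e > 0))
  }
})

test_that("CAC stabilises the measured amplitude near the target", {
  p <- generate_random_cs(100, 0.6, 0.6, seed = 23)
  R <- p$x_true * p$xi_true
  cfg <- cim_preset("cac_wigner", "artificial")
  run <- run_cim("cac_wigner", p, R, eta = 0.05, cfg, trajectory = TRUE, seed = 24)
  second_half <- mean(run$trace$mean_g2mu2[(cfg$n_steps / 2 + 1):cfg$n_steps])
  expect_gt(second_half, 0.5 * cfg$tau)
  expect_lt(second_half, 1.5 * cfg$tau)
})

test_that("Wigner and positive-P supports agree on matched seeds", {
  p <- generate_random_cs(150, 0.6, 0.6, seed = 25)
  R <- p$x_true * p$xi_true
  cfg <- cim_preset("cac_wigner", "artificial")
  rw <- run_cim("cac_wigner", p, R, 0.05, cfg, seed = 26)
  rp <- run_cim("positive_p", p, R, 0.05, cfg, seed = 26)
  expect_gte(mean(rw$sigma == rp$sigma), 0.9)
})

test_that("runs are reproducible bit-for-bit at a fixed seed", {
  p <- generate_random_cs(30, 0.6, 0.4, seed = 27)
  cfg <- cim_preset("cac_wigner", "artificial", n_steps = 100)
  r1 <- run_cim("cac_wigner", p, p$x_true * p$xi_true, 0.05, cfg, seed = 28)
  r2 <- run_cim("cac_wigner", p, p$x_true * p$xi_true, 0.05, cfg, seed = 28)
  expect_identical(r1$amplitudes, r2$amplitudes)
  expect_identical(r1$sigma, r2$sigma)
})
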