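test_that("a decoupled problem is solved exactly in one alternating iteration", {
  # orthonormal observation matrix, noise-free, threshold below every
  # matched-filter magnitude on the true support: support and values are
  # recovered exactly
  set.seed(71)
  Q <- qr.Q(qr(matrix(rnorm(400), 20, 20)))
  x <- numeric(20); x[c(3, 8, 15)] <- c(1.5, -2, 1)
  xi <- as.numeric(x != 0)
  prob <- structure(
    list(A = Q, y = as.vector(Q %*% x), x_true = x, xi_true = xi, N = 20),
    class = "cs_problem"
  )
  cfg <- cim_preset("cac_wigner", "artificial", eta_init = 0.3, eta_end = 0.3)
  fit <- run_hybrid(prob, "cac_wigner", n_iters = 1, cfg = cfg,
                    cdp = "cgd", seed = 72)
  expect_equal(fit$sigma, xi)
  expect_equal(glance(fit)$rmse, 0, tolerance = 1e-8)
})

test_that("the least-squares stage never increases the residual at fixed support", {
  set.seed(73)
  p <- generate_random_cs(60, 0.6, 0.3)
  q <- as_qubo(p)
  sigma <- p$xi_true
  R0 <- rnorm(60) * sigma
  res0 <- 0.5 * sum((p$y - p$A %*% R0)^2)
  sol <- solve_cgd(q, sigma = sigma, R_init = R0)
  expect_lte(0.5 * sum((p$y - p$A %*% sol$R)^2), res0 + 1e-12)
})

test_that("hybrid recovery succeeds well inside the L0-recoverable regime", {
  # N = 200, alpha = 0.6, a = 0.2, noise-free, annealed threshold
  ok <- 0
  for (s in 1:5) {
    p <- generate_random_cs(200, 0.6, 0.2, seed = 700 + s)
    cfg <- cim_preset("cac_wigner", "artificial",
                      eta_init = 0.6, eta_end = 0.18)
    fit <- run_hybrid(p, "cac_wigner", n_iters = 51, cfg = cfg,
                      cdp = "jacobi", seed = 800 + s)
    if (glance(fit)$rmse < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("tidy/glance expose the per-iteration log and final summary", {
  p <- generate_random_cs(40, 0.6, 0.3, seed = 74)
  cfg <- cim_preset("cac_wigner", "artificial", n_steps = 100,
                    eta_init = 0.4, eta_end = 0.2, velo = 5)
  fit <- run_hybrid(p, "cac_wigner", n_iters = 4, cfg = cfg, seed = 75)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_named(td, c("iteration", "eta", "support_size", "hamiltonian",
                     "direction_cosine", "rmse"))
  expect_equal(td$eta, threshold_schedule(0:3, 0.4, 0.2, 5))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$hamiltonian, td$hamiltonian[4])
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the machine-chosen support reaches the exhaustive optimum on small instances", {
  hits <- 0
  for (s in 1:10) {
    p <- small_instance(seed = 900 + s, N = 12)
    R <- p$x_true * p$xi_true
    lam <- 0.05^2 / 2
    truth <- bf_exhaustive_min(p$A, p$y, R, lam)
    cfg <- cim_preset("cac_wigner", "artificial")
    run <- run_cim("cac_wigner", p, R, eta = 0.05, cfg, seed = 1000 + s)
    H_cim <- qubo_hamiltonian(R, run$sigma, p$A, p$y, lambda = lam)
    if (H_cim <= truth$H + 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 7)
})
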