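test_that("incremental delta-H bookkeeping equals full re-evaluation", {
  set.seed(51)
  p <- generate_random_cs(25, 0.7, 0.4)
  R <- rnorm(25)
  lam <- 0.02
  sch <- anneal_schedule("exponential", n_steps = 400)
  res <- sa_metropolis(p, R, lam, sch, seed = 52, history = TRUE)
  recomputed <- qubo_hamiltonian(R, res$sigma, p$A, p$y, lambda = lam)
  expect_equal(res$hamiltonian, recomputed, tolerance = 1e-9)
})

test_that("zero-temperature annealing is greedy on a decoupled problem", {
  # orthonormal columns: spins decouple; sigma_r = 1 iff the matched-filter
  # energy gain 0.5 R_r^2 d_r - R_r z_r exceeds -lambda ... i.e. flips
  # converge to the elementwise minimiser
  set.seed(53)
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  y <- rnorm(8)
  R <- as.vector(crossprod(Q, y))       # exact per-spin values
  lam <- 0.01
  sch <- anneal_schedule("zero_temperature", n_steps = 800)
  res <- sa_metropolis(structure(list(A = Q, y = y), class = "cs_problem"),
                       R, lam, sch, seed = 54)
  want <- as.numeric(0.5 * R^2 - R * as.vector(crossprod(Q, y)) + lam < 0)
  expect_equal(res$sigma, want)
})

test_that("zero-temperature energy trace is non-increasing", {
  set.seed(55)
  p <- generate_random_cs(30, 0.6, 0.5)
  res <- sa_metropolis(p, rnorm(30), 0.01,
                       anneal_schedule("zero_temperature", n_steps = 500),
                       seed = 56, history = TRUE)
  expect_true(all(diff(res$energy_trace) <= 1e-12))
})

test_that("long annealing reaches the exhaustive ground state on small instances", {
  hits <- 0
  for (s in 1:10) {
    p <- small_instance(seed = 500 + s, N = 12)
    R <- p$x_true * p$xi_true
    lam <- 0.05^2 / 2
    truth <- bf_exhaustive_min(p$A, p$y, R, lam)
    res <- sa_metropolis(p, R, lam,
                         anneal_schedule("exponential", 0.02, 2e-5, 4000),
                         seed = 600 + s)
    if (res$hamiltonian <= truth$H + 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("FISTA reproduces the closed-form solutions", {
  # lam1 = 0 with orthonormal columns: least squares = matched filter
  set.seed(57)
  Q <- qr.Q(qr(matrix(rnorm(60), 10, 6)))
  y <- rnorm(10)
  fit <- lasso_fista(Q, y, lam1 = 0, tol = 1e-12)
  expect_equal(fit$x, as.vector(crossprod(Q, y)), tolerance = 1e-6)
  # lam1 above the null threshold kills the solution
  A <- matrix(rnorm(40), 8, 5)
  y2 <- rnorm(8)
  lam_max <- max(abs(crossprod(A, y2)))
  expect_equal(lasso_fista(A, y2, lam1 = lam_max * 1.001)$x, rep(0, 5))
  # scalar problem: soft threshold
  a1 <- matrix(2, 1, 1)
  fit1 <- lasso_fista(a1, 3, lam1 = 1, tol = 1e-14)
  expect_equal(fit1$x, (2 * 3 - 1) / 4, tolerance = 1e-8)
})

test_that("FISTA objective decreases and matches glmnet on a dense problem", {
  skip_if_not_installed("glmnet")
  set.seed(58)
  M <- 40; N <- 20
  A <- matrix(rnorm(M * N, sd = sqrt(1 / M)), M, N)
  x0 <- numeric(N); x0[1:4] <- c(2, -1.5, 1, 3)
  y <- as.vector(A %*% x0) + rnorm(M, sd = 0.05)
  lam1 <- 0.02
  fit <- lasso_fista(A, y, lam1 = lam1, tol = 1e-12, max_iter = 20000)
  expect_true(all(diff(fit$objective) <= 1e-10))
  gl <- glmnet::glmnet(A, y, lambda = lam1 / M, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  xg <- as.vector(gl$beta)
  obj <- function(x) 0.5 * sum((y - A %*% x)^2) + lam1 * sum(abs(x))
  expect_equal(obj(fit$x), obj(xg), tolerance = 1e-6)
  expect_equal(fit$x, xg, tolerance = 1e-3)
})
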