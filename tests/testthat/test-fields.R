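test_that("binarisation maps positives to 1 and the boundary to 0", {
  expect_equal(binarise(c(0.3, -0.3, 0, 1e-12)), c(1, 0, 0, 1))
  expect_error(binarise(c(1, NA)))
})

test_that("open-loop local field matches the brute-force double loop", {
  # listed small instance
  A <- matrix(c(0.6, -0.2, 0.1, 0.5, -0.4, 0.3), nrow = 2)
  y <- c(0.9, -0.3)
  R <- c(1.2, -0.7, 0.4)
  cvec <- c(0.5, -0.1, 0.2)
  expect_equal(ol_local_field(cvec, R, A, y), bf_ol_field(cvec, R, A, y),
               tolerance = 1e-12)
  # random instances, N <= 20
  set.seed(11)
  for (k in 1:5) {
    p <- generate_random_cs(sample(5:20, 1), 0.7, 0.5)
    cvec <- rnorm(p$N); R <- rnorm(p$N)
    expect_equal(ol_local_field(cvec, R, p$A, p$y),
                 bf_ol_field(cvec, R, p$A, p$y), tolerance = 1e-10)
  }
  # A = 0 kills everything; c <= 0 leaves the pure matched filter
  A0 <- matrix(0, 2, 3)
  expect_equal(ol_local_field(cvec <- c(1, 1, 1), R = rnorm(3), A0, y), rep(0, 3))
  p <- generate_random_cs(10, 0.6, 0.5, seed = 2)
  expect_equal(ol_local_field(rep(-1, 10), rnorm(10), p$A, p$y),
               as.vector(crossprod(p$A, p$y)), tolerance = 1e-12)
})

test_that("open-loop injection thresholds the absolute field", {
  expect_equal(ol_injection(c(0.1, -0.3, 0), 0.1), c(0, 0.2, -0.1))
})

test_that("CAC local field matches the brute-force double loop and degenerate cases", {
  tau <- 1; g2 <- 1e-7; s <- sqrt(tau / g2)
  A <- matrix(c(0.6, -0.2, 0.1, 0.5, -0.4, 0.3), nrow = 2)
  y <- c(0.9, -0.3)
  R <- c(1.2, -0.7, 0.4)
  mu_t <- c(0.8, -0.5, 0.3) * s
  expect_equal(cac_local_field(mu_t, R, A, y, tau = tau, g2 = g2),
               bf_cac_field(mu_t, R, A, y, tau, g2), tolerance = 1e-7)
  set.seed(12)
  for (k in 1:5) {
    p <- generate_random_cs(sample(5:20, 1), 0.7, 0.5)
    mu_t <- rnorm(p$N, sd = s); R <- rnorm(p$N)
    got <- cac_local_field(mu_t, R, p$A, p$y, tau = tau, g2 = g2)
    want <- bf_cac_field(mu_t, R, p$A, p$y, tau, g2)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # amplitudes parked at -sqrt(tau/g2) annihilate the interaction term
  p <- generate_random_cs(10, 0.6, 0.5, seed = 13)
  h <- cac_local_field(rep(-s, 10), rnorm(10), p$A, p$y, tau = tau, g2 = g2)
  expect_equal(h, s * as.vector(crossprod(p$A, p$y)), tolerance = 1e-9 * s)
})

test_that("CAC injection combines error gain, field drive and threshold", {
  expect_equal(cac_injection(h = c(1, 2), R = c(1, 1), e = c(0, 0),
                             eta = 0.1, tau = 1, g2 = 1, j = 1), c(0, 0))
  # threshold cancellation: R h = (eta^2/2) sqrt(tau/g2)
  eta <- 0.3; tau <- 2; g2 <- 1e-4
  hval <- (eta^2 / 2) * sqrt(tau / g2)
  expect_equal(cac_injection(hval, 1, e = 5, eta, tau, g2, j = 2), 0)
  expect_equal(cac_injection(h = 1, R = 1, e = 2, eta = 0, tau = 1, g2 = 1, j = 1), 2)
})

test_that("CDP local field matches the brute-force double loop", {
  set.seed(14)
  p <- generate_random_cs(15, 0.6, 0.4)
  R <- rnorm(15)
  sigma <- as.numeric(runif(15) < 0.5)
  expect_equal(cdp_local_field(R, sigma, p$A, p$y),
               bf_cdp_field(R, sigma, p$A, p$y), tolerance = 1e-10)
  expect_equal(cdp_local_field(R, rep(0, 15), p$A, p$y),
               as.vector(crossprod(p$A, p$y)), tolerance = 1e-12)
})
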