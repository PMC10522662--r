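# Independent brute-force oracles, written directly from the elementwise
# definitions (O(N^2 M) double loops, 2^N enumeration). Deliberately slow
# and simple; never share code with the implementation.

bf_ol_field <- function(c, R, A, y) {
  N <- ncol(A)
  h <- numeric(N)
  for (r in seq_len(N)) {
    acc <- 0
    for (rp in seq_len(N)) {
      if (rp == r) next
      acc <- acc + sum(A[, r] * A[, rp]) * R[rp] * as.numeric(c[rp] > 0)
    }
    h[r] <- -acc + sum(A[, r] * y)
  }
  h
}

bf_cac_field <- function(mu_t, R, A, y, tau, g2) {
  N <- ncol(A)
  s <- sqrt(tau / g2)
  h <- numeric(N)
  for (r in seq_len(N)) {
    acc <- 0
    for (rp in seq_len(N)) {
      if (rp == r) next
      acc <- acc + sum(A[, r] * A[, rp]) * R[rp] * 0.5 * (mu_t[rp] + s)
    }
    h[r] <- -acc + s * sum(A[, r] * y)
  }
  h
}

bf_cdp_field <- function(R, sigma, A, y) {
  N <- ncol(A)
  h <- numeric(N)
  for (r in seq_len(N)) {
    acc <- 0
    for (rp in seq_len(N)) {
      if (rp == r) next
      acc <- acc + sum(A[, r] * A[, rp]) * R[rp] * sigma[rp]
    }
    h[r] <- -acc + sum(A[, r] * y)
  }
  h
}

bf_hamiltonian <- function(R, sigma, A, y, lam) {
  N <- ncol(A)
  acc <- 0
  if (N >= 2) {
    for (r in seq_len(N - 1)) {
      for (rp in (r + 1):N) {
        acc <- acc + sum(A[, r] * A[, rp]) * R[r] * R[rp] * sigma[r] * sigma[rp]
      }
    }
  }
  zee <- 0
  for (r in seq_len(N)) zee <- zee + sum(y * A[, r]) * R[r] * sigma[r]
  acc - zee + lam * sum(sigma)
}

# exhaustive ground-state search over all 2^N supports at fixed R, against
# the pairwise (self-interaction-free) Hamiltonian the machines minimise
bf_exhaustive_min <- function(A, y, R, lam) {
  N <- ncol(A)
  dg <- colSums(A^2)
  best <- Inf
  best_sigma <- numeric(N)
  for (code in 0:(2^N - 1)) {
    sigma <- as.numeric(bitwAnd(code, 2^(seq_len(N) - 1)) > 0)
    v <- R * sigma
    H <- 0.5 * sum((y - A %*% v)^2) - 0.5 * sum(y^2) - 0.5 * sum(dg * v^2) +
      lam * sum(sigma)
    if (H < best) {
      best <- H
      best_sigma <- sigma
    }
  }
  list(H = best, sigma = best_sigma)
}

small_instance <- function(seed = 42, N = 12, alpha = 0.6, a = 0.4, nu = 0) {
  generate_random_cs(N, alpha, a, nu, seed = seed)
}
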