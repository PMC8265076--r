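# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: naive loops, dense linear algebra, step-by-step
# textbook procedures.

# closed-form ordinary least squares
ols_oracle <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)
}

# naive loop simulation of the two-phase AR(1) residual process: stationary
# pre-phase start, innovations switch to the post parameters at t = tau
sim_two_phase_ar1 <- function(n, tau, phi1, phi2, s2w1, s2w2) {
  r <- numeric(n)
  r[1] <- rnorm(1, 0, sqrt(s2w1 / (1 - phi1^2)))
  for (t in 2:n) {
    if (t <= tau - 1) r[t] <- phi1 * r[t - 1] + rnorm(1, 0, sqrt(s2w1))
    else r[t] <- phi2 * r[t - 1] + rnorm(1, 0, sqrt(s2w2))
  }
  r
}

# textbook step-up Benjamini-Hochberg: sort, p * m / rank, enforce
# monotonicity from the largest down, cap at 1, restore input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) ps[i] <- min(ps[i], ps[i + 1])
  ps <- pmin(ps, 1)
  out <- numeric(m)
  out[o] <- ps
  out
}

# random symmetric positive definite matrix
rand_spd <- function(k) {
  A <- matrix(rnorm(k * k), k)
  crossprod(A) + diag(k)
}

# a small multi-unit dataset with a known change-point, used by several files
make_test_dataset <- function(N = 2, n = 60, tau = 30, delta = 4,
                              Delta = 0, phi = 0.3, seed = 123) {
  sc <- rits_scenario(N = N, n = n, tau = tau,
                      mean = segmented_mean(10, 0.05, delta = delta,
                                            Delta = Delta),
                      noise = noise_params("ar1", phi, phi, 1, 1))
  simulate_its(sc, seed = seed)
}
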