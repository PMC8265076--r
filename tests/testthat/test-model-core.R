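test_that("segmented design encodes the piecewise mean", {
  X <- segmented_design(3, 2)
  expect_equal(unname(X),
               rbind(c(1, 1, 0, 0), c(1, 2, 1, 2), c(1, 3, 1, 3)))

  # tau = n: only the last row carries the post indicator
  X5 <- segmented_design(5, 5)
  expect_equal(unname(X5[, 3]), c(0, 0, 0, 0, 1))
  # tau = n + 1 is the null design (indicator never fires)...
  X6 <- segmented_design(5, 6)
  expect_equal(unname(X6[, 3:4]), matrix(0, 5, 2))
  expect_equal(unname(X6[, 1:2]), unname(cbind(1, 1:5)))
  # ...and anything beyond is rejected, as is tau <= 1
  expect_error(segmented_design(5, 7), "out of range")
  expect_error(segmented_design(5, 1), "out of range")

  # indicator column counts the post-phase ticks (brute-force count)
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    tau <- sample(2:n, 1)
    expect_equal(sum(segmented_design(n, tau)[, 3]),
                 sum(vapply(1:n, function(t) t >= tau, logical(1))))
  }

  # X %*% params reproduces mean_function at every tick
  p <- segmented_mean(3, -0.2, 1, 0.1)
  expect_equal(drop(segmented_design(10, 5) %*% as.numeric(p)),
               mean_function(p, 1:10, 5))
})

test_that("mean function branches at the change-point", {
  expect_equal(mean_function(segmented_mean(1, 0, 0, 0), 7, 3), 1)
  expect_equal(mean_function(segmented_mean(0, 1, 2, 0.5), 10, 10), 17)
  expect_equal(mean_function(segmented_mean(3, -0.2, 1, 0.1), 4, 5), 2.2)
  expect_error(mean_function(segmented_mean(), 0, 3), ">= 1")
})

test_that("level and trend change match their definitions", {
  expect_equal(level_change(segmented_mean(0, 0, 2, 0.5), 10), 7)
  expect_equal(level_change(segmented_mean(5, 1, 0, 0), 17), 0)
  expect_equal(trend_change(segmented_mean(0, 0, 0, 0.5)), 0.5)
  expect_equal(trend_change(segmented_mean(1, 2, 3, 0)), 0)

  # identities over random draws: level change is the jump between the
  # projected pre mean and the post mean at tau; trend change the slope gap
  set.seed(42)
  for (rep in 1:25) {
    p <- segmented_mean(rnorm(1), rnorm(1), rnorm(1), rnorm(1))
    tau <- sample(2:50, 1)
    post_at_tau <- mean_function(p, tau, tau)
    pre_proj <- p[["beta0"]] + p[["beta1"]] * tau
    expect_equal(level_change(p, tau), post_at_tau - pre_proj)
    expect_equal(trend_change(p),
                 (p[["beta1"]] + p[["Delta"]]) - p[["beta1"]])
    # re-indexing t -> t + c shifts the level change by Delta * c
    cc <- sample(1:10, 1)
    expect_equal(level_change(p, tau + cc) - level_change(p, tau),
                 p[["Delta"]] * cc)
  }
})

test_that("marginal variance closed forms hold and grow with |phi|", {
  expect_equal(marginal_variance(noise_params("ar1", 0, 0, 2, 2), 1), 2)
  expect_equal(marginal_variance(noise_params("ar1", 0.6, 0, 1, 1), 1), 1.5625)
  expect_equal(marginal_variance(noise_params("ar1", 0, 0.5, 1, 3), 2), 4)
  expect_equal(marginal_variance(noise_params("independent",
                                              sigma2_w1 = 7), 1), 7)
  expect_equal(marginal_variance(noise_params("exchangeable", 0.4, 0.4,
                                              2.5, 2.5), 2), 2.5)

  phis <- seq(0, 0.95, by = 0.05)
  v <- vapply(phis, function(p)
    marginal_variance(noise_params("ar1", p, p, 1, 1), 1), numeric(1))
  expect_true(all(diff(v) > 0))
  vneg <- vapply(-phis, function(p)
    marginal_variance(noise_params("ar1", p, p, 1, 1), 1), numeric(1))
  expect_equal(v, vneg)
  expect_error(noise_params("ar1", 1.0, 0, 1, 1), "inside")
})

test_that("whitening is identity for unit white noise and switches phase at tau", {
  L <- whitening_matrix(noise_params("ar1", 0, 0, 1, 1), 8, 4)
  expect_equal(L, diag(8))

  nz <- noise_params("ar1", 0.5, -0.3, 2, 0.5)
  n <- 9; tau <- 5
  L <- whitening_matrix(nz, n, tau)
  # row tau regresses on r[tau-1] with the POST parameters
  expect_equal(L[tau, tau], 1 / sqrt(nz$sigma2_w2))
  expect_equal(L[tau, tau - 1], -nz$phi2 / sqrt(nz$sigma2_w2))
  # last pre-phase innovation row still uses the pre parameters
  expect_equal(L[tau - 1, tau - 1], 1 / sqrt(nz$sigma2_w1))
  expect_equal(L[tau - 1, tau - 2], -nz$phi1 / sqrt(nz$sigma2_w1))
  # first row scales by the inverse pre-phase marginal sd
  expect_equal(L[1, 1], 1 / sqrt(marginal_variance(nz, 1)))
})

test_that("whitening decorrelates the simulated two-phase process", {
  # Monte-Carlo covariance oracle: naive-loop simulation at n = 6
  set.seed(7)
  n <- 6; tau <- 4
  nz <- noise_params("ar1", 0.6, -0.4, 1, 2.5)
  reps <- 100000
  R <- t(replicate(reps, sim_two_phase_ar1(n, tau, nz$phi1, nz$phi2,
                                           nz$sigma2_w1, nz$sigma2_w2)))
  L <- whitening_matrix(nz, n, tau)
  S <- L %*% cov(R) %*% t(L)
  expect_lt(max(abs(S - diag(n))), 0.03)
})

test_that("whitening composed with its inverse reconstructs the residuals", {
  set.seed(11)
  for (structure in c("ar1", "exchangeable", "independent")) {
    for (rep in 1:5) {
      # exchangeable correlations must stay above -1/(m-1); keep them >= 0
      phi <- if (structure == "independent") c(0, 0)
             else if (structure == "exchangeable") runif(2, 0, 0.8)
             else runif(2, -0.8, 0.8)
      nz <- noise_params(structure, phi[1], phi[2],
                         runif(1, 0.2, 3), runif(1, 0.2, 3))
      n <- sample(8:40, 1)
      tau <- sample(4:(n - 2), 1)
      r <- rnorm(n)
      L <- whitening_matrix(nz, n, tau)
      expect_equal(drop(solve(L, L %*% r)), r, tolerance = 1e-10)
    }
  }
})

test_that("containers validate their invariants", {
  expect_error(unit_series("A", 1:5, c(1, 2, NA, 4, 5)), "missing")
  expect_error(unit_series("A", c(1, 2, 2, 3), 1:4), "increasing")
  expect_error(unit_series("A", c(1, 2, 5, 6), 1:4), "evenly spaced")
  u1 <- unit_series("A", 1:10, rnorm(10))
  u2 <- unit_series("B", 2:11, rnorm(10))
  expect_error(its_dataset(list(u1, u2)), "common time grid")
  expect_error(its_dataset(list(u1, u1)), "duplicate")
  d <- its_dataset(list(u1))
  expect_equal(d$N, 1L)
  expect_error(its_dataset(list(u1), intervention = 99), "outside")

  expect_error(candidate_set(integer(0), 20), "empty")
  expect_error(candidate_set(c(3, 10), 20), "inadmissible")
  cs <- candidate_set(c(10, 5, 10), 20)
  expect_equal(cs$indices, c(5L, 10L))
})
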