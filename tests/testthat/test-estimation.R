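test_that("GLS reduces to OLS under identity weights and solves the normal equations", {
  set.seed(21)
  n <- 40; tau <- 18
  X <- segmented_design(n, tau)
  y <- rnorm(n, mean = 5)
  f <- gls_fit(y, X)
  expect_equal(unname(f$coefficients), drop(unname(ols_oracle(y, X))),
               tolerance = 1e-10)
  expect_equal(f$cov, solve(t(X) %*% X), tolerance = 1e-10,
               ignore_attr = TRUE)

  # exact recovery of a noiseless signal under any valid whitening
  beta_star <- c(2, -0.5, 3, 0.25)
  y0 <- drop(X %*% beta_star)
  for (nz in list(noise_params("ar1", 0.7, -0.2, 0.5, 2),
                  noise_params("independent", sigma2_w1 = 2, sigma2_w2 = 0.1))) {
    L <- whitening_matrix(nz, n, tau)
    expect_equal(unname(gls_fit(y0, X, L)$coefficients), beta_star,
                 tolerance = 1e-12)
  }

  # dense-algebra oracle: explicit weighted normal equations
  nz <- noise_params("ar1", 0.6, 0.3, 1.5, 0.8)
  L <- whitening_matrix(nz, n, tau)
  W <- t(L) %*% L
  f2 <- gls_fit(y, X, L)
  expect_equal(unname(f2$coefficients),
               drop(unname(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))),
               tolerance = 1e-10)
  expect_equal(f2$cov, solve(t(X) %*% W %*% X), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(gls_fit(y, cbind(X, X[, 1])), "singular")
})

test_that("method-of-moments noise estimates recover known processes", {
  set.seed(5)
  # white noise: phase dependence estimates stay near zero
  r <- rnorm(2000)
  nz <- mom_noise(r, tau = 1000, structure = "ar1")
  expect_gt(nz$phi1, -0.1); expect_lt(nz$phi1, 0.1)
  expect_gt(nz$phi2, -0.1); expect_lt(nz$phi2, 0.1)
  expect_equal(nz$sigma2_w1, 1, tolerance = 0.1)

  # AR(1) with phi = 0.7 in both phases, 4000 points per phase
  set.seed(6)
  r <- sim_two_phase_ar1(8000, 4001, 0.7, 0.7, 1, 1)
  nz <- mom_noise(r, tau = 4001, structure = "ar1")
  expect_gt(nz$phi1, 0.65); expect_lt(nz$phi1, 0.75)
  expect_gt(nz$phi2, 0.65); expect_lt(nz$phi2, 0.75)
  expect_equal(nz$sigma2_w1, 1, tolerance = 0.15)

  # degenerate inputs
  expect_error(mom_noise(rep(1, 100), tau = 50, structure = "ar1"),
               "degenerate")
  expect_error(mom_noise(rnorm(10), tau = 3, structure = "ar1"),
               "phase too short")

  # independent structure forces phi to zero
  nz <- mom_noise(rnorm(100), tau = 50, structure = "independent")
  expect_identical(nz$phi1, 0); expect_identical(nz$phi2, 0)
})

test_that("conditional log-likelihood matches a naive scalar-density oracle", {
  # zero residuals, unit variance: 10 standard-normal densities at 0
  nz <- noise_params("ar1", 0, 0, 1, 1)
  expect_equal(conditional_loglik(rep(0, 11), nz, 6),
               -(10 / 2) * log(2 * pi))

  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    tau <- sample(4:(n - 2), 1)
    nz <- noise_params("ar1", runif(1, -0.8, 0.8), runif(1, -0.8, 0.8),
                       runif(1, 0.3, 2), runif(1, 0.3, 2))
    r <- rnorm(n)
    naive <- 0
    for (t in 2:n) {
      phi <- if (t <= tau - 1) nz$phi1 else nz$phi2
      s2 <- if (t <= tau - 1) nz$sigma2_w1 else nz$sigma2_w2
      naive <- naive + dnorm(r[t] - phi * r[t - 1], 0, sqrt(s2), log = TRUE)
    }
    expect_equal(conditional_loglik(r, nz, tau), naive, tolerance = 1e-12)
  }

  # the likelihood falls off when the variance moves away from its optimum
  set.seed(32)
  r <- rnorm(60)
  base <- mom_noise(r, tau = 30, structure = "ar1")
  ll_at <- function(scale) {
    nz <- noise_params("ar1", base$phi1, base$phi2,
                       base$sigma2_w1 * scale, base$sigma2_w2 * scale)
    conditional_loglik(r, nz, 30)
  }
  scales <- c(1, 1.5, 2.5, 4)
  lls <- vapply(scales, ll_at, numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("IRLS at a fixed change-point: OLS limit, recovery, determinism", {
  # independent structure: the segmented fit IS per-phase OLS
  set.seed(41)
  n <- 80; tau <- 40
  sc <- rits_scenario(N = 1, n = n, tau = tau,
                      mean = segmented_mean(10, 0.1, 4, -0.05),
                      noise = noise_params("independent",
                                           sigma2_w1 = 1, sigma2_w2 = 2))
  d <- simulate_its(sc, seed = 1)
  f <- fit_unit(d$units[[1]], tau, "independent")
  X <- segmented_design(n, tau)
  expect_equal(unname(unclass(f$mean)),
               drop(unname(ols_oracle(d$units[[1]]$values, X))),
               tolerance = 1e-8)

  # residuals + fitted reconstruct the data exactly
  expect_equal(f$fitted + f$residuals, d$units[[1]]$values)

  # parameter recovery within 3 standard errors at the true change-point
  truth <- list(beta = c(10, 0.1, 4, -0.05), phi = c(0.5, 0.2))
  sc2 <- rits_scenario(N = 1, n = 500, tau = 250,
                       mean = do.call(segmented_mean, as.list(truth$beta)),
                       noise = noise_params("ar1", 0.5, 0.2, 1, 1))
  d2 <- simulate_its(sc2, seed = 99)
  f2 <- fit_unit(d2$units[[1]], 250, "ar1")
  se_beta <- sqrt(diag(f2$mean_cov))
  expect_true(all(abs(unclass(f2$mean) - truth$beta) < 3 * se_beta))
  se_phi <- sqrt((1 - truth$phi^2) / c(249, 251))
  expect_lt(abs(f2$noise$phi1 - 0.5), 3 * se_phi[1])
  expect_lt(abs(f2$noise$phi2 - 0.2), 3 * se_phi[2])
  expect_true(f2$converged)

  # determinism: identical input, identical output
  f3 <- fit_unit(d2$units[[1]], 250, "ar1")
  expect_identical(f2, f3)
})

test_that("likelihood profile finds a strong change-point and is coherent", {
  # 10-marginal-SD level jump at t = 50: argmax must hit it
  sd1 <- sqrt(1 / (1 - 0.09))
  sc <- rits_scenario(N = 1, n = 100, tau = 50,
                      mean = segmented_mean(10, 0.05, delta = 10 * sd1),
                      noise = noise_params("ar1", 0.3, 0.3, 1, 1))
  for (seed in 1:10) {
    d <- simulate_its(sc, seed = seed)
    pr <- changepoint_profile(d, 40:60, "ar1")
    expect_equal(pr$tau_hat, 50)
    # argmax attains the maximum by construction
    expect_equal(max(pr$logliks, na.rm = TRUE),
                 pr$logliks[match(50, pr$candidates$indices)])
  }

  # pure noise: profile finite everywhere
  d0 <- simulate_its(rits_scenario(N = 1, n = 100, tau = 50,
                                   mean = segmented_mean(10, 0)),
                     seed = 3)
  pr0 <- changepoint_profile(d0, 40:60, "ar1")
  expect_true(all(is.finite(pr0$logliks)))
})

test_that("multiple units borrow strength and pool log-likelihoods", {
  # pooled profile log-likelihood is the sum of the unit-wise profiles
  d <- make_test_dataset(N = 3, n = 80, tau = 40, delta = 2, seed = 8)
  pr <- changepoint_profile(d, 35:45, "ar1")
  per_unit <- lapply(d$units, function(u)
    changepoint_profile(its_dataset(list(u)), 35:45, "ar1")$logliks)
  expect_equal(pr$logliks, Reduce(`+`, per_unit))

  # with a shared 2-marginal-SD jump, three units pin the change-point
  sd1 <- sqrt(1 / (1 - 0.09))
  sc <- rits_scenario(N = 3, n = 120, tau = 60,
                      mean = segmented_mean(10, 0.05, delta = 2 * sd1),
                      noise = noise_params("ar1", 0.3, 0.3, 1, 1))
  d3 <- simulate_its(sc, seed = 14)
  expect_equal(changepoint_profile(d3, 50:70, "ar1")$tau_hat, 60)
})

test_that("rits() assembles a coherent fit object", {
  d <- make_test_dataset(N = 2, n = 80, tau = 40, delta = 4, seed = 5)
  fit <- rits(d, candidates = 35:45)
  expect_s3_class(fit, "rits")
  expect_true(fit$tau_hat %in% fit$candidates$indices)

  # summaries are recomputable from the unit fits (internal identity)
  for (id in names(fit$unit_fits)) {
    f <- fit$unit_fits[[id]]
    s <- fit$summaries[[id]]
    expect_identical(s$estimate[s$quantity == "level_change"],
                     level_change(f$mean, fit$tau_hat))
    expect_identical(s$estimate[s$quantity == "trend_change"],
                     trend_change(f$mean))
    expect_identical(s$estimate[s$quantity == "corr_change"],
                     f$noise$phi2 - f$noise$phi1)
    expect_identical(s$estimate[s$quantity == "var_change"],
                     marginal_variance(f$noise, 2) -
                       marginal_variance(f$noise, 1))
  }

  # a 1-unit dataset gives exactly the single-series model
  d1 <- its_dataset(list(d$units[[1]]))
  fit1 <- rits(d1, candidates = 35:45)
  manual <- fit_unit(d$units[[1]], fit1$tau_hat, "ar1")
  expect_equal(unclass(fit1$unit_fits[[1]]$mean), unclass(manual$mean))
  expect_equal(fit1$unit_fits[[1]]$noise, manual$noise)

  # determinism end to end
  fit_b <- rits(d, candidates = 35:45)
  expect_equal(coef(fit), coef(fit_b))
  expect_identical(fit$tau_hat, fit_b$tau_hat)

  # methods run
  expect_equal(dim(coef(fit)), c(2L, 4L))
  expect_equal(fitted(fit) + residuals(fit),
               sapply(d$units, `[[`, "values"))
  expect_equal(unname(predict(fit)[, 1]), fit$unit_fits[[1]]$fitted)
  expect_output(print(fit), "change-point")
  expect_output(print(summary(fit)), "Phase estimates")
  expect_s3_class(logLik(fit), "logLik")
})
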