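## Deterministic building blocks of the segmented model: the piecewise-linear
## design, effect summaries, and the phase-specific error structures.
##
## Conventions used throughout the package:
##   * analysis runs on integer ticks t = 1..n (dates are mapped in io);
##   * tau is the FIRST index of the post phase: the mean uses the shifted
##     branch for t >= tau;
##   * residual innovations are phase 1 for 1 < t <= tau - 1 and phase 2 for
##     tau - 1 < t <= n, so the innovation at t = tau already uses the
##     post-phase parameters and regresses on r[tau - 1] across the boundary.

#' Segmented mean-function parameters
#'
#' The per-unit mean function is `beta0 + beta1 * t` before the change-point
#' and `(beta0 + delta) + (beta1 + Delta) * t` from the change-point on.
#' `delta = Delta = 0` encodes "no change in the mean function".
#'
#' @param beta0,beta1 Pre-phase intercept and per-tick slope.
#' @param delta,Delta Intercept shift and slope shift at the change-point.
#' @return Named numeric vector of class `"segmented_mean"` with elements
#'   `beta0`, `beta1`, `delta`, `Delta`.
#' @export
#' @examples
#' segmented_mean(10, 0.1, delta = 2, Delta = -0.05)
segmented_mean <- function(beta0 = 0, beta1 = 0, delta = 0, Delta = 0) {
  p <- c(beta0 = beta0, beta1 = beta1, delta = delta, Delta = Delta)
  if (!all(is.finite(p))) stop("mean parameters must be finite")
  class(p) <- "segmented_mean"
  p
}

as_mean_params <- function(p) {
  p <- unclass(unlist(p))
  if (length(p) != 4L || !all(is.finite(p)))
    stop("expected four finite mean parameters (beta0, beta1, delta, Delta)")
  names(p) <- c("beta0", "beta1", "delta", "Delta")
  p
}

#' Phase-specific noise parameters
#'
#' Describes the error process around the mean in both phases.  For the
#' AR(1) structure `phi1`/`phi2` are the adjacent (lag-1) correlations and
#' `sigma2_w1`/`sigma2_w2` the innovation variances; the marginal variance is
#' `sigma2_w / (1 - phi^2)`.  For the exchangeable structure `phi` is the
#' constant within-phase pairwise correlation and `sigma2_w` is the marginal
#' variance itself.  The independent structure forces `phi1 = phi2 = 0`.
#'
#' @param structure One of `"ar1"`, `"exchangeable"`, `"independent"`.
#' @param phi1,phi2 Phase dependence parameters, strictly inside (-1, 1).
#' @param sigma2_w1,sigma2_w2 Positive phase variances (innovation variances
#'   for AR(1), marginal variances otherwise).
#' @return A list of class `"noise_params"`.
#' @export
noise_params <- function(structure = c("ar1", "exchangeable", "independent"),
                         phi1 = 0, phi2 = 0, sigma2_w1 = 1, sigma2_w2 = 1) {
  structure <- match.arg(structure)
  if (structure == "independent" && (phi1 != 0 || phi2 != 0))
    stop("independent structure requires phi1 = phi2 = 0")
  if (abs(phi1) >= 1 || abs(phi2) >= 1)
    stop("dependence parameters must lie strictly inside (-1, 1)")
  if (sigma2_w1 < 0 || sigma2_w2 < 0)
    stop("phase variances must be nonnegative")
  out <- list(structure = structure, phi1 = phi1, phi2 = phi2,
              sigma2_w1 = sigma2_w1, sigma2_w2 = sigma2_w2)
  class(out) <- "noise_params"
  out
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("<noise_params %s: phi = (%.4g, %.4g), sigma2_w = (%.4g, %.4g)>\n",
              x$structure, x$phi1, x$phi2, x$sigma2_w1, x$sigma2_w2))
  invisible(x)
}

#' Design matrix of the segmented mean function
#'
#' Row t of the returned matrix is `[1, t, I(t >= tau), t * I(t >= tau)]`,
#' so that `X %*% c(beta0, beta1, delta, Delta)` evaluates the piecewise
#' mean at every tick.  With `tau = n + 1` the indicator never fires and the
#' first two columns reproduce the simple linear regression design (the
#' null model of the supremum Wald test).
#'
#' @param n Series length.
#' @param tau Change-point index, `1 < tau <= n + 1` (`n + 1` means "no
#'   post phase", i.e. the null design).
#' @return An `n x 4` numeric matrix with columns `beta0, beta1, delta,
#'   Delta`.
#' @export
#' @examples
#' segmented_design(5, 4)
segmented_design <- function(n, tau) {
  n <- as.integer(n); tau <- as.integer(tau)
  if (n < 1L) stop("`n` must be positive")
  if (tau <= 1L || tau > n + 1L)
    stop(sprintf("`tau` = %d out of range (need 1 < tau <= %d)", tau, n + 1L))
  t <- seq_len(n)
  post <- as.numeric(t >= tau)
  X <- cbind(1, t, post, t * post)
  colnames(X) <- c("beta0", "beta1", "delta", "Delta")
  X
}

#' Evaluate the piecewise mean function
#'
#' @param params Mean parameters (see [segmented_mean()]).
#' @param t Time index (vectorised).
#' @param tau Change-point index.
#' @return Numeric vector of mean values.
#' @export
mean_function <- function(params, t, tau) {
  p <- as_mean_params(params)
  if (any(t < 1)) stop("`t` must be >= 1")
  ifelse(t < tau, p["beta0"] + p["beta1"] * t,
         (p["beta0"] + p["delta"]) + (p["beta1"] + p["Delta"]) * t)
}

#' Level change at the change-point
#'
#' The discontinuity between the pre-phase mean projected to the
#' change-point and the post-phase mean there: `delta + Delta * tau`, the
#' change in intercept anchored at the change-point.  This, together with
#' the trend change, is the headline effect measure of an ITS analysis.
#'
#' @inheritParams mean_function
#' @return A single number.
#' @export
#' @examples
#' level_change(segmented_mean(0, 1, delta = 2, Delta = 0.5), tau = 10)
level_change <- function(params, tau) {
  p <- as_mean_params(params)
  unname(p["delta"] + p["Delta"] * tau)
}

#' Trend change
#'
#' The post-minus-pre difference in slope, `Delta`.
#'
#' @inheritParams mean_function
#' @return A single number.
#' @export
trend_change <- function(params) {
  unname(as_mean_params(params)["Delta"])
}

#' Marginal variance of the response in one phase
#'
#' For the AR(1) structure the stationary marginal variance is
#' `sigma2_w / (1 - phi^2)`; for independent errors it is `sigma2_w`; for
#' the exchangeable structure `sigma2_w` already stores the marginal
#' variance.
#'
#' @param noise A [noise_params()] object.
#' @param phase `1` (pre) or `2` (post).
#' @return Positive number.
#' @export
marginal_variance <- function(noise, phase = 1L) {
  stopifnot(inherits(noise, "noise_params"), phase %in% c(1L, 2L))
  phi <- if (phase == 1L) noise$phi1 else noise$phi2
  s2 <- if (phase == 1L) noise$sigma2_w1 else noise$sigma2_w2
  if (abs(phi) >= 1) stop("|phi| must be < 1")
  switch(noise$structure,
         ar1 = s2 / (1 - phi^2),
         exchangeable = s2,
         independent = s2)
}

## innovation phase of tick t (t >= 2): pre for 1 < t <= tau - 1,
## post for tau - 1 < t <= n
innovation_phase <- function(t, tau) ifelse(t <= tau - 1L, 1L, 2L)

## observation phase: pre block 1..tau-1, post block tau..n
observation_phase <- function(t, tau) ifelse(t < tau, 1L, 2L)

#' Whitening transform for phase-specific error structures
#'
#' Returns the `n x n` matrix `L` that maps a residual vector with the given
#' noise structure to (approximately) independent unit-variance innovations,
#' so that `t(L) %*% L` is the inverse error covariance used by generalized
#' least squares.  For AR(1), row 1 scales the first residual by the inverse
#' pre-phase marginal standard deviation and row `t >= 2` computes
#' `(r[t] - phi[j(t)] r[t-1]) / sigma_w[j(t)]` with the innovation phase
#' `j(t)` switching to the post parameters at `t = tau`.  For independent
#' errors `L` is diagonal; for the exchangeable structure `L` is the
#' block-wise inverse symmetric square root of the compound-symmetry
#' covariance of each phase.
#'
#' @param noise A [noise_params()] object.
#' @param n Series length.
#' @param tau Change-point index (`n + 1` for a single-phase series).
#' @return An `n x n` matrix.
#' @export
whitening_matrix <- function(noise, n, tau) {
  stopifnot(inherits(noise, "noise_params"))
  n <- as.integer(n); tau <- as.integer(tau)
  if (tau <= 1L || tau > n + 1L) stop("invalid `tau`")
  if (!all(is.finite(c(noise$phi1, noise$phi2, noise$sigma2_w1, noise$sigma2_w2))))
    stop("non-finite noise parameters")
  switch(noise$structure,
    ar1 = {
      L <- matrix(0, n, n)
      L[1L, 1L] <- 1 / sqrt(marginal_variance(noise, 1L))
      if (n >= 2L) {
        t <- 2:n
        j <- innovation_phase(t, tau)
        phi <- ifelse(j == 1L, noise$phi1, noise$phi2)
        sw <- sqrt(ifelse(j == 1L, noise$sigma2_w1, noise$sigma2_w2))
        L[cbind(t, t)] <- 1 / sw
        L[cbind(t, t - 1L)] <- -phi / sw
      }
      L
    },
    independent = {
      j <- observation_phase(seq_len(n), tau)
      diag(1 / sqrt(ifelse(j == 1L, noise$sigma2_w1, noise$sigma2_w2)), n)
    },
    exchangeable = {
      L <- matrix(0, n, n)
      pre <- seq_len(tau - 1L)
      post <- if (tau <= n) tau:n else integer(0)
      L[pre, pre] <- cs_inv_sqrt(length(pre), noise$sigma2_w1, noise$phi1)
      if (length(post))
        L[post, post] <- cs_inv_sqrt(length(post), noise$sigma2_w2, noise$phi2)
      L
    })
}

## inverse symmetric square root of v * [(1-rho) I + rho J], closed form via
## the two eigenvalues of compound symmetry
cs_inv_sqrt <- function(m, v, rho) {
  if (m == 0L) return(matrix(0, 0, 0))
  if (rho <= -1 / max(m - 1, 1)) stop("exchangeable correlation out of range")
  a <- 1 / sqrt(v * (1 - rho))           # within-contrast eigenvalue
  b <- 1 / sqrt(v * (1 + (m - 1) * rho)) # equicorrelated-mean eigenvalue
  if (m == 1L) return(matrix(b, 1, 1))
  J <- matrix(1 / m, m, m)
  a * (diag(m) - J) + b * J
}

## Fast application of the whitening transform to a vector or the columns of
## a matrix, avoiding the dense n x n product for the AR(1)/independent hot
## paths of the grid search.
whiten_apply <- function(M, noise, tau) {
  M <- as.matrix(M)
  n <- nrow(M)
  switch(noise$structure,
    ar1 = {
      out <- matrix(0, n, ncol(M))
      out[1L, ] <- M[1L, ] / sqrt(marginal_variance(noise, 1L))
      if (n >= 2L) {
        t <- 2:n
        j <- innovation_phase(t, tau)
        phi <- ifelse(j == 1L, noise$phi1, noise$phi2)
        sw <- sqrt(ifelse(j == 1L, noise$sigma2_w1, noise$sigma2_w2))
        out[t, ] <- (M[t, , drop = FALSE] - phi * M[t - 1L, , drop = FALSE]) / sw
      }
      out
    },
    independent = {
      j <- observation_phase(seq_len(n), tau)
      M / sqrt(ifelse(j == 1L, noise$sigma2_w1, noise$sigma2_w2))
    },
    exchangeable = whitening_matrix(noise, n, tau) %*% M)
}
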