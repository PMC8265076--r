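## Estimation machinery: GLS for the mean, method of moments for the noise,
## alternated inside an IRLS loop; conditional likelihood for change-point
## profiling.

#' Generalized least squares via a whitening transform
#'
#' Minimises `|| L (y - X beta) ||^2`.  Because `L` maps the errors to unit
#' variance, the coefficient covariance is simply
#' `solve(t(LX) %*% LX)` -- the innovation variance is folded into `L`.
#'
#' @param y Response vector.
#' @param X Design matrix (`n x p`).
#' @param L Whitening transform: an `n x n` matrix (see
#'   [whitening_matrix()]), or `NULL` for the identity (ordinary least
#'   squares).
#' @return List with `coefficients` (length p) and `cov` (`p x p`).
#' @export
#' @examples
#' X <- segmented_design(20, 11)
#' y <- X %*% c(1, 0.5, 2, -0.1) + rnorm(20)
#' gls_fit(y, X)$coefficients
gls_fit <- function(y, X, L = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(L)) {
    yw <- y; Xw <- X
  } else {
    yw <- as.numeric(L %*% y); Xw <- L %*% X
  }
  gls_fit_whitened(yw, Xw)
}

## shared solver on already-whitened inputs
gls_fit_whitened <- function(yw, Xw) {
  qrx <- qr(Xw)
  if (qrx$rank < ncol(Xw))
    stop("singular design: whitened design matrix is rank deficient")
  beta <- qr.coef(qrx, yw)
  R <- qr.R(qrx)[seq_len(ncol(Xw)), , drop = FALSE]
  cov <- chol2inv(R)
  dimnames(cov) <- list(colnames(Xw), colnames(Xw))
  list(coefficients = setNames(as.numeric(beta), colnames(Xw)), cov = cov)
}

## lag-1 sample autocorrelation, mean-corrected
lag1_acf <- function(z) {
  zc <- z - mean(z)
  den <- sum(zc^2)
  if (den == 0) stop("degenerate data: residuals have zero variance")
  sum(zc[-length(zc)] * zc[-1L]) / den
}

#' Method-of-moments noise estimates from residuals
#'
#' Splits the residual vector at the change-point (pre phase `1..tau-1`,
#' post phase `tau..n`) and estimates the dependence and variance parameters
#' of each phase from sample moments.  For AR(1), `phi_j` is the lag-1
#' sample autocorrelation of the phase-`j` residuals and the innovation
#' variance is the phase variance times `1 - phi_j^2`.  For the exchangeable
#' structure, the common correlation is the average off-diagonal product
#' moment of the centred phase residuals and `sigma2_w` is the phase
#' variance.  Independent errors take `phi = 0` and the phase variance.
#'
#' @param residuals Numeric residual vector.
#' @param tau Change-point index; `NULL` (or `n + 1`) treats the whole
#'   series as a single phase and duplicates its parameters into both slots.
#' @param structure Correlation structure.
#' @param control A [rits_control()] list (clamping and minimum phase
#'   length).
#' @return A [noise_params()] object.
#' @export
mom_noise <- function(residuals, tau = NULL,
                      structure = c("ar1", "exchangeable", "independent"),
                      control = rits_control()) {
  structure <- match.arg(structure)
  r <- as.numeric(residuals)
  n <- length(r)
  single <- is.null(tau) || tau > n
  if (single) {
    if (n < control$min_segment)
      stop(sprintf("phase too short: %d observations, need >= %d",
                   n, control$min_segment))
    p <- phase_moments(r, structure, control)
    return(noise_params(structure, phi1 = p$phi, phi2 = p$phi,
                        sigma2_w1 = p$s2w, sigma2_w2 = p$s2w))
  }
  tau <- as.integer(tau)
  pre <- r[seq_len(tau - 1L)]
  post <- r[tau:n]
  if (length(pre) < control$min_segment || length(post) < control$min_segment)
    stop(sprintf(
      "phase too short at tau = %d: %d pre / %d post observations, need >= %d each",
      tau, length(pre), length(post), control$min_segment))
  p1 <- phase_moments(pre, structure, control)
  p2 <- phase_moments(post, structure, control)
  noise_params(structure, phi1 = p1$phi, phi2 = p2$phi,
               sigma2_w1 = p1$s2w, sigma2_w2 = p2$s2w)
}

## Moments of one phase.  Two small-sample corrections keep the Wald tests
## honest at realistic phase lengths (a few dozen points):
##   * the phase variance divisor is m - 2, accounting for the intercept and
##     slope absorbed by the phase's mean fit;
##   * the lag-1 autocorrelation gets a first-order Marriott-Pope/Kendall
##     style bias correction, phi + 2 (1 + 3 phi) / m; the factor 2 reflects
##     that each phase's residuals come from an intercept-plus-trend fit
##     (trend-detrended AR(1) residuals have about twice the mean-detrended
##     ACF bias).
phase_moments <- function(z, structure, control) {
  m <- length(z)
  ss <- sum((z - mean(z))^2)
  v <- ss / max(m - 2L, 1L)
  if (v <= 0 || !is.finite(v))
    stop("degenerate data: residuals have zero variance")
  cl <- control$phi_clamp
  switch(structure,
    independent = list(phi = 0, s2w = v),
    ar1 = {
      phi <- lag1_acf(z)
      phi <- phi + 2 * (1 + 3 * phi) / m
      phi <- min(max(phi, -cl), cl)
      list(phi = phi, s2w = v * (1 - phi^2))
    },
    exchangeable = {
      zc <- z - mean(z)
      ## average off-diagonal product over the within-phase variance
      rho <- (sum(zc)^2 - sum(zc^2)) / ((m - 1) * sum(zc^2))
      lo <- max(-1 / (m - 1) + 1e-6, -cl)
      rho <- min(max(rho, lo), cl)
      list(phi = rho, s2w = v)
    })
}

#' Conditional log-likelihood of residuals under phase-specific noise
#'
#' For AR(1) and independent structures this conditions on the first
#' observation and sums the Gaussian log-densities of the innovations
#' `e[t] = r[t] - phi[j(t)] r[t-1]` over `t = 2..n`, with the innovation
#' phase switching to the post parameters at `t = tau`.  When
#' `control$condition_on_first` is `FALSE` the stationary marginal density
#' of `r[1]` is added.  For the exchangeable structure the full Gaussian
#' log-density under the block compound-symmetry covariance is returned
#' (there is no natural one-step conditioning for that structure).
#'
#' @param residuals Residual vector.
#' @param noise A [noise_params()] object.
#' @param tau Change-point index (`n + 1` for single phase).
#' @param control A [rits_control()] list.
#' @return Log-likelihood value (a single number).
#' @export
conditional_loglik <- function(residuals, noise, tau,
                               control = rits_control()) {
  r <- as.numeric(residuals)
  n <- length(r)
  if (noise$sigma2_w1 <= 0 || noise$sigma2_w2 <= 0)
    stop("non-positive phase variance")
  if (noise$structure == "exchangeable") {
    L <- whitening_matrix(noise, n, tau)
    e <- as.numeric(L %*% r)
    pre <- tau - 1L; post <- n - pre
    logdetL <- cs_logdet_inv_sqrt(pre, noise$sigma2_w1, noise$phi1) +
      cs_logdet_inv_sqrt(post, noise$sigma2_w2, noise$phi2)
    return(-n / 2 * log(2 * pi) - 0.5 * sum(e^2) + logdetL)
  }
  t <- 2:n
  j <- innovation_phase(t, tau)
  phi <- ifelse(j == 1L, noise$phi1, noise$phi2)
  sw <- sqrt(ifelse(j == 1L, noise$sigma2_w1, noise$sigma2_w2))
  e <- r[t] - phi * r[t - 1L]
  ll <- sum(dnorm(e, 0, sw, log = TRUE))
  if (!control$condition_on_first)
    ll <- ll + dnorm(r[1L], 0, sqrt(marginal_variance(noise, 1L)), log = TRUE)
  ll
}

## log-determinant of the inverse square root of an m-dim CS block
cs_logdet_inv_sqrt <- function(m, v, rho) {
  if (m == 0L) return(0)
  -0.5 * ((m - 1) * log(v * (1 - rho)) + log(v * (1 + (m - 1) * rho)))
}

#' IRLS fit of one unit at a fixed change-point
#'
#' Alternates (a) generalized least squares for the segmented mean under the
#' current whitening transform and (b) method-of-moments noise estimation on
#' the updated residuals, starting from identity weights (an ordinary
#' least-squares fit), until the largest absolute parameter change drops
#' below `control$tol` or `control$max_iter` is reached.  With independent
#' errors the mean fit decouples by phase, so the loop converges immediately
#' to the segmented OLS fit.
#'
#' @param series A [unit_series()], or a bare numeric vector of outcomes.
#' @param tau Change-point index (first post-phase tick); `NULL` fits the
#'   single-line null model (intercept + slope, one noise phase).
#' @param structure Correlation structure.
#' @param control A [rits_control()] list.
#' @return An object of class `"unit_fit"`: list with `mean`
#'   ([segmented_mean()] parameters, or `(beta0, beta1)` for the null
#'   model), `mean_cov`, `noise`, `loglik`, `fitted`, `residuals`, `tau`,
#'   `converged`, `iterations`.
#' @export
fit_unit <- function(series, tau,
                     structure = c("ar1", "exchangeable", "independent"),
                     control = rits_control()) {
  structure <- match.arg(structure)
  y <- if (inherits(series, "unit_series")) series$values else as.numeric(series)
  n <- length(y)
  null_model <- is.null(tau)
  tau_noise <- if (null_model) n + 1L else as.integer(tau)
  if (!null_model && (tau_noise <= control$min_segment ||
                      tau_noise > n - control$min_segment + 1L))
    stop(sprintf("tau = %d inadmissible for n = %d (min_segment = %d)",
                 tau_noise, n, control$min_segment))
  X <- segmented_design(n, if (null_model) n + 1L else tau_noise)
  if (null_model) X <- X[, 1:2, drop = FALSE]

  ## identity-weight start: plain OLS
  fit <- tryCatch(gls_fit_whitened(y, X), error = function(e)
    stop(sprintf("singular design at tau = %s: %s",
                 if (null_model) "null" else tau_noise, conditionMessage(e))))
  beta <- fit$coefficients
  res <- y - as.numeric(X %*% beta)
  noise <- mom_noise(res, if (null_model) NULL else tau_noise, structure, control)
  theta <- c(beta, noise$phi1, noise$phi2, noise$sigma2_w1, noise$sigma2_w2)

  converged <- FALSE
  iter <- 1L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    yw <- whiten_apply(y, noise, tau_noise)
    Xw <- whiten_apply(X, noise, tau_noise)
    fit <- tryCatch(gls_fit_whitened(as.numeric(yw), Xw), error = function(e)
      stop(sprintf("singular design at tau = %s: %s",
                   if (null_model) "null" else tau_noise, conditionMessage(e))))
    beta <- fit$coefficients
    res <- y - as.numeric(X %*% beta)
    noise <- mom_noise(res, if (null_model) NULL else tau_noise, structure,
                       control)
    theta_new <- c(beta, noise$phi1, noise$phi2, noise$sigma2_w1,
                   noise$sigma2_w2)
    if (max(abs(theta_new - theta)) < control$tol) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
  }
  if (!converged)
    warning(sprintf("IRLS did not converge in %d iterations at tau = %s",
                    control$max_iter, if (null_model) "null" else tau_noise))

  mean_par <- if (null_model) beta else
    segmented_mean(beta[1L], beta[2L], beta[3L], beta[4L])
  structure(
    list(mean = mean_par, mean_cov = fit$cov, noise = noise,
         loglik = conditional_loglik(res, noise, tau_noise, control),
         fitted = as.numeric(X %*% beta), residuals = res,
         tau = if (null_model) NA_integer_ else tau_noise,
         null_model = null_model, converged = converged, iterations = iter),
    class = "unit_fit"
  )
}

#' @export
print.unit_fit <- function(x, ...) {
  cat(sprintf("<unit_fit%s: tau = %s, logLik = %.3f, %d IRLS iterations%s>\n",
              if (x$null_model) " (null model)" else "",
              if (is.na(x$tau)) "-" else x$tau, x$loglik, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  print(x$mean)
  print(x$noise)
  invisible(x)
}

#' Conditional-likelihood profile over candidate change-points
#'
#' Fits every unit at each candidate change-point and records the summed
#' conditional log-likelihood; the estimated global change-point is the
#' candidate attaining the maximum (ties broken by the earliest candidate).
#' A candidate at which any unit's fit fails (e.g. a rank-deficient design)
#' is dropped with a warning rather than aborting the grid search.
#'
#' @param data An [its_dataset()].
#' @param candidates A [candidate_set()] (or plain integer vector of
#'   indices).
#' @param structure Correlation structure.
#' @param control A [rits_control()] list.
#' @return An object of class `"likelihood_profile"`: list with
#'   `candidates`, `logliks` (NA for dropped candidates), `tau_hat`
#'   (argmax candidate index), and `fits` (per-candidate lists of
#'   [fit_unit()] results).
#' @export
changepoint_profile <- function(data, candidates,
                                structure = c("ar1", "exchangeable",
                                              "independent"),
                                control = rits_control()) {
  structure <- match.arg(structure)
  stopifnot(inherits(data, "its_dataset"))
  if (!inherits(candidates, "candidate_set"))
    candidates <- candidate_set(candidates, n = length(data$times),
                                min_segment = control$min_segment)
  Q <- candidates$indices
  logliks <- rep(NA_real_, length(Q))
  fits <- vector("list", length(Q))
  for (k in seq_along(Q)) {
    fk <- tryCatch(
      lapply(data$units, fit_unit, tau = Q[k], structure = structure,
             control = control),
      error = function(e) {
        warning(sprintf("candidate tau = %d dropped: %s", Q[k],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(fk)) {
      fits[[k]] <- fk
      logliks[k] <- sum(vapply(fk, `[[`, numeric(1), "loglik"))
    }
  }
  if (all(is.na(logliks)))
    stop("no candidate change-point admitted a valid fit")
  structure(
    list(candidates = candidates, logliks = logliks,
         tau_hat = Q[which.max(logliks)], fits = fits),
    class = "likelihood_profile"
  )
}

#' @export
print.likelihood_profile <- function(x, ...) {
  cat(sprintf("<likelihood_profile: %d candidates, tau_hat = %d>\n",
              length(x$candidates$indices), x$tau_hat))
  invisible(x)
}
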