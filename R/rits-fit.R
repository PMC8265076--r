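#' Fit a robust interrupted time series model
#'
#' Jointly estimates the segmented mean functions, the phase-specific noise
#' parameters and the global over-all-units change-point for a multi-unit
#' ITS dataset.  For every candidate change-point, each unit is fitted by
#' iteratively re-weighted least squares (generalized least squares for the
#' mean, method of moments for the noise); the estimated change-point is the
#' candidate maximising the summed conditional log-likelihood, and the final
#' per-unit estimates are the IRLS fits at that candidate.  With a single
#' unit this is the single-series (robust ITS) model; with several units the
#' change-point is shared while all other parameters stay unit-specific.
#'
#' Reported effect summaries per unit are the level change
#' `delta + Delta * tau_hat` (discontinuity at the change-point), the trend
#' change `Delta`, the change in adjacent correlation `phi2 - phi1`, and the
#' change in marginal variance.  Confidence intervals and p-values are
#' Wald-type with standard-normal quantiles; they condition on the estimated
#' change-point (uncertainty in `tau_hat` is not propagated).
#'
#' @param data An [its_dataset()].
#' @param candidates A [candidate_set()] or plain integer vector of candidate
#'   change-point indices; `NULL` uses every admissible index.
#' @param structure Correlation structure: `"ar1"` (default),
#'   `"exchangeable"`, or `"independent"`.
#' @param alpha Significance level for the reported confidence intervals.
#' @param control A [rits_control()] list.
#' @return An object of class `"rits"`; see Details.  Use `print()`,
#'   `summary()`, `coef()`, `fitted()`, `residuals()`, `predict()`,
#'   `plot()`, `simulate()` and `logLik()` on it.
#' @seealso [supremum_wald_test()] for the formal existence test;
#'   [rits_report()] for report tables.
#' @export
#' @examples
#' sc <- rits_preset("level-jump", N = 1, n = 60)
#' d <- simulate_its(sc, seed = 1)
#' fit <- rits(d, candidates = 26:36)
#' fit
rits <- function(data, candidates = NULL,
                 structure = c("ar1", "exchangeable", "independent"),
                 alpha = 0.05, control = rits_control()) {
  structure <- match.arg(structure)
  stopifnot(inherits(data, "its_dataset"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  n <- length(data$times)
  if (is.null(candidates)) {
    candidates <- candidate_set(
      (control$min_segment + 1L):(n - control$min_segment + 1L), n = n,
      min_segment = control$min_segment)
  } else if (!inherits(candidates, "candidate_set")) {
    candidates <- candidate_set(candidates, n = n,
                                min_segment = control$min_segment)
  }
  profile <- changepoint_profile(data, candidates, structure, control)
  tau_hat <- profile$tau_hat
  k <- match(tau_hat, candidates$indices)
  unit_fits <- profile$fits[[k]]
  summaries <- lapply(unit_fits, unit_summaries, tau = tau_hat, alpha = alpha)

  out <- structure(
    list(call = match.call(), data = data, candidates = candidates,
         structure = structure, alpha = alpha, control = control,
         profile = profile, tau_hat = tau_hat,
         tau_time = data$times[tau_hat], unit_fits = unit_fits,
         summaries = summaries),
    class = "rits"
  )
  out
}

## effect summaries for one unit at the estimated change-point
unit_summaries <- function(fit, tau, alpha) {
  p <- fit$mean
  S <- fit$mean_cov
  z <- qnorm(1 - alpha / 2)
  a <- c(0, 0, 1, tau)                      # level change = delta + Delta*tau
  lc <- sum(a * p)
  lc_se <- sqrt(drop(t(a) %*% S %*% a))
  tc <- p[["Delta"]]
  tc_se <- sqrt(S[4L, 4L])

  nz <- fit$noise
  cc <- nz$phi2 - nz$phi1
  m1 <- tau - 1L
  m2 <- length(fit$residuals) - m1
  cc_se <- if (nz$structure == "ar1")
    sqrt((1 - nz$phi1^2) / m1 + (1 - nz$phi2^2) / m2) else NA_real_
  v1 <- marginal_variance(nz, 1L)
  v2 <- marginal_variance(nz, 2L)
  vc <- v2 - v1
  vc_se <- sqrt(2 * v1^2 / (m1 - 1) + 2 * v2^2 / (m2 - 1))

  est <- c(lc, tc, cc, vc)
  se <- c(lc_se, tc_se, cc_se, vc_se)
  pval <- 2 * pnorm(-abs(est / se))
  data.frame(
    quantity = c("level_change", "trend_change", "corr_change", "var_change"),
    estimate = est, se = se,
    ci_lower = est - z * se, ci_upper = est + z * se,
    p_value = pval, row.names = NULL
  )
}

#' @export
print.rits <- function(x, digits = 4, ...) {
  cat("Robust interrupted time series model",
      if (x$data$N > 1L) sprintf("(%d units)", x$data$N) else "(single unit)",
      "\n")
  cat("  correlation structure:", x$structure, "\n")
  cat(sprintf("  estimated change-point: index %d (%s) out of %d candidates\n",
              x$tau_hat, format(x$tau_time),
              length(x$candidates$indices)))
  if (!is.na(x$candidates$theoretical_index))
    cat(sprintf("  formal intervention index: %d (%s)\n",
                x$candidates$theoretical_index,
                format(x$data$times[x$candidates$theoretical_index])))
  cat("\nPer-unit effect summaries at the estimated change-point:\n")
  for (id in names(x$unit_fits)) {
    cat(sprintf("\n  Unit %s:\n", id))
    s <- x$summaries[[id]]
    print(format(s, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.rits <- function(object, ...) {
  do.call(rbind, lapply(object$unit_fits, function(f) unclass(f$mean)))
}

#' @export
fitted.rits <- function(object, ...) {
  sapply(object$unit_fits, `[[`, "fitted")
}

#' @export
residuals.rits <- function(object, ...) {
  sapply(object$unit_fits, `[[`, "residuals")
}

#' @export
logLik.rits <- function(object, ...) {
  ll <- sum(vapply(object$unit_fits, `[[`, numeric(1), "loglik"))
  ## 4 mean + 2 phi + 2 variance parameters per unit, plus the shared tau
  attr(ll, "df") <- 8L * object$data$N + 1L
  attr(ll, "nobs") <- object$data$N * length(object$data$times)
  class(ll) <- "logLik"
  ll
}

#' Predict the estimated mean function
#'
#' Evaluates each unit's fitted piecewise mean at the requested time indices
#' (1-based ticks of the analysis grid), using the estimated change-point.
#'
#' @param object A fitted [rits()] model.
#' @param ticks Integer time indices; defaults to the observed grid.
#' @param ... Unused.
#' @return Numeric matrix, one column per unit.
#' @export
predict.rits <- function(object, ticks = NULL, ...) {
  if (is.null(ticks)) ticks <- seq_along(object$data$times)
  sapply(object$unit_fits, function(f)
    mean_function(f$mean, ticks, object$tau_hat))
}

#' @export
summary.rits <- function(object, ...) {
  est <- lapply(names(object$unit_fits), function(id) {
    f <- object$unit_fits[[id]]
    phase_estimates(f, object$tau_hat, object$alpha, id)
  })
  out <- list(
    structure = object$structure, N = object$data$N,
    n = length(object$data$times), tau_hat = object$tau_hat,
    tau_time = object$tau_time, alpha = object$alpha,
    candidates = object$candidates,
    estimates = do.call(rbind, est),
    summaries = do.call(rbind, Map(function(id, s)
      cbind(unit = id, s), names(object$summaries), object$summaries)),
    converged = vapply(object$unit_fits, `[[`, logical(1), "converged")
  )
  rownames(out$summaries) <- NULL
  class(out) <- "summary.rits"
  out
}

## pre/post intercepts and slopes with Wald intervals, one unit
phase_estimates <- function(fit, tau, alpha, unit_id) {
  p <- unclass(fit$mean)
  S <- fit$mean_cov
  z <- qnorm(1 - alpha / 2)
  combos <- list(
    pre_intercept  = c(1, 0, 0, 0),
    pre_slope      = c(0, 1, 0, 0),
    post_intercept = c(1, 0, 1, 0),
    post_slope     = c(0, 1, 0, 1)
  )
  est <- vapply(combos, function(a) sum(a * p), numeric(1))
  se <- vapply(combos, function(a) sqrt(drop(t(a) %*% S %*% a)), numeric(1))
  data.frame(
    unit = unit_id, parameter = names(combos), estimate = unname(est),
    se = unname(se), ci_lower = unname(est - z * se),
    ci_upper = unname(est + z * se),
    p_value = unname(2 * pnorm(-abs(est / se))), row.names = NULL
  )
}

#' @export
print.summary.rits <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Robust ITS fit: %d unit(s), n = %d, %s errors\n", x$N, x$n, x$structure))
  cat(sprintf("Estimated change-point: index %d (%s)\n", x$tau_hat,
              format(x$tau_time)))
  if (!all(x$converged))
    cat("NOTE: IRLS did not converge for unit(s): ",
        paste(names(x$converged)[!x$converged], collapse = ", "), "\n")
  cat("\nPhase estimates:\n")
  print(format(x$estimates, digits = digits), row.names = FALSE)
  cat("\nChange summaries:\n")
  print(format(x$summaries, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Parametric resampling: draws new datasets from the fitted segmented means
#' and noise parameters at the estimated change-point, on the same time
#' grid.
#'
#' @param object A fitted [rits()] model.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` [its_dataset()] objects.
#' @export
simulate.rits <- function(object, nsim = 1, seed = NULL, ...) {
  sc <- scenario_from_fit(object)
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_its(sc), simplify = FALSE)
}

scenario_from_fit <- function(object) {
  rits_scenario(
    N = object$data$N, n = length(object$data$times), tau = object$tau_hat,
    mean = lapply(object$unit_fits, `[[`, "mean"),
    noise = lapply(object$unit_fits, `[[`, "noise"),
    times = object$data$times,
    unit_ids = names(object$unit_fits)
  )
}

#' Plot a fitted robust ITS model
#'
#' `which = "fit"` overlays the fitted piecewise mean on each unit's series
#' and marks the estimated change-point; `"profile"` draws the conditional
#' log-likelihood over the candidate set; `"residuals"` shows residuals over
#' time with the phase boundary.
#'
#' @param x A fitted [rits()] model.
#' @param which One of `"fit"`, `"profile"`, `"residuals"`.
#' @param units Unit ids to draw (default all).
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.rits <- function(x, which = c("fit", "profile", "residuals"),
                      units = NULL, ...) {
  which <- match.arg(which)
  if (is.null(units)) units <- names(x$unit_fits)
  times <- x$data$times
  if (which == "profile") {
    q <- x$candidates$indices
    plot(times[q], x$profile$logliks, type = "b", pch = 16,
         xlab = "candidate change-point", ylab = "conditional log-likelihood",
         main = "Change-point likelihood profile", ...)
    abline(v = as.numeric(times[x$tau_hat]), col = "firebrick", lty = 2)
    return(invisible(x))
  }
  old <- par(mfrow = c(length(units), 1), mar = c(3.5, 3.5, 2, 1),
             mgp = c(2, 0.7, 0))
  on.exit(par(old))
  for (id in units) {
    f <- x$unit_fits[[id]]
    if (which == "fit") {
      plot(times, x$data$units[[id]]$values, type = "l", col = "grey40",
           xlab = "time", ylab = "outcome", main = paste("Unit", id), ...)
      pre <- seq_len(x$tau_hat - 1L)
      post <- x$tau_hat:length(times)
      lines(times[pre], f$fitted[pre], col = "steelblue", lwd = 2)
      lines(times[post], f$fitted[post], col = "firebrick", lwd = 2)
      abline(v = as.numeric(times[x$tau_hat]), lty = 2)
    } else {
      plot(times, f$residuals, type = "h", xlab = "time", ylab = "residual",
           main = paste("Unit", id, "residuals"), ...)
      abline(v = as.numeric(times[x$tau_hat]), lty = 2, col = "firebrick")
      abline(h = 0, col = "grey60")
    }
  }
  invisible(x)
}
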