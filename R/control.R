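#' Control parameters for robits estimation
#'
#' Collects the numerical knobs of the iteratively re-weighted least squares
#' (IRLS) loop and of the supremum Wald test into one object, in the style of
#' `glm.control()`.
#'
#' @param min_segment Minimum number of observations required in each phase
#'   (pre and post change-point).  Two points pin down an intercept and a
#'   slope; at least two residual pairs are needed for the lag-1
#'   autocorrelation, hence the default of 4.
#' @param tol Convergence tolerance of the IRLS loop: iteration stops when
#'   the maximum absolute change across all mean and noise parameters falls
#'   below `tol`.
#' @param max_iter Maximum number of IRLS iterations.  Non-convergence
#'   produces a warning and the best iterate, flagged in the fit.
#' @param phi_clamp Autoregressive / exchangeable correlation estimates are
#'   clamped to `[-phi_clamp, phi_clamp]` so that marginal variances stay
#'   finite; the model requires correlations strictly inside (-1, 1).
#' @param condition_on_first Logical; if `TRUE` (default) the likelihood used
#'   for change-point profiling conditions on the first observation and sums
#'   Gaussian innovation densities over t = 2..n.  If `FALSE` the stationary
#'   marginal density of the first observation is added.
#' @param wald_cov Which covariance estimator enters the Wald quadratic form
#'   of [supremum_wald_test()]: `"null"` (default) evaluates the GLS
#'   covariance of the segmented-design estimator under the null-fitted
#'   single-phase noise -- the natural plug-in when testing the no-change
#'   null, and markedly better calibrated in small samples; `"alt"` uses the
#'   covariance of the alternative-model estimator (the textbook Wald
#'   form).  See the package vignette for the calibration evidence.
#'
#' @return A list of class `"rits_control"`.
#' @export
#' @examples
#' rits_control(tol = 1e-10)
rits_control <- function(min_segment = 4L,
                         tol = 1e-8,
                         max_iter = 50L,
                         phi_clamp = 0.99,
                         condition_on_first = TRUE,
                         wald_cov = c("null", "alt")) {
  wald_cov <- match.arg(wald_cov)
  min_segment <- as.integer(min_segment)
  if (min_segment < 2L) stop("`min_segment` must be at least 2")
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be a positive number")
  if (max_iter < 1L) stop("`max_iter` must be at least 1")
  if (phi_clamp <= 0 || phi_clamp >= 1) stop("`phi_clamp` must lie in (0, 1)")
  structure(
    list(min_segment = min_segment, tol = tol, max_iter = as.integer(max_iter),
         phi_clamp = phi_clamp, condition_on_first = isTRUE(condition_on_first),
         wald_cov = wald_cov),
    class = "rits_control"
  )
}
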