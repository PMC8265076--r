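## Synthetic data with the exact stochastic structure of the model:
## piecewise-linear means plus phase-specific AR(1) (or exchangeable /
## independent) residuals sharing one global change-point across units.

#' Specify a simulation scenario
#'
#' Defines everything needed to draw multi-unit ITS datasets from the
#' model: the shared change-point, per-unit mean and noise parameters, and
#' the time grid.  Mean/noise parameters may be given once (recycled over
#' units) or as a list with one element per unit.
#'
#' @param N Number of units.
#' @param n Series length.
#' @param tau True change-point index (first post-phase tick), shared by
#'   all units.
#' @param mean A [segmented_mean()] or list of one per unit.
#' @param noise A [noise_params()] or list of one per unit.
#' @param start,step Calendar grid: start date and step in days.  Ignored
#'   when `times` is supplied; if `start` is `NULL` the grid is integer
#'   ticks `1..n`.
#' @param times Optional explicit time grid of length `n`.
#' @param unit_ids Optional unit labels (default `"A"`, `"B"`, ...).
#' @param missing_frac Fraction of interior cells blanked to `NA` when the
#'   dataset is written out with [write_its()] (exercises the missing-value
#'   interpolation path); the in-memory simulation itself is always
#'   complete.
#' @return An object of class `"rits_scenario"`.
#' @seealso [simulate_its()], [rits_preset()]
#' @export
#' @examples
#' sc <- rits_scenario(N = 2, n = 80, tau = 40,
#'                     mean = segmented_mean(10, 0.05, delta = 3),
#'                     noise = noise_params("ar1", 0.3, 0.3, 1, 1))
#' simulate_its(sc, seed = 1)
rits_scenario <- function(N, n, tau,
                          mean = segmented_mean(),
                          noise = noise_params("ar1", 0.3, 0.3, 1, 1),
                          start = NULL, step = 14, times = NULL,
                          unit_ids = NULL, missing_frac = 0) {
  N <- as.integer(N); n <- as.integer(n); tau <- as.integer(tau)
  if (N < 1L) stop("`N` must be positive")
  if (tau <= 1L || tau > n) stop("`tau` must satisfy 1 < tau <= n")
  if (missing_frac < 0 || missing_frac >= 0.5)
    stop("`missing_frac` must lie in [0, 0.5)")
  expand <- function(x, what, cls) {
    if (inherits(x, cls)) x <- list(x)
    if (length(x) == 1L) x <- rep(x, N)
    if (length(x) != N) stop(sprintf("`%s` must have 1 or N elements", what))
    x
  }
  mean <- lapply(expand(mean, "mean", "segmented_mean"), as_mean_params)
  noise <- expand(noise, "noise", "noise_params")
  stopifnot(all(vapply(noise, inherits, logical(1), "noise_params")))
  if (is.null(times)) {
    times <- if (is.null(start)) seq_len(n)
             else as.Date(start) + step * (seq_len(n) - 1L)
  }
  if (length(times) != n) stop("`times` must have length n")
  if (is.null(unit_ids)) unit_ids <- make_unit_ids(N)
  structure(
    list(N = N, n = n, tau = tau, mean = mean, noise = noise,
         times = times, unit_ids = as.character(unit_ids),
         missing_frac = missing_frac),
    class = "rits_scenario"
  )
}

make_unit_ids <- function(N) {
  if (N <= 26L) LETTERS[seq_len(N)] else paste0("U", seq_len(N))
}

#' @export
print.rits_scenario <- function(x, ...) {
  cat(sprintf("<rits_scenario: N = %d, n = %d, tau = %d, %s errors>\n",
              x$N, x$n, x$tau, x$noise[[1L]]$structure))
  invisible(x)
}

#' Simulate one unit from a scenario
#'
#' Draws the residual process with the scenario's phase boundaries: the
#' first residual comes from the pre-phase stationary marginal
#' distribution, then `r[t] = phi[j(t)] r[t-1] + e[t]` with
#' `e[t] ~ N(0, sigma2_w[j(t)])`, the innovation phase switching to the
#' post parameters at `t = tau`.  The outcome is the piecewise mean plus
#' the residual.  For the exchangeable structure the phase residual blocks
#' are drawn from the compound-symmetry Gaussian; for independent errors
#' the draws are i.i.d. within phase.
#'
#' @param scenario A [rits_scenario()].
#' @param unit Unit index in `1..N`.
#' @return A [unit_series()].
#' @export
simulate_unit <- function(scenario, unit = 1L) {
  stopifnot(inherits(scenario, "rits_scenario"))
  i <- as.integer(unit)
  if (i < 1L || i > scenario$N) stop("`unit` out of range")
  n <- scenario$n; tau <- scenario$tau
  nz <- scenario$noise[[i]]
  r <- switch(nz$structure,
    ar1 = {
      r <- numeric(n)
      r[1L] <- rnorm(1L, 0, sqrt(marginal_variance(nz, 1L)))
      t <- 2:n
      j <- innovation_phase(t, tau)
      phi <- ifelse(j == 1L, nz$phi1, nz$phi2)
      e <- rnorm(n - 1L, 0, sqrt(ifelse(j == 1L, nz$sigma2_w1, nz$sigma2_w2)))
      for (k in seq_along(t)) r[t[k]] <- phi[k] * r[t[k] - 1L] + e[k]
      r
    },
    independent = {
      j <- observation_phase(seq_len(n), tau)
      rnorm(n, 0, sqrt(ifelse(j == 1L, nz$sigma2_w1, nz$sigma2_w2)))
    },
    exchangeable = c(cs_draw(tau - 1L, nz$sigma2_w1, nz$phi1),
                     cs_draw(n - tau + 1L, nz$sigma2_w2, nz$phi2)))
  mu <- mean_function(scenario$mean[[i]], seq_len(n), tau)
  unit_series(scenario$unit_ids[i], scenario$times, mu + r)
}

## one compound-symmetry Gaussian block: shared component + idiosyncratic
cs_draw <- function(m, v, rho) {
  if (m == 0L) return(numeric(0))
  if (rho < 0) { # negative CS has no factor representation; use Cholesky
    S <- v * ((1 - rho) * diag(m) + rho * matrix(1, m, m))
    return(drop(rnorm(m) %*% chol(S)))
  }
  shared <- rnorm(1L, 0, sqrt(v * rho))
  shared + rnorm(m, 0, sqrt(v * (1 - rho)))
}

#' Simulate a multi-unit ITS dataset
#'
#' Draws `N` independent units on the shared grid, optionally writing the
#' result to a CSV file in the package's wide dialect.
#'
#' @param scenario A [rits_scenario()].
#' @param seed Optional integer seed for reproducibility.
#' @param file Optional path; if given the dataset is also written with
#'   [write_its()] (honouring the scenario's `missing_frac`).
#' @return An [its_dataset()].
#' @export
simulate_its <- function(scenario, seed = NULL, file = NULL) {
  stopifnot(inherits(scenario, "rits_scenario"))
  if (!is.null(seed)) set.seed(seed)
  units <- lapply(seq_len(scenario$N), function(i) simulate_unit(scenario, i))
  d <- its_dataset(units)
  if (!is.null(file))
    write_its(d, file, missing_frac = scenario$missing_frac)
  d
}

#' Preset simulation scenarios
#'
#' Named scenarios covering the canonical study conditions: a no-change
#' null, an abrupt level jump, a slope change, a change confined to the
#' noise process (no mean change but alteration of the variance and
#' autocorrelation -- the case that motivates modelling the correlation
#' structure), and a four-unit multi-year biweekly panel mirroring the
#' shape of typical patient-experience sample data.
#'
#' All presets use AR(1) errors with `phi = 0.3` and unit innovation
#' variance unless the preset is about the noise itself.  The level-jump
#' preset places a jump of 5 pre-phase marginal standard deviations at the
#' change-point; the slope-change preset bends the slope by 0.05 outcome
#' units per tick.
#'
#' @param name One of `"null"`, `"level-jump"`, `"slope-change"`,
#'   `"noise-only-change"`, `"paper-shape"`.
#' @param N,n Override the preset's number of units / series length
#'   (`NULL` keeps the preset default).
#' @param ... Further arguments passed to [rits_scenario()].
#' @return A [rits_scenario()].
#' @export
#' @examples
#' names(rits_presets())
#' rits_preset("null")
rits_preset <- function(name = c("null", "level-jump", "slope-change",
                                 "noise-only-change", "paper-shape"),
                        N = NULL, n = NULL, ...) {
  name <- match.arg(name)
  base_noise <- noise_params("ar1", 0.3, 0.3, 1, 1)
  sd1 <- sqrt(marginal_variance(base_noise, 1L))
  args <- switch(name,
    "null" = list(N = 4L, n = 100L, tau = 50L,
                  mean = segmented_mean(10, 0.05), noise = base_noise),
    "level-jump" = {
      tau <- if (is.null(n)) 50L else as.integer(n) %/% 2L
      list(N = 1L, n = 100L, tau = tau,
           mean = segmented_mean(10, 0.05, delta = 5 * sd1),
           noise = base_noise)
    },
    "slope-change" = list(N = 1L, n = 100L, tau = 50L,
                          mean = segmented_mean(10, 0.05, Delta = 0.05),
                          noise = base_noise),
    "noise-only-change" = list(
      N = 4L, n = 100L, tau = 50L, mean = segmented_mean(10, 0.05),
      noise = noise_params("ar1", phi1 = 0.2, phi2 = 0.6,
                           sigma2_w1 = 1, sigma2_w2 = 0.5)),
    "paper-shape" = list(
      N = 4L, n = 193L, tau = 75L,
      mean = segmented_mean(60, 0.02, delta = 4, Delta = -0.03),
      noise = base_noise, start = "2010-01-01", step = 14)
  )
  if (!is.null(N)) args$N <- as.integer(N)
  if (!is.null(n)) {
    args$n <- as.integer(n)
    if (name != "level-jump") args$tau <- max(2L, args$n %/% 2L)
  }
  do.call(rits_scenario, modifyList(args, list(...)))
}

#' @rdname rits_preset
#' @export
rits_presets <- function() {
  nm <- c("null", "level-jump", "slope-change", "noise-only-change",
          "paper-shape")
  setNames(lapply(nm, rits_preset), nm)
}
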