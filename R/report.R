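## Tabular report bundle mirroring the classic ITS report: the supremum
## Wald test table, phase estimates, change summaries, the likelihood
## profile and residual diagnostics.  Every number is copied from the fit /
## test objects -- nothing is recomputed, so the report cannot drift from
## the model output.

#' Assemble (and optionally write) a report bundle
#'
#' @param fit A fitted [rits()] model.
#' @param swt Optional [supremum_wald_test()] result computed on the same
#'   dataset, candidate set and structure; a mismatch is an error.
#' @param dir Optional output directory; when given, the tables are written
#'   as CSV files plus a lossless `report.json`, and (with `plots = TRUE`)
#'   PNG diagnostics.
#' @param plots Write PNG plots of the fitted means and likelihood profile.
#' @param acf_lag_max Largest lag of the per-phase residual
#'   autocorrelations.
#' @return An object of class `"rits_report"`: a list of data frames
#'   `swt` (may be `NULL`), `unit_labels`, `estimates`, `summary`,
#'   `profile`, `residuals`, `acf`, plus the scalar `tau_hat`, `tau_time`,
#'   `structure`, `alpha`.
#' @export
rits_report <- function(fit, swt = NULL, dir = NULL, plots = FALSE,
                        acf_lag_max = 10L) {
  stopifnot(inherits(fit, "rits"))
  if (!is.null(swt)) {
    stopifnot(inherits(swt, "rits_swt"))
    if (!identical(swt$candidates$indices, fit$candidates$indices) ||
        !identical(swt$structure, fit$structure) ||
        nrow(swt$unit_table) != fit$data$N)
      stop("mismatched provenance: `swt` was not computed on the same dataset/candidates/structure as `fit`")
  }
  s <- summary(fit)
  times <- fit$data$times
  resid <- do.call(rbind, lapply(names(fit$unit_fits), function(id)
    data.frame(unit = id, time = times,
               phase = observation_phase(seq_along(times), fit$tau_hat),
               residual = fit$unit_fits[[id]]$residuals)))
  acf_tab <- do.call(rbind, lapply(names(fit$unit_fits), function(id) {
    r <- fit$unit_fits[[id]]$residuals
    pre <- r[seq_len(fit$tau_hat - 1L)]
    post <- r[fit$tau_hat:length(r)]
    rbind(phase_acf(pre, id, 1L, acf_lag_max),
          phase_acf(post, id, 2L, acf_lag_max))
  }))
  bundle <- structure(
    list(
      swt = if (is.null(swt)) NULL else swt$table,
      unit_labels = if (is.null(swt)) NULL else swt$unit_table,
      exists = if (is.null(swt)) NULL else swt$exists,
      estimates = s$estimates,
      summary = s$summaries,
      profile = data.frame(tau = fit$candidates$indices,
                           time = times[fit$candidates$indices],
                           loglik = fit$profile$logliks),
      residuals = resid, acf = acf_tab,
      tau_hat = fit$tau_hat, tau_time = fit$tau_time,
      structure = fit$structure, alpha = fit$alpha
    ),
    class = "rits_report"
  )
  if (!is.null(dir)) write_report(bundle, dir, fit, plots)
  bundle
}

phase_acf <- function(r, id, phase, lag_max) {
  lm <- min(lag_max, length(r) - 2L)
  a <- drop(acf(r, lag.max = lm, plot = FALSE)$acf)
  data.frame(unit = id, phase = phase, lag = seq_along(a) - 1L, acf = a)
}

write_report <- function(bundle, dir, fit, plots) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("swt", "unit_labels", "estimates", "summary", "profile",
            "residuals", "acf")
  for (nm in tabs) {
    if (!is.null(bundle[[nm]]))
      write.csv(fmt_times(bundle[[nm]]), file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(unclass(bundle), function(x) if (is.data.frame(x)) fmt_times(x) else x),
    file.path(dir, "report.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, null = "null",
    Date = "ISO8601")
  if (plots) {
    png(file.path(dir, "fit.png"), width = 900,
        height = 280 * fit$data$N)
    plot(fit, which = "fit")
    dev.off()
    png(file.path(dir, "profile.png"), width = 700, height = 450)
    plot(fit, which = "profile")
    dev.off()
  }
  invisible(dir)
}

fmt_times <- function(df) {
  for (j in seq_along(df)) if (inherits(df[[j]], "Date"))
    df[[j]] <- format(df[[j]])
  df
}

#' @export
print.rits_report <- function(x, digits = 4, ...) {
  cat("ITS analysis report\n")
  cat(sprintf("  estimated change-point: index %d (%s), %s errors\n",
              x$tau_hat, format(x$tau_time), x$structure))
  if (!is.null(x$swt)) {
    cat(sprintf("  supremum Wald test: change-point %s\n",
                if (x$exists) "EXISTS for at least one unit" else "not detected"))
    print(format(x$swt, digits = digits), row.names = FALSE)
    cat("\n")
    print(format(x$unit_labels, digits = digits), row.names = FALSE)
  }
  cat("\nPhase estimates:\n")
  print(format(x$estimates, digits = digits), row.names = FALSE)
  cat("\nChange summaries:\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
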