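## Core in-memory containers: a single evenly spaced series, a multi-unit
## dataset on a shared grid, and the set of candidate change-points.

#' Construct a single-unit interrupted time series
#'
#' A `unit_series` holds one unit's outcome sequence on an evenly spaced time
#' grid.  Missing values are not allowed here: interpolation and trimming
#' happen upstream, in [its_data()] / [interpolate_missing()].
#'
#' @param unit_id Character label for the unit.
#' @param times Strictly increasing vector of measurement times, either
#'   `Date`s or numeric ticks, evenly spaced up to the modal-step tolerance.
#' @param values Numeric outcome vector, same length as `times`, no `NA`s.
#' @param step_tol Relative tolerance on grid regularity.  The default 0.15
#'   accepts calendar-month grids (steps of 28--31 days around a modal 31)
#'   while still rejecting genuinely irregular sampling.
#'
#' @return An object of class `"unit_series"`: a list with elements
#'   `unit_id`, `times`, `values`, `n`.
#' @seealso [its_data()] for building a multi-unit dataset.
#' @export
#' @examples
#' unit_series("A", 1:20, rnorm(20))
unit_series <- function(unit_id, times, values, step_tol = 0.15) {
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length")
  n <- length(values)
  if (n < 2L) stop("a unit series needs at least two observations")
  if (anyNA(values))
    stop(sprintf("unit '%s' has missing values; interpolate or trim first",
                 unit_id))
  if (anyNA(times)) stop("`times` contains missing entries")
  tnum <- as.numeric(times)
  d <- diff(tnum)
  if (any(d <= 0)) stop("`times` must be strictly increasing")
  step <- modal_step(d)
  if (any(abs(d - step) > step_tol * step))
    stop(sprintf(
      "unit '%s': time grid is not evenly spaced (modal step %g, observed steps %g..%g)",
      unit_id, step, min(d), max(d)))
  structure(
    list(unit_id = as.character(unit_id), times = times,
         values = as.numeric(values), n = n),
    class = "unit_series"
  )
}

## most common spacing, robust to a few rounding wobbles
modal_step <- function(d) {
  ud <- sort(unique(d))
  if (length(ud) == 1L) return(ud)
  tab <- tabulate(match(d, ud))
  ud[which.max(tab)]
}

#' @export
print.unit_series <- function(x, ...) {
  cat(sprintf("<unit_series '%s': n = %d, %s .. %s>\n", x$unit_id, x$n,
              format(x$times[1]), format(x$times[x$n])))
  invisible(x)
}

#' Assemble a multi-unit ITS dataset from unit series
#'
#' All units must share an identical time grid (use [restrict_overlap()]
#' first if they do not).  The formal intervention time `t*` is recorded so
#' that candidate change-point windows can be anchored to it; it is distinct
#' from the change-point, which [rits()] estimates.
#'
#' @param units A list of [unit_series()] objects on a common grid.
#' @param intervention Optional intervention time (same scale as the grid).
#'   Must lie within the observed time span when given.
#'
#' @return An object of class `"its_dataset"`: list with `units`, `N`,
#'   `times`, `grid_step`, `intervention_time`.
#' @export
its_dataset <- function(units, intervention = NULL) {
  if (!length(units)) stop("`units` must contain at least one unit series")
  if (!all(vapply(units, inherits, logical(1), "unit_series")))
    stop("all elements of `units` must be unit_series objects")
  t0 <- units[[1L]]$times
  for (u in units[-1L]) {
    if (u$n != length(t0) || any(as.numeric(u$times) != as.numeric(t0)))
      stop(sprintf(
        "unit '%s' is not on the common time grid; apply restrict_overlap() first",
        u$unit_id))
  }
  ids <- vapply(units, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids)) stop("duplicate unit ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(units) <- ids
  if (!is.null(intervention)) {
    ti <- as.numeric(intervention)
    rng <- range(as.numeric(t0))
    if (ti < rng[1] || ti > rng[2])
      stop("`intervention` lies outside the observed time span")
  }
  structure(
    list(units = units, N = length(units), times = t0,
         grid_step = modal_step(diff(as.numeric(t0))),
         intervention_time = intervention),
    class = "its_dataset"
  )
}

#' @export
print.its_dataset <- function(x, ...) {
  cat(sprintf("<its_dataset: %d unit%s, n = %d, %s .. %s, step %g>\n",
              x$N, if (x$N == 1L) "" else "s", length(x$times),
              format(x$times[1]), format(x$times[length(x$times)]),
              x$grid_step))
  if (!is.null(x$intervention_time))
    cat("  intervention at", format(x$intervention_time), "\n")
  invisible(x)
}

#' @export
as.data.frame.its_dataset <- function(x, ...) {
  out <- data.frame(time = x$times)
  for (u in x$units) out[[u$unit_id]] <- u$values
  out
}

#' Map a calendar time to its 1-based grid index
#'
#' @param data An [its_dataset()].
#' @param time A time on the scale of the dataset grid.
#' @param match `"exact"` requires `time` to be a grid point; `"nearest"`
#'   snaps to the closest grid point.
#' @return Integer index in `1..n`.
#' @export
time_to_index <- function(data, time, match = c("exact", "nearest")) {
  match <- match.arg(match)
  tn <- as.numeric(data$times)
  x <- as.numeric(time)
  if (match == "exact") {
    i <- which(tn == x)
    if (!length(i)) stop("time ", format(time), " is not on the measurement grid")
    return(i[1L])
  }
  which.min(abs(tn - x))
}

#' Candidate change-points
#'
#' The set Q of admissible change-point indices that the grid search and the
#' supremum Wald test range over.  A change-point index tau is the FIRST
#' index of the post phase, so admissibility requires at least `min_segment`
#' observations on each side: `min_segment < tau <= n - min_segment + 1`.
#'
#' @param indices Integer vector of 1-based candidate indices.
#' @param n Series length the candidates refer to.
#' @param theoretical Optional index mapped from the formal intervention time
#'   `t*`; recorded but not required to be a member of the set.
#' @param min_segment Minimum phase length (see [rits_control()]).
#' @return An object of class `"candidate_set"` with elements `indices`,
#'   `theoretical_index`, `n`.
#' @seealso [candidates_from_range()] to build the set from a date window.
#' @export
#' @examples
#' candidate_set(45:55, n = 100)
candidate_set <- function(indices, n, theoretical = NULL, min_segment = 4L) {
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices)) stop("candidate set is empty")
  n <- as.integer(n)
  bad <- indices <= min_segment | indices > n - min_segment + 1L
  if (any(bad))
    stop(sprintf(
      "candidate indices {%s} are inadmissible for n = %d (need %d < tau <= %d)",
      paste(indices[bad], collapse = ", "), n, min_segment,
      n - min_segment + 1L))
  structure(
    list(indices = indices, n = n,
         theoretical_index = if (is.null(theoretical)) NA_integer_
                             else as.integer(theoretical)),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set: %d candidates in %d..%d (n = %d)%s>\n",
              length(x$indices), min(x$indices), max(x$indices), x$n,
              if (is.na(x$theoretical_index)) ""
              else sprintf(", theoretical index %d", x$theoretical_index)))
  invisible(x)
}
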