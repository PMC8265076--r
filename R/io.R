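## Ingestion: CSV/TSV reading with typed errors, overlap restriction across
## units, linear interpolation of interior missing values, candidate-set
## construction from date windows, and the matching writer.

#' Read a wide CSV/TSV interrupted time series table
#'
#' Expects one time column (first by default) and one numeric column per
#' unit.  Blank cells are kept as `NA` (flagged missing, never zeroed);
#' malformed numeric cells, unparseable dates and duplicated timestamps
#' raise errors naming the offending rows.
#'
#' @param path File path.
#' @param sep `"auto"` (sniff from the extension / first line), `"csv"` or
#'   `"tsv"`.
#' @param date_format Optional `strptime` format string; by default ISO
#'   dates (`YYYY-MM-DD`) are tried, then plain numeric ticks.
#' @param time_col Index or name of the time column.
#' @return A `data.frame` with a `time` column (Date or numeric) followed by
#'   one numeric column per unit, possibly containing `NA`s.
#' @seealso [its_data()] to turn the table into an analysable dataset.
#' @export
read_its <- function(path, sep = c("auto", "csv", "tsv"),
                     date_format = NULL, time_col = 1L) {
  sep <- match.arg(sep)
  if (!file.exists(path)) stop("file not found: ", path)
  if (sep == "auto") {
    sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "tsv"
           else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
           else if (grepl("\t", readLines(path, n = 1L))) "tsv" else "csv"
  }
  sc <- if (sep == "tsv") "\t" else ","
  raw <- read.csv(path, sep = sc, check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2L) stop("table must have a time column plus >= 1 unit column")
  if (is.character(time_col)) time_col <- match(time_col, names(raw))
  if (is.na(time_col)) stop("time column not found")
  tchr <- raw[[time_col]]
  times <- parse_times(tchr, date_format)
  dup <- duplicated(times)
  if (any(dup))
    stop("duplicated timestamp(s): ",
         paste(unique(format(times[dup])), collapse = ", "))
  out <- data.frame(time = times)
  for (j in setdiff(seq_along(raw), time_col)) {
    v <- raw[[j]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("column '%s': non-numeric value(s) in row(s) %s",
                   names(raw)[j], paste(bad, collapse = ", ")))
    out[[names(raw)[j]]] <- num
  }
  ord <- order(as.numeric(out$time))
  out[ord, , drop = FALSE]
}

parse_times <- function(x, date_format = NULL) {
  if (!is.null(date_format)) {
    d <- as.Date(x, format = date_format)
    if (anyNA(d))
      stop("unparseable date(s) in row(s) ",
           paste(which(is.na(d)), collapse = ", "))
    return(d)
  }
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  if (!anyNA(d)) return(d)
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  bad <- which(is.na(d) & is.na(num))
  stop("unparseable date(s) in row(s) ", paste(bad, collapse = ", "))
}

#' Restrict units to their overlapping time points
#'
#' The model requires every unit to be observed on the same grid, so
#' analysis uses only time points present in all units: a unit observed
#' only through 2015 truncates units observed through 2016 down to 2015.
#' Accepts a list of [unit_series()] (possibly on different grids) and
#' returns them cut to the common timestamps.
#'
#' @param units List of [unit_series()].
#' @return List of [unit_series()] on the common grid.
#' @export
restrict_overlap <- function(units) {
  stopifnot(length(units) >= 1L,
            all(vapply(units, inherits, logical(1), "unit_series")))
  common <- as.numeric(units[[1L]]$times)
  for (u in units[-1L]) common <- intersect(common, as.numeric(u$times))
  if (!length(common))
    stop("units share no overlapping time points")
  common <- sort(common)
  lapply(units, function(u) {
    keep <- as.numeric(u$times) %in% common
    unit_series(u$unit_id, u$times[keep], u$values[keep])
  })
}

#' Linearly interpolate interior missing values
#'
#' Fills `NA`s by linear interpolation on the time grid.  Missing values at
#' the edges cannot be interpolated; they are trimmed with a warning.
#' Imputed positions are reported so users can judge the (small, but real)
#' bias risk of analysing interpolated series.
#'
#' @param values Numeric vector with `NA`s.
#' @param times Time grid, same length (defaults to `seq_along(values)`).
#' @return List with `values`, `times`, `imputed` (indices into the
#'   returned vectors), `trimmed` (number of edge observations dropped).
#' @export
#' @examples
#' interpolate_missing(c(1, NA, 3))
interpolate_missing <- function(values, times = seq_along(values)) {
  values <- as.numeric(values)
  if (length(values) != length(times))
    stop("`values` and `times` must have the same length")
  if (all(is.na(values))) stop("all values are missing")
  obs <- which(!is.na(values))
  first <- obs[1L]; last <- obs[length(obs)]
  trimmed <- (first - 1L) + (length(values) - last)
  if (trimmed > 0L) {
    warning(sprintf("%d leading/trailing missing value(s) trimmed (edge values cannot be interpolated)",
                    trimmed))
    values <- values[first:last]
    times <- times[first:last]
  }
  miss <- which(is.na(values))
  if (length(miss)) {
    warning(sprintf(
      "%d interior missing value(s) linearly interpolated at index(es) %s; interpolation can bias parameter estimates",
      length(miss), paste(miss, collapse = ", ")))
    values[miss] <- approx(as.numeric(times)[-miss], values[-miss],
                           xout = as.numeric(times)[miss])$y
  }
  list(values = values, times = times, imputed = miss, trimmed = trimmed)
}

#' Build an analysable dataset from a wide table
#'
#' The full ingestion pipeline: per-unit edge trimming of missing values,
#' restriction to the time points covered by every unit, linear
#' interpolation of interior gaps, grid-regularity validation, and
#' assembly into an [its_dataset()].
#'
#' @param x A wide `data.frame` as returned by [read_its()] (first column
#'   time, remaining columns units), or a path handed through to
#'   [read_its()].
#' @param intervention Optional formal intervention time.
#' @param analysis_start,analysis_end Optional window restricting the rows
#'   used for analysis before any other processing.
#' @param ... Passed to [read_its()] when `x` is a path.
#' @return An [its_dataset()].
#' @export
its_data <- function(x, intervention = NULL, analysis_start = NULL,
                     analysis_end = NULL, ...) {
  if (is.character(x)) x <- read_its(x, ...)
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  times <- x[[1L]]
  if (!is.null(analysis_start))
    x <- x[as.numeric(times) >= as.numeric(coerce_time(analysis_start, times)), ,
           drop = FALSE]
  times <- x[[1L]]
  if (!is.null(analysis_end))
    x <- x[as.numeric(times) <= as.numeric(coerce_time(analysis_end, times)), ,
           drop = FALSE]
  times <- x[[1L]]
  if (nrow(x) < 2L) stop("fewer than two rows remain after filtering")
  units <- lapply(names(x)[-1L], function(id) {
    fixed <- interpolate_missing(x[[id]], times)
    unit_series(id, fixed$times, fixed$values)
  })
  units <- restrict_overlap(units)
  ## interior gaps of a unit may coincide with another unit's edges; a final
  ## interpolation pass is unnecessary because unit_series rejects NAs
  its_dataset(units, intervention = if (is.null(intervention)) NULL
              else coerce_time(intervention, times))
}

coerce_time <- function(x, template) {
  if (inherits(template, "Date") && !inherits(x, "Date")) as.Date(x) else x
}

#' Candidate change-points from a time window
#'
#' Maps all measurement time points inside `[start, end]` to grid indices
#' and filters them to admissible change-point values.  Because candidates
#' are the measurement dates themselves, any two windows whose endpoints
#' fall between the same pair of measurement dates produce identical sets.
#'
#' @param data An [its_dataset()].
#' @param start,end Window bounds (inclusive), on the scale of the grid.
#' @param control A [rits_control()] list (for the minimum phase length).
#' @return A [candidate_set()]; its `theoretical_index` records the grid
#'   point nearest the dataset's intervention time, when one is set.
#' @export
candidates_from_range <- function(data, start, end,
                                  control = rits_control()) {
  stopifnot(inherits(data, "its_dataset"))
  tn <- as.numeric(data$times)
  s <- as.numeric(coerce_time(start, data$times))
  e <- as.numeric(coerce_time(end, data$times))
  if (e < s) stop("`end` precedes `start`")
  idx <- which(tn >= s & tn <= e)
  if (!length(idx))
    stop("no measurement time points fall inside the candidate window")
  n <- length(tn)
  idx <- idx[idx > control$min_segment & idx <= n - control$min_segment + 1L]
  if (!length(idx))
    stop("no admissible candidate change-points inside the window (phases too short)")
  theo <- if (is.null(data$intervention_time)) NULL
          else time_to_index(data, data$intervention_time, match = "nearest")
  candidate_set(idx, n = n, theoretical = theo,
                min_segment = control$min_segment)
}

#' Write a dataset in the wide CSV/TSV dialect
#'
#' Inverse of [read_its()]/[its_data()] for complete data.  Optionally
#' blanks a fraction of interior cells (useful for exercising the
#' missing-data path with synthetic data).
#'
#' @param data An [its_dataset()].
#' @param path Output path; extension `.tsv` selects tab separation.
#' @param missing_frac Fraction of interior cells written as empty.
#' @return `path`, invisibly.
#' @export
write_its <- function(data, path, missing_frac = 0) {
  stopifnot(inherits(data, "its_dataset"))
  df <- as.data.frame(data)
  if (missing_frac > 0) {
    n <- nrow(df)
    for (j in seq_along(df)[-1L]) {
      k <- max(0L, round(missing_frac * (n - 2L)))
      if (k > 0L) df[sample(2:(n - 1L), k), j] <- NA
    }
  }
  df$time <- format(df$time)
  ## 17 significant digits: doubles survive the write -> read round trip
  for (j in seq_along(df)[-1L]) {
    v <- df[[j]]
    out <- formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- NA
    df[[j]] <- out
  }
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}
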