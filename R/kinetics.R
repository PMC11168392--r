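# Time-resolved metrics: first/second differences, sliding-window peak
# selection, replicate aggregation, percent-of-maximum normalization.

#' Absolute change (first difference) of a time series
#'
#' The rate-of-change metric: at each time point, the difference from the
#' previous measurement. Values are per sampling interval (unit/interval) and
#' are anchored to the right edge of their interval — the "current" time
#' point; on a uniform grid the per-hour variant differs only by the constant
#' `1/dt` (`per_hour = TRUE`).
#'
#' @param time_h Strictly increasing times in hours (>= 2 points).
#' @param value Readout values, same length.
#' @param per_hour Divide each difference by its interval length.
#' @return A tibble with columns `time_h` (right edges) and `change`
#'   (`length(value) - 1` rows).
#' @examples
#' absolute_change(0:3, c(0, 2, 6, 7))
#' @export
absolute_change <- function(time_h, value, per_hour = FALSE) {
  stopifnot(is.numeric(time_h), is.numeric(value),
            length(time_h) == length(value))
  if (length(value) < 2) {
    stop("need at least 2 points for absolute change", call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  ch <- diff(value)
  if (per_hour) ch <- ch / diff(time_h)
  tibble::tibble(time_h = time_h[-1], change = ch)
}

#' Acceleration (second difference) of a time series
#'
#' The change in the rate of change: at each time point, the rate of change
#' minus the rate at the previous time point (unit/interval^2, or
#' unit/hour^2 with `per_hour = TRUE`). Values around zero indicate a steady
#' rate; a falling acceleration with a rising readout flags a slowing of the
#' increase.
#'
#' @inheritParams absolute_change
#' @return A tibble with columns `time_h` (right edges, from the third time
#'   point on) and `acceleration` (`length(value) - 2` rows).
#' @examples
#' acceleration(0:3, c(0, 1, 4, 9))
#' @export
acceleration <- function(time_h, value, per_hour = FALSE) {
  if (length(value) < 3) {
    stop("need at least 3 points for acceleration", call. = FALSE)
  }
  ch <- absolute_change(time_h, value, per_hour = per_hour)
  acc <- diff(ch$change)
  if (per_hour) acc <- acc / diff(ch$time_h)
  tibble::tibble(time_h = ch$time_h[-1], acceleration = acc)
}

#' Change and acceleration in one table
#'
#' Convenience wrapper returning the readout together with its first and
#' second differences aligned on the right-edge convention (`change` is `NA`
#' at the first time point, `acceleration` at the first two).
#'
#' @inheritParams absolute_change
#' @return A tibble with columns `time_h`, `value`, `change`, `acceleration`.
#' @export
rate_series <- function(time_h, value, per_hour = FALSE) {
  ch <- absolute_change(time_h, value, per_hour = per_hour)
  acc <- acceleration(time_h, value, per_hour = per_hour)
  tibble::tibble(
    time_h = time_h,
    value = value,
    change = c(NA_real_, ch$change),
    acceleration = c(NA_real_, NA_real_, acc$acceleration)
  )
}

#' Sliding-window maximum of a series
#'
#' The anomaly-damped peak-selection rule: among all contiguous windows of
#' length `window_h` on the grid, find the window with the highest mean;
#' within that window, return the single time point with the highest value.
#' Ties choose the earliest window, then the earliest time point, so the
#' result is deterministic. With `basis = "change"` the rule is applied to
#' the first differences of the series (the maximum-rate time of the
#' emulated analysis), with `basis = "value"` to the series itself.
#'
#' @inheritParams absolute_change
#' @param window_h Window length in hours (default 2); must be an integer
#'   multiple of the grid spacing and not exceed the series span.
#' @param basis Search the raw values (`"value"`) or the first differences
#'   (`"change"`).
#' @return A one-row tibble: `peak_time_h`, `peak_value`, `window_start_h`,
#'   `window_end_h`, `basis`.
#' @examples
#' t <- seq(0, 10, 0.5)
#' sliding_window_max(t, exp(-(t - 4)^2))
#' @export
sliding_window_max <- function(time_h, value, window_h = 2.0,
                               basis = c("value", "change")) {
  basis <- match.arg(basis)
  stopifnot(length(time_h) == length(value))
  dt <- check_uniform_grid(time_h)
  if (basis == "change") {
    ch <- absolute_change(time_h, value)
    time_h <- ch$time_h
    value <- ch$change
  }
  span <- time_h[length(time_h)] - time_h[1]
  if (window_h > span + 1e-9) {
    stop("series span is shorter than `window_h`", call. = FALSE)
  }
  steps <- window_h / dt
  if (abs(steps - round(steps)) > 1e-6) {
    stop("`window_h` must be an integer multiple of the grid spacing",
         call. = FALSE)
  }
  steps <- as.integer(round(steps))
  n <- length(value)
  n_windows <- n - steps
  if (n_windows < 1) stop("series span is shorter than `window_h`", call. = FALSE)
  means <- vapply(seq_len(n_windows), function(i) {
    mean(value[i:(i + steps)])
  }, numeric(1))
  best_w <- which.max(means)  # earliest on ties
  idx <- best_w:(best_w + steps)
  best_i <- idx[which.max(value[idx])]
  tibble::tibble(
    peak_time_h = time_h[best_i],
    peak_value = value[best_i],
    window_start_h = time_h[best_w],
    window_end_h = time_h[best_w + steps],
    basis = basis
  )
}

#' Average technical fields into experimental replicates
#'
#' For each (trigger, readout, replicate, time), the mean over technical
#' image fields becomes the experimental-replicate value. Panels without a
#' `field` column (or with all-`NA` fields, e.g. cytokines) pass through
#' unchanged apart from dropping the column.
#'
#' @param panel A tidy panel with columns `trigger`, `readout`, `replicate`,
#'   optionally `field`, `time_h`, `value`.
#' @return A replicate-level tibble (no `field` column).
#' @export
aggregate_replicates <- function(panel) {
  validate_panel(panel)
  if (!"field" %in% names(panel)) {
    return(tibble::as_tibble(panel[panel_cols]))
  }
  grids <- dplyr::summarise(
    dplyr::group_by(panel, .data$trigger, .data$readout, .data$replicate,
                    .data$field),
    grid = paste(sort(.data$time_h), collapse = ","), .groups = "drop"
  )
  n_grids <- dplyr::summarise(
    dplyr::group_by(grids, .data$trigger, .data$readout, .data$replicate),
    n = dplyr::n_distinct(.data$grid), .groups = "drop"
  )
  if (any(n_grids$n > 1)) {
    stop("technical fields within a replicate have inconsistent time grids",
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(panel, .data$trigger, .data$readout, .data$replicate,
                    .data$time_h),
    value = mean(.data$value), .groups = "drop"
  )
  dplyr::arrange(out, .data$trigger, .data$readout, .data$replicate,
                 .data$time_h)
}

#' Study-level summary: mean and SEM across replicates
#'
#' @param panel A replicate-level panel (run [aggregate_replicates()] first
#'   if technical fields are present).
#' @return A tibble with columns `trigger`, `readout`, `time_h`, `n`,
#'   `mean`, `sem`.
#' @export
replicate_summary <- function(panel) {
  validate_panel(panel)
  if ("field" %in% names(panel) && !all(is.na(panel$field))) {
    panel <- aggregate_replicates(panel)
  }
  dplyr::summarise(
    dplyr::group_by(panel, .data$trigger, .data$readout, .data$time_h),
    n = dplyr::n(),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}

#' Per-replicate maxima and their times
#'
#' For each experimental replicate, locate its maximum value and the time at
#' which it occurs (earliest time on ties); `per_replicate_peak()` then
#' reports the mean and SEM of those per-replicate maxima and times — the
#' replicate-respecting peak estimate of the emulated analysis.
#'
#' @param panel A tidy panel; technical fields are averaged first.
#' @return `replicate_peaks()`: a tibble with one row per (trigger, readout,
#'   replicate): `peak_time_h`, `peak_value`. `per_replicate_peak()`: one row
#'   per (trigger, readout): `n`, `mean_peak_value`, `sem_peak_value`,
#'   `mean_peak_time_h`, `sem_peak_time_h`.
#' @examples
#' study <- simulate_study(seed = 1)
#' per_replicate_peak(dplyr::filter(study$panel, readout == "speck_count"))
#' @export
replicate_peaks <- function(panel) {
  panel <- aggregate_replicates(panel)
  dplyr::summarise(
    dplyr::group_by(panel, .data$trigger, .data$readout, .data$replicate),
    peak_time_h = .data$time_h[which.max(.data$value)],
    peak_value = max(.data$value),
    .groups = "drop"
  )
}

#' @rdname replicate_peaks
#' @export
per_replicate_peak <- function(panel) {
  peaks <- replicate_peaks(panel)
  dplyr::summarise(
    dplyr::group_by(peaks, .data$trigger, .data$readout),
    n = dplyr::n(),
    mean_peak_value = mean(.data$peak_value),
    sem_peak_value = stats::sd(.data$peak_value) / sqrt(dplyr::n()),
    mean_peak_time_h = mean(.data$peak_time_h),
    sem_peak_time_h = stats::sd(.data$peak_time_h) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}

#' Scale a series to percent of its maximum
#'
#' @param value Numeric vector with a positive maximum.
#' @return `value / max(value) * 100`; the maximum maps to exactly 100.
#' @examples
#' percent_of_max(c(0, 5, 10))
#' @export
percent_of_max <- function(value) {
  stopifnot(is.numeric(value))
  m <- max(value, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("`value` must have a positive maximum", call. = FALSE)
  }
  value / m * 100
}

#' Change and acceleration for every group of a panel
#'
#' Applies [rate_series()] per (trigger, readout) to the replicate-mean
#' trajectory and returns the summary metric table used by the pipeline.
#'
#' @param panel A tidy panel.
#' @param per_hour Divide differences by the interval length.
#' @return A tibble with columns `trigger`, `readout`, `time_h`, `mean`,
#'   `sem`, `change`, `acceleration`.
#' @export
panel_rates <- function(panel, per_hour = FALSE) {
  summ <- replicate_summary(panel)
  parts <- dplyr::group_split(dplyr::group_by(summ, .data$trigger, .data$readout))
  out <- lapply(parts, function(g) {
    g <- dplyr::arrange(g, .data$time_h)
    rs <- rate_series(g$time_h, g$mean, per_hour = per_hour)
    dplyr::mutate(g, change = rs$change, acceleration = rs$acceleration)
  })
  dplyr::bind_rows(out)
}
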