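# Temporal association between readouts: landmark extraction on normalized
# trajectories, and pairwise lags between landmarks.
#
# The underlying study describes readout associations visually; the
# landmark/lag formalization here is this package's own quantification and
# is labelled as such in reports.

#' Extract temporal landmarks per (trigger, readout)
#'
#' Normalizes each replicate-mean trajectory to percent of maximum and
#' records three landmarks:
#'
#' * `onset_time_h` — first time the normalized value reaches
#'   `100 * onset_fraction`;
#' * `peak_rate_time_h` — sliding-window maximum of the first differences
#'   ([sliding_window_max()] with `basis = "change"`);
#' * `peak_time_h` — sliding-window maximum of the values themselves.
#'
#' Readouts that never rise above zero have undefined landmarks: their row is
#' kept with `NA`s and a warning, never fabricated.
#'
#' @param panel A tidy panel (fields averaged first).
#' @param onset_fraction Fraction of maximum defining onset (default 0.1).
#' @param window_h Sliding-window length in hours.
#' @return A tibble with columns `trigger`, `readout`, `onset_time_h`,
#'   `peak_rate_time_h`, `peak_time_h`.
#' @export
landmark_extract <- function(panel, onset_fraction = 0.1, window_h = 2.0) {
  stopifnot(onset_fraction > 0, onset_fraction <= 1)
  summ <- replicate_summary(panel)
  parts <- dplyr::group_split(dplyr::group_by(summ, .data$trigger, .data$readout))
  rows <- lapply(parts, function(g) {
    g <- dplyr::arrange(g, .data$time_h)
    base <- tibble::tibble(trigger = g$trigger[1], readout = g$readout[1])
    if (max(g$mean, na.rm = TRUE) <= 0) {
      warning("all-zero readout ", g$readout[1], " for trigger ",
              g$trigger[1], ": landmarks undefined", call. = FALSE)
      return(dplyr::mutate(base, onset_time_h = NA_real_,
                           peak_rate_time_h = NA_real_,
                           peak_time_h = NA_real_))
    }
    pct <- percent_of_max(g$mean)
    onset <- g$time_h[which(pct >= 100 * onset_fraction)[1]]
    pk <- sliding_window_max(g$time_h, pct, window_h, basis = "value")
    pr <- sliding_window_max(g$time_h, pct, window_h, basis = "change")
    dplyr::mutate(base, onset_time_h = onset,
                  peak_rate_time_h = pr$peak_time_h,
                  peak_time_h = pk$peak_time_h)
  })
  dplyr::bind_rows(rows)
}

#' Lags between the landmarks of two readouts
#'
#' For each trigger, subtracts the landmarks of `readout_a` from those of
#' `readout_b`; a positive lag means `readout_b` reaches the landmark later.
#' Missing landmarks propagate as `NA`.
#'
#' @param landmarks A landmark table from [landmark_extract()].
#' @param readout_a,readout_b Readout labels present in the table.
#' @return A tibble with columns `trigger`, `readout_a`, `readout_b`,
#'   `onset_lag_h`, `peak_rate_lag_h`, `peak_lag_h`.
#' @export
pairwise_lag <- function(landmarks, readout_a, readout_b) {
  need <- c("trigger", "readout", "onset_time_h", "peak_rate_time_h",
            "peak_time_h")
  stopifnot(all(need %in% names(landmarks)))
  a <- landmarks[landmarks$readout == readout_a, ]
  b <- landmarks[landmarks$readout == readout_b, ]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("both readouts must be present in the landmark table", call. = FALSE)
  }
  merged <- dplyr::inner_join(a, b, by = "trigger",
                              suffix = c("_a", "_b"))
  tibble::tibble(
    trigger = merged$trigger,
    readout_a = readout_a,
    readout_b = readout_b,
    onset_lag_h = merged$onset_time_h_b - merged$onset_time_h_a,
    peak_rate_lag_h = merged$peak_rate_time_h_b - merged$peak_rate_time_h_a,
    peak_lag_h = merged$peak_time_h_b - merged$peak_time_h_a
  )
}

#' All pairwise landmark lags of a study
#'
#' Convenience wrapper producing the full lag matrix (every ordered readout
#' pair) per trigger.
#'
#' @inheritParams landmark_extract
#' @return A tibble of lags for every ordered pair of readouts.
#' @export
lag_matrix <- function(panel, onset_fraction = 0.1, window_h = 2.0) {
  lm <- landmark_extract(panel, onset_fraction, window_h)
  readouts <- unique(lm$readout)
  pairs <- expand.grid(a = readouts, b = readouts,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  dplyr::bind_rows(Map(function(a, b) pairwise_lag(lm, a, b),
                       pairs$a, pairs$b))
}
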