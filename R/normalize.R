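# Readout normalization: LDH percent cytotoxicity and IL-1b:IL-18 ratios.

#' Subtract the reference-wavelength background from LDH absorbances
#'
#' Colorimetric LDH assays read formazan absorbance at 490 nm and an optical
#' background at 680 nm; the net signal is their difference.
#'
#' @param a490,a680 Absorbance readings (vectorized).
#' @return `a490 - a680`.
#' @examples
#' background_subtract(0.8, 0.1)
#' @export
background_subtract <- function(a490, a680) {
  stopifnot(is.numeric(a490), is.numeric(a680))
  a490 - a680
}

#' Percent cytotoxicity from an LDH absorbance triplet
#'
#' \deqn{\%cytotoxicity = 100 \cdot \frac{treated - spontaneous}{maximum - spontaneous}}
#'
#' computed on background-subtracted absorbances. The quantity is invariant
#' to adding a constant to all three readings and to rescaling all three by a
#' common factor, so it is unit- and offset-free. With noisy inputs it can
#' fall outside \[0, 100\]; such values are reported as-is with a warning
#' rather than clipped.
#'
#' @param treated Treated-well LDH activity (vectorized over time/wells).
#' @param spontaneous Spontaneous-release control (untreated lysis baseline).
#' @param maximum Maximum-release control (full lysis).
#' @return Percent cytotoxicity, same length as `treated`.
#' @examples
#' percent_cytotoxicity(0.6, 0.2, 1.0)  # 50
#' @export
percent_cytotoxicity <- function(treated, spontaneous, maximum) {
  stopifnot(is.numeric(treated), is.numeric(spontaneous), is.numeric(maximum))
  if (any(maximum <= spontaneous)) {
    stop("`maximum` must exceed `spontaneous` (undefined denominator)",
         call. = FALSE)
  }
  pct <- 100 * (treated - spontaneous) / (maximum - spontaneous)
  out_of_range <- is.finite(pct) & (pct < 0 | pct > 100)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " percent-cytotoxicity value(s) outside [0, 100] (noisy inputs);",
            " reported as-is", call. = FALSE)
  }
  pct
}

#' Convert simulated LDH triplets to a percent-cytotoxicity panel
#'
#' Applies [percent_cytotoxicity()] row-wise to an LDH triplet table (as
#' produced by [simulate_ldh_series()] or read from file) and returns a tidy
#' panel slice with readout `"ldh_pct"`, mergeable with the other readouts.
#'
#' @param ldh A tibble with columns `trigger`, `replicate`, `time_h`,
#'   `a_treated`, `a_spontaneous`, `a_maximum`.
#' @return A tidy panel tibble (readout `"ldh_pct"`).
#' @export
ldh_percent_panel <- function(ldh) {
  needed <- c("trigger", "replicate", "time_h", "a_treated", "a_spontaneous",
              "a_maximum")
  missing_cols <- setdiff(needed, names(ldh))
  if (length(missing_cols) > 0) {
    stop("LDH table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    trigger = ldh$trigger,
    readout = "ldh_pct",
    replicate = ldh$replicate,
    field = NA_integer_,
    time_h = ldh$time_h,
    value = percent_cytotoxicity(ldh$a_treated, ldh$a_spontaneous,
                                 ldh$a_maximum)
  )
}

#' IL-1b:IL-18 concentration ratio over time
#'
#' Elementwise ratio of two aligned concentration series. Time points where
#' the denominator is at or below `il18_floor` (e.g. below the assay's lower
#' detection bound) are undefined (`NA`) rather than clipped.
#'
#' @param il1b,il18 Tibbles (or data frames) with columns `time_h` and
#'   `value` on identical time grids.
#' @param il18_floor Detection floor for the denominator (same units as
#'   `il18$value`).
#' @return A tibble with columns `time_h` and `ratio`.
#' @examples
#' a <- tibble::tibble(time_h = 0:3, value = c(0, 2, 5, 7.5))
#' b <- tibble::tibble(time_h = 0:3, value = c(0, 1, 2, 2))
#' cytokine_ratio(a, b)
#' @export
cytokine_ratio <- function(il1b, il18, il18_floor = 0) {
  stopifnot(all(c("time_h", "value") %in% names(il1b)),
            all(c("time_h", "value") %in% names(il18)))
  if (nrow(il1b) != nrow(il18) ||
      any(abs(il1b$time_h - il18$time_h) > 1e-9)) {
    stop("IL-1b and IL-18 series are not on the same time grid", call. = FALSE)
  }
  defined <- il18$value > il18_floor
  tibble::tibble(
    time_h = il1b$time_h,
    ratio = ifelse(defined, il1b$value / il18$value, NA_real_)
  )
}

#' Replicate-aware cytokine-ratio trajectories for a study panel
#'
#' Computes, per trigger, the IL-1b:IL-18 ratio of the replicate-mean
#' concentrations together with per-replicate ratios; the ratio SEM is the
#' SEM of the replicate-level ratios (no delta-method approximation).
#'
#' @param panel A tidy panel containing readouts `IL1B_pg_ml` and
#'   `IL18_pg_ml`.
#' @param il18_floor Denominator detection floor (pg/mL).
#' @return A tibble with columns `trigger`, `time_h`, `ratio` (of replicate
#'   means), `ratio_sem` (across replicate-level ratios), `n`.
#' @export
panel_cytokine_ratio <- function(panel, il18_floor = 0) {
  validate_panel(panel)
  cyt <- panel[panel$readout %in% c("IL1B_pg_ml", "IL18_pg_ml"), ]
  if (nrow(cyt) == 0) stop("panel has no cytokine readouts", call. = FALSE)
  wide <- tidyr::pivot_wider(
    aggregate_replicates(cyt),
    names_from = "readout", values_from = "value"
  )
  per_rep <- dplyr::mutate(
    wide,
    rep_ratio = ifelse(.data$IL18_pg_ml > il18_floor,
                       .data$IL1B_pg_ml / .data$IL18_pg_ml, NA_real_)
  )
  dplyr::summarise(
    dplyr::group_by(per_rep, .data$trigger, .data$time_h),
    ratio = ifelse(mean(.data$IL18_pg_ml) > il18_floor,
                   mean(.data$IL1B_pg_ml) / mean(.data$IL18_pg_ml), NA_real_),
    ratio_sem = stats::sd(.data$rep_ratio, na.rm = TRUE) /
      sqrt(max(sum(!is.na(.data$rep_ratio)), 1)),
    n = dplyr::n(),
    .groups = "drop"
  )
}
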