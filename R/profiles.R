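#' Generative parameters for one inflammasome trigger
#'
#' A `trigger_profile` bundles the kinetic parameters that the synthetic-study
#' generator uses for one second-signal trigger (e.g. ATP, MSU crystals,
#' nigericin): a unimodal ASC-speck pulse, monotone sigmoidal cumulative
#' cytokine release, and a monotone LDH (lysis) rise. The same object doubles
#' as ground truth for parameter-recovery tests.
#'
#' The noiseless speck curve is the gamma-type pulse
#' \eqn{m(t) = A (t/t_p)^k e^{k(1 - t/t_p)}}, which attains its maximum `A`
#' exactly at `speck_peak_time_h`. When `signal_loss_time_h` is set, the curve
#' is multiplied by \eqn{e^{-(t - t_{loss})/\tau_{loss}}} past that time,
#' emulating the rapid GFP-signal loss seen with nigericin. Cytokine and LDH
#' curves are logistic in time, shifted and scaled so they start at zero.
#'
#' @param name Label for the trigger (used as the `trigger` column in panels).
#' @param speck_peak_time_h Time of the noiseless speck-count maximum (hours,
#'   > 0).
#' @param speck_amplitude Expected maximum speck count per imaged field
#'   (specks/field, >= 0).
#' @param speck_shape_k Dimensionless pulse sharpness (> 0). Larger values give
#'   a narrower pulse; the noiseless maximum rate of increase falls at
#'   \eqn{t_p (1 - 1/\sqrt{k})}.
#' @param signal_loss_time_h Time after which the speck signal decays
#'   exponentially to zero (hours), or `NULL` for no loss.
#' @param signal_loss_tau_h Decay time constant of the signal loss (hours).
#' @param cyt_max_il1b,cyt_max_il18 Plateau extracellular concentrations
#'   (pg/mL, >= 0).
#' @param cyt_t50_h,cyt_tau_h Logistic midpoint and time constant of cytokine
#'   release (hours; `cyt_tau_h` > 0). Shared by the two interleukins.
#' @param ldh_max_frac Fraction of maximum (full-lysis) LDH release approached
#'   at late times, in \[0, 1\].
#' @param ldh_t50_h,ldh_tau_h Logistic midpoint and time constant of the LDH
#'   rise (hours; `ldh_tau_h` > 0).
#' @param count_noise Draw speck counts from a Poisson distribution with the
#'   noiseless curve as mean (`TRUE`) or return the noiseless mean (`FALSE`).
#' @param conc_cv Coefficient of variation of the multiplicative (lognormal)
#'   noise on concentrations and LDH increments (>= 0; 0 = noiseless).
#'
#' @return An object of class `trigger_profile` (a named list).
#' @seealso [trigger_preset()], [study_design()], [simulate_study()]
#' @examples
#' p <- trigger_profile("atp", speck_peak_time_h = 3, speck_amplitude = 50,
#'                      cyt_max_il1b = 700, cyt_max_il18 = 100,
#'                      cyt_t50_h = 18, cyt_tau_h = 2.5,
#'                      ldh_max_frac = 0.25, ldh_t50_h = 18, ldh_tau_h = 2)
#' @export
trigger_profile <- function(name,
                            speck_peak_time_h,
                            speck_amplitude,
                            speck_shape_k = 2,
                            signal_loss_time_h = NULL,
                            signal_loss_tau_h = 0.5,
                            cyt_max_il1b = 0,
                            cyt_max_il18 = 0,
                            cyt_t50_h = 6,
                            cyt_tau_h = 2,
                            ldh_max_frac = 0,
                            ldh_t50_h = 6,
                            ldh_tau_h = 2,
                            count_noise = TRUE,
                            conc_cv = 0.15) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  check_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
    }
  }
  check_pos(speck_peak_time_h, "speck_peak_time_h")
  check_nonneg(speck_amplitude, "speck_amplitude")
  check_pos(speck_shape_k, "speck_shape_k")
  if (!is.null(signal_loss_time_h)) {
    check_pos(signal_loss_time_h, "signal_loss_time_h")
    check_pos(signal_loss_tau_h, "signal_loss_tau_h")
  }
  check_nonneg(cyt_max_il1b, "cyt_max_il1b")
  check_nonneg(cyt_max_il18, "cyt_max_il18")
  check_pos(cyt_t50_h, "cyt_t50_h")
  check_pos(cyt_tau_h, "cyt_tau_h")
  if (!is.numeric(ldh_max_frac) || length(ldh_max_frac) != 1 ||
      !is.finite(ldh_max_frac) || ldh_max_frac < 0 || ldh_max_frac > 1) {
    stop("`ldh_max_frac` must be in [0, 1]", call. = FALSE)
  }
  check_pos(ldh_t50_h, "ldh_t50_h")
  check_pos(ldh_tau_h, "ldh_tau_h")
  check_nonneg(conc_cv, "conc_cv")

  structure(list(
    name = name,
    speck_peak_time_h = speck_peak_time_h,
    speck_amplitude = speck_amplitude,
    speck_shape_k = speck_shape_k,
    signal_loss_time_h = signal_loss_time_h,
    signal_loss_tau_h = signal_loss_tau_h,
    cyt_max_il1b = cyt_max_il1b,
    cyt_max_il18 = cyt_max_il18,
    cyt_t50_h = cyt_t50_h,
    cyt_tau_h = cyt_tau_h,
    ldh_max_frac = ldh_max_frac,
    ldh_t50_h = ldh_t50_h,
    ldh_tau_h = ldh_tau_h,
    count_noise = isTRUE(count_noise),
    conc_cv = conc_cv
  ), class = "trigger_profile")
}

#' @export
print.trigger_profile <- function(x, ...) {
  cat("<trigger_profile> ", x$name, "\n", sep = "")
  cat("  speck pulse: peak ", x$speck_peak_time_h, " h, amplitude ",
      x$speck_amplitude, " specks/field, shape k = ", x$speck_shape_k, "\n",
      sep = "")
  if (!is.null(x$signal_loss_time_h)) {
    cat("  signal loss after ", x$signal_loss_time_h, " h (tau ",
        x$signal_loss_tau_h, " h)\n", sep = "")
  }
  cat("  cytokines: IL-1b max ", x$cyt_max_il1b, ", IL-18 max ",
      x$cyt_max_il18, " pg/mL; t50 ", x$cyt_t50_h, " h, tau ",
      x$cyt_tau_h, " h\n", sep = "")
  cat("  LDH: max fraction ", x$ldh_max_frac, ", t50 ", x$ldh_t50_h,
      " h, tau ", x$ldh_tau_h, " h\n", sep = "")
  invisible(x)
}

#' Shipped trigger presets
#'
#' Editable presets encoding the kinetic archetypes of the three canonical
#' NLRP3 second signals in LPS-primed THP-1-derived macrophages:
#'
#' * `atp_like` — low-amplitude speck pulse peaking at 3 h; slow, late cytokine
#'   release (midpoint 18 h) with a high IL-1b:IL-18 plateau ratio (7:1); LDH
#'   rising late to ~25% of maximum.
#' * `msu_like` — potent speck pulse peaking at 6 h; rapid early cytokine
#'   release with plateau ratio 5.5:1; intermediate lysis.
#' * `nigericin_like` — fast, high speck pulse peaking at 2 h with GFP signal
#'   loss switched on after 2.5 h; the strongest, fastest cytokine release
#'   (plateau ratio 3.75:1) and extensive lysis.
#'
#' @param name Preset name, or leave missing to get all presets as a named
#'   list.
#' @return A `trigger_profile` (single `name`) or named list of all three.
#' @examples
#' trigger_preset("nigericin_like")
#' names(trigger_presets())
#' @export
trigger_preset <- function(name = c("atp_like", "msu_like", "nigericin_like")) {
  name <- match.arg(name)
  trigger_presets()[[name]]
}

#' @rdname trigger_preset
#' @export
trigger_presets <- function() {
  list(
    atp_like = trigger_profile(
      name = "ATP",
      speck_peak_time_h = 3, speck_amplitude = 50, speck_shape_k = 1.2,
      cyt_max_il1b = 700, cyt_max_il18 = 100,
      cyt_t50_h = 18, cyt_tau_h = 2.5,
      ldh_max_frac = 0.25, ldh_t50_h = 18, ldh_tau_h = 2
    ),
    msu_like = trigger_profile(
      name = "MSU",
      speck_peak_time_h = 6, speck_amplitude = 150, speck_shape_k = 1.6,
      cyt_max_il1b = 1100, cyt_max_il18 = 200,
      cyt_t50_h = 2, cyt_tau_h = 1,
      ldh_max_frac = 0.4, ldh_t50_h = 6, ldh_tau_h = 3
    ),
    nigericin_like = trigger_profile(
      name = "nigericin",
      speck_peak_time_h = 2, speck_amplitude = 160, speck_shape_k = 2.56,
      signal_loss_time_h = 2.5, signal_loss_tau_h = 0.5,
      cyt_max_il1b = 3000, cyt_max_il18 = 800,
      cyt_t50_h = 0.8, cyt_tau_h = 0.5,
      ldh_max_frac = 0.9, ldh_t50_h = 1.5, ldh_tau_h = 1
    )
  )
}

#' Sampling design of a synthetic study
#'
#' Describes how one readout is sampled: how many experimental replicates,
#' how many technical image fields per replicate, and the time grid. Defaults
#' match the live-imaging arm of the emulated study design: n = 5 replicates,
#' 12 fields, one frame every 30 min for 21 h. Cytokine/LDH sampling typically
#' uses `study_design(t_end_h = 24, dt_h = 1)`.
#'
#' @param n_replicates Number of experimental (biological) replicates.
#' @param n_fields Number of technical image fields per replicate.
#' @param t_start_h,t_end_h,dt_h Sampling grid in hours; `dt_h > 0`, at least
#'   3 grid points (needed for acceleration).
#' @param seed Integer seed; per-replicate substreams are derived from it so
#'   adding replicates never perturbs earlier ones.
#' @return An object of class `study_design`.
#' @examples
#' study_design(seed = 7)
#' @export
study_design <- function(n_replicates = 5,
                         n_fields = 12,
                         t_start_h = 0,
                         t_end_h = 21,
                         dt_h = 0.5,
                         seed = 1L) {
  stopifnot(is.numeric(n_replicates), n_replicates >= 1,
            is.numeric(n_fields), n_fields >= 1)
  if (!is.numeric(dt_h) || dt_h <= 0) stop("`dt_h` must be > 0", call. = FALSE)
  if (t_end_h <= t_start_h) stop("`t_end_h` must exceed `t_start_h`", call. = FALSE)
  times <- seq(t_start_h, t_end_h, by = dt_h)
  if (length(times) < 3) {
    stop("time grid must have at least 3 points", call. = FALSE)
  }
  structure(list(
    n_replicates = as.integer(n_replicates),
    n_fields = as.integer(n_fields),
    t_start_h = t_start_h,
    t_end_h = t_end_h,
    dt_h = dt_h,
    times = times,
    seed = as.integer(seed)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> n_replicates = ", x$n_replicates,
      ", n_fields = ", x$n_fields,
      ", grid = [", x$t_start_h, ", ", x$t_end_h, "] h by ", x$dt_h,
      " h, seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
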