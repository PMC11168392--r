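# Synthetic-study generator: trigger-specific readout kinetics with known
# ground truth. All randomness flows through per-replicate substreams derived
# from design$seed, so identical (profile, design) pairs give identical panels
# and adding replicates never changes earlier ones.

#' Noiseless mean curves of the generator
#'
#' `speck_mean()` is the gamma-type pulse
#' \eqn{m(t) = A (t/t_p)^k e^{k(1 - t/t_p)}} (maximum `A` at \eqn{t_p}),
#' optionally multiplied by an exponential decay after `signal_loss_time_h`.
#' `cytokine_mean()` is a logistic in time, shifted and scaled so that
#' \eqn{C(0) = 0} and \eqn{C \to C_{max}}; it is non-decreasing.
#'
#' @param t Times in hours (>= 0).
#' @param profile A [trigger_profile()].
#' @param analyte `"IL1B"` or `"IL18"` — selects the plateau concentration.
#' @return Numeric vector of means at `t`.
#' @export
speck_mean <- function(t, profile) {
  tp <- profile$speck_peak_time_h
  k <- profile$speck_shape_k
  A <- profile$speck_amplitude
  m <- ifelse(t <= 0, 0, A * (t / tp)^k * exp(k * (1 - t / tp)))
  tl <- profile$signal_loss_time_h
  if (!is.null(tl)) {
    loss <- ifelse(t > tl, exp(-(t - tl) / profile$signal_loss_tau_h), 1)
    m <- m * loss
  }
  m
}

#' @rdname speck_mean
#' @export
cytokine_mean <- function(t, profile, analyte = c("IL1B", "IL18")) {
  analyte <- match.arg(analyte)
  cmax <- if (analyte == "IL1B") profile$cyt_max_il1b else profile$cyt_max_il18
  scaled_logistic(t, profile$cyt_t50_h, profile$cyt_tau_h) * cmax
}

# Logistic rise normalized so g(0) = 0, g(Inf) = 1.
scaled_logistic <- function(t, t50, tau) {
  s <- stats::plogis((t - t50) / tau)
  s0 <- stats::plogis(-t50 / tau)
  (s - s0) / (1 - s0)
}

# Lognormal multiplicative noise factors with mean 1 and given CV.
lnorm_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
}

#' Simulate ASC-speck count time series
#'
#' Generates per-field speck counts on the design's time grid for one trigger.
#' The noiseless field mean follows [speck_mean()]; with `count_noise` on,
#' each (replicate, field, time) count is drawn from a Poisson distribution
#' with that mean — the standard dispersion model for particle counts.
#'
#' @param profile A [trigger_profile()].
#' @param design A [study_design()].
#' @return A tibble panel with columns `trigger`, `readout`
#'   (`"speck_count"`), `replicate`, `field`, `time_h`, `value`, carrying the
#'   generative ground truth as attribute `"ground_truth"` (see
#'   [ground_truth()]).
#' @examples
#' panel <- simulate_speck_series(trigger_preset("atp_like"),
#'                                study_design(seed = 1))
#' head(panel)
#' @export
simulate_speck_series <- function(profile, design) {
  stopifnot(inherits(profile, "trigger_profile"),
            inherits(design, "study_design"))
  times <- design$times
  m <- speck_mean(times, profile)
  out <- vector("list", design$n_replicates)
  for (r in seq_len(design$n_replicates)) {
    seed_r <- substream_seed(design$seed, profile$name, "speck", r)
    vals <- with_substream(seed_r, {
      if (profile$count_noise) {
        matrix(stats::rpois(length(times) * design$n_fields, rep(m, design$n_fields)),
               nrow = length(times))
      } else {
        matrix(rep(m, design$n_fields), nrow = length(times))
      }
    })
    out[[r]] <- tibble::tibble(
      trigger = profile$name,
      readout = "speck_count",
      replicate = r,
      field = rep(seq_len(design$n_fields), each = length(times)),
      time_h = rep(times, design$n_fields),
      value = as.numeric(vals)
    )
  }
  panel <- dplyr::bind_rows(out)
  attr(panel, "ground_truth") <- tibble::tibble(
    trigger = profile$name,
    readout = "speck_count",
    peak_time_h = profile$speck_peak_time_h,
    peak_value = profile$speck_amplitude
  )
  panel
}

#' Simulate extracellular cytokine time series
#'
#' Cumulative cytokine release per replicate on the design grid: a monotone
#' scaled-logistic mean (see [cytokine_mean()]) with multiplicative lognormal
#' noise of coefficient of variation `profile$conc_cv`, the standard noise
#' model for immunoassay concentrations. Values are non-negative by
#' construction.
#'
#' @inheritParams simulate_speck_series
#' @param analyte `"IL1B"` or `"IL18"`.
#' @return A tibble panel (readout `"IL1B_pg_ml"` or `"IL18_pg_ml"`, `field`
#'   is `NA` — cytokines are measured per replicate supernatant) with
#'   ground-truth attribute.
#' @export
simulate_cytokine_series <- function(profile, design, analyte = c("IL1B", "IL18")) {
  stopifnot(inherits(profile, "trigger_profile"),
            inherits(design, "study_design"))
  analyte <- match.arg(analyte)
  times <- design$times
  m <- cytokine_mean(times, profile, analyte)
  readout <- if (analyte == "IL1B") "IL1B_pg_ml" else "IL18_pg_ml"
  out <- vector("list", design$n_replicates)
  for (r in seq_len(design$n_replicates)) {
    seed_r <- substream_seed(design$seed, profile$name, readout, r)
    vals <- with_substream(seed_r, m * lnorm_factors(length(m), profile$conc_cv))
    out[[r]] <- tibble::tibble(
      trigger = profile$name,
      readout = readout,
      replicate = r,
      field = NA_integer_,
      time_h = times,
      value = vals
    )
  }
  panel <- dplyr::bind_rows(out)
  cmax <- if (analyte == "IL1B") profile$cyt_max_il1b else profile$cyt_max_il18
  attr(panel, "ground_truth") <- tibble::tibble(
    trigger = profile$name,
    readout = readout,
    peak_time_h = design$t_end_h,
    peak_value = cmax * scaled_logistic(design$t_end_h, profile$cyt_t50_h,
                                        profile$cyt_tau_h)
  )
  panel
}

#' Simulate raw LDH absorbance triplets
#'
#' Emulates a colorimetric LDH cytotoxicity assay: for each replicate and time
#' the generator emits the background-subtracted (490 nm minus 680 nm)
#' absorbances of the treated well plus the per-replicate spontaneous-release
#' and maximum-release (full lysis) controls, which are constant over time
#' within a replicate. The treated signal interpolates from the spontaneous
#' level towards `spontaneous + ldh_max_frac * (maximum - spontaneous)` along
#' a scaled logistic; multiplicative lognormal noise (CV `conc_cv`) acts on
#' the lysis increment.
#'
#' Feeding the triplets through [percent_cytotoxicity()] recovers
#' `100 * ldh_max_frac * g(t)` up to noise, where `g` is the scaled logistic.
#'
#' @inheritParams simulate_speck_series
#' @param a_spontaneous,a_maximum Control absorbance levels (arbitrary units).
#' @return A tibble with columns `trigger`, `replicate`, `time_h`,
#'   `a_treated`, `a_spontaneous`, `a_maximum`.
#' @export
simulate_ldh_series <- function(profile, design,
                                a_spontaneous = 0.2, a_maximum = 1.2) {
  stopifnot(inherits(profile, "trigger_profile"),
            inherits(design, "study_design"))
  if (a_maximum <= a_spontaneous) {
    stop("`a_maximum` must exceed `a_spontaneous`", call. = FALSE)
  }
  times <- design$times
  g <- scaled_logistic(times, profile$ldh_t50_h, profile$ldh_tau_h)
  out <- vector("list", design$n_replicates)
  for (r in seq_len(design$n_replicates)) {
    seed_r <- substream_seed(design$seed, profile$name, "ldh", r)
    noisy_g <- with_substream(seed_r, g * lnorm_factors(length(g), profile$conc_cv))
    out[[r]] <- tibble::tibble(
      trigger = profile$name,
      replicate = r,
      time_h = times,
      a_treated = a_spontaneous +
        profile$ldh_max_frac * (a_maximum - a_spontaneous) * noisy_g,
      a_spontaneous = a_spontaneous,
      a_maximum = a_maximum
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate a complete multi-trigger study
#'
#' Runs the three readout generators for every profile: specks on the imaging
#' grid (default every 30 min for 21 h, 12 fields), cytokines and LDH on the
#' sampling grid (default every hour for 24 h). Returns all panels plus the
#' generative ground truth.
#'
#' @param profiles A list of [trigger_profile()]s (default: the three shipped
#'   presets).
#' @param n_replicates,n_fields Replication structure (defaults 5 and 12).
#' @param speck_design,cyt_design Optional [study_design()] overrides for the
#'   imaging and sampling grids.
#' @param seed Integer seed for the whole study.
#' @return A list with elements `panel` (speck + cytokine readouts, long
#'   tibble), `ldh` (absorbance triplets), and `ground_truth`.
#' @examples
#' study <- simulate_study(seed = 42)
#' dplyr::count(study$panel, trigger, readout)
#' @export
simulate_study <- function(profiles = trigger_presets(),
                           n_replicates = 5,
                           n_fields = 12,
                           speck_design = NULL,
                           cyt_design = NULL,
                           seed = 1L) {
  if (inherits(profiles, "trigger_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "trigger_profile")))
  speck_design <- speck_design %||%
    study_design(n_replicates, n_fields, 0, 21, 0.5, seed = seed)
  cyt_design <- cyt_design %||%
    study_design(n_replicates, 1, 0, 24, 1.0, seed = seed)

  panels <- list()
  truths <- list()
  ldh <- list()
  for (p in profiles) {
    sp <- simulate_speck_series(p, speck_design)
    il1b <- simulate_cytokine_series(p, cyt_design, "IL1B")
    il18 <- simulate_cytokine_series(p, cyt_design, "IL18")
    panels <- c(panels, list(sp, il1b, il18))
    truths <- c(truths, list(ground_truth(sp), ground_truth(il1b),
                             ground_truth(il18)))
    ldh <- c(ldh, list(simulate_ldh_series(p, cyt_design)))
  }
  list(
    panel = dplyr::bind_rows(panels),
    ldh = dplyr::bind_rows(ldh),
    ground_truth = dplyr::bind_rows(truths)
  )
}

#' Retrieve the generative ground truth attached to a simulated panel
#'
#' @param x A panel produced by one of the simulators.
#' @return A tibble of true peak times/values, or `NULL` if absent.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)
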