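# Pooled-resampling bootstrap for two-group comparisons with small n, plus
# the Shapiro-Wilk normality gate.

#' Pooled-resampling bootstrap test for two small groups
#'
#' Non-parametric two-sided test in the spirit of Dwivedi et al.'s bootstrap
#' framework for small samples. The observed statistic is the mean difference
#' `mean(a) - mean(b)` (or a Welch-type t statistic with
#' `statistic = "t_type"`). The null distribution is formed by pooled
#' resampling: both groups are pooled, `length(a)` and `length(b)` values are
#' drawn with replacement from the pool, and the statistic recomputed,
#' `n_boot` times. The p-value uses the plus-one correction
#' \deqn{p = \frac{1 + \#\{|T^*| \ge |T_{obs}|\}}{n\_boot + 1},}
#' so p is never exactly 0. The confidence interval is the percentile
#' interval of the statistic under resampling each group from itself.
#'
#' @param a,b Numeric vectors (>= 2 finite values each).
#' @param n_boot Number of resamples (>= 1000 recommended for reported
#'   analyses).
#' @param statistic `"mean_diff"` or `"t_type"` (Welch-type denominator).
#' @param alpha Level for the percentile CI (default 0.05 gives a 95% CI).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @return An object of class `bootstrap_result`: a list with
#'   `observed_stat`, `p_value`, `ci_low`, `ci_high`, `n_boot`, `seed`,
#'   `statistic`, `n_a`, `n_b`.
#' @examples
#' bootstrap_test(c(5, 7, 9, 6, 8), c(1, 2, 3, 2, 2), n_boot = 2000, seed = 1)
#' @export
bootstrap_test <- function(a, b, n_boot = 10000,
                           statistic = c("mean_diff", "t_type"),
                           alpha = 0.05, seed = 1L) {
  statistic <- match.arg(statistic)
  if (!is.numeric(a) || !is.numeric(b) || !all(is.finite(a)) ||
      !all(is.finite(b))) {
    stop("`a` and `b` must be numeric with finite values only", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  stopifnot(n_boot >= 1)

  stat_fun <- if (statistic == "mean_diff") {
    function(x, y) mean(x) - mean(y)
  } else {
    function(x, y) {
      se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
      d <- mean(x) - mean(y)
      if (se == 0) {
        if (d == 0) 0 else sign(d) * Inf
      } else {
        d / se
      }
    }
  }
  observed <- stat_fun(a, b)
  pool <- c(a, b)

  res <- with_substream(seed, {
    # Null distribution: both group sizes resampled from the pooled values.
    ia <- matrix(sample.int(na + nb, na * n_boot, replace = TRUE), nrow = na)
    ib <- matrix(sample.int(na + nb, nb * n_boot, replace = TRUE), nrow = nb)
    null_stats <- if (statistic == "mean_diff") {
      colMeans(matrix(pool[ia], nrow = na)) -
        colMeans(matrix(pool[ib], nrow = nb))
    } else {
      vapply(seq_len(n_boot), function(j) {
        stat_fun(pool[ia[, j]], pool[ib[, j]])
      }, numeric(1))
    }
    # CI: each group resampled from itself.
    ja <- matrix(sample.int(na, na * n_boot, replace = TRUE), nrow = na)
    jb <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = nb)
    ci_stats <- if (statistic == "mean_diff") {
      colMeans(matrix(a[ja], nrow = na)) - colMeans(matrix(b[jb], nrow = nb))
    } else {
      vapply(seq_len(n_boot), function(j) {
        stat_fun(a[ja[, j]], b[jb[, j]])
      }, numeric(1))
    }
    list(null_stats = null_stats, ci_stats = ci_stats)
  })

  p <- (1 + sum(abs(res$null_stats) >= abs(observed))) / (n_boot + 1)
  ci <- stats::quantile(res$ci_stats, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
  structure(list(
    observed_stat = observed,
    p_value = p,
    ci_low = ci[1],
    ci_high = ci[2],
    n_boot = as.integer(n_boot),
    seed = as.integer(seed),
    statistic = statistic,
    alpha = alpha,
    n_a = na,
    n_b = nb
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> pooled-resampling test (", x$statistic, ")\n",
      sep = "")
  cat(sprintf("  observed = %.4g, p = %.4g (n_boot = %d, seed = %d)\n",
              x$observed_stat, x$p_value, x$n_boot, x$seed))
  cat(sprintf("  %g%% percentile CI: [%.4g, %.4g]; n = %d vs %d\n",
              100 * (1 - x$alpha), x$ci_low, x$ci_high, x$n_a, x$n_b))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Runs the standard Shapiro-Wilk test and flags whether the sample looks
#' normal at level `alpha`. The flag is informational only: downstream
#' comparisons always use the pooled-resampling bootstrap, which is valid
#' either way — the gate merely documents why the non-parametric route is
#' appropriate.
#'
#' @param values Numeric sample (3 <= n <= 5000, not constant).
#' @param alpha Flagging level (default 0.05).
#' @return A list with `statistic`, `p_value`, `normal` (logical).
#' @examples
#' shapiro_wilk_gate(rnorm(20))
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || length(values) < 3) {
    stop("need at least 3 numeric values", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("Shapiro-Wilk statistic is undefined for a constant sample",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(
    statistic = unname(sw$statistic),
    p_value = sw$p.value,
    normal = sw$p.value > alpha
  )
}

#' Bootstrap comparisons between two conditions at selected times
#'
#' For each requested time point, gathers the replicate-level values of one
#' readout under two conditions (triggers) and runs [bootstrap_test()].
#' Per-time seeds are substreamed from `seed`, so adding time points never
#' changes existing results. Raw p-values are reported alongside a
#' Benjamini-Hochberg-adjusted column.
#'
#' @param panel A tidy panel (technical fields are averaged first).
#' @param readout The readout to compare (e.g. `"speck_count"`).
#' @param condition_a,condition_b Trigger labels to compare.
#' @param times Time points (hours) at which to test; all must be present
#'   for both conditions.
#' @param n_boot,statistic,alpha Passed to [bootstrap_test()].
#' @param seed Integer seed for the whole comparison table.
#' @return A tibble with columns `condition_a`, `condition_b`, `readout`,
#'   `time_h`, `stat`, `p_raw`, `p_bh`, `ci_low`, `ci_high`, `n_boot`,
#'   `seed`.
#' @export
compare_at_times <- function(panel, readout, condition_a, condition_b,
                             times, n_boot = 10000,
                             statistic = c("mean_diff", "t_type"),
                             alpha = 0.05, seed = 1L) {
  statistic <- match.arg(statistic)
  panel <- aggregate_replicates(panel)
  panel <- panel[panel$readout == readout, ]
  if (nrow(panel) == 0) stop("readout not present in panel", call. = FALSE)
  rows <- lapply(times, function(tt) {
    va <- panel$value[panel$trigger == condition_a &
                        abs(panel$time_h - tt) < 1e-9]
    vb <- panel$value[panel$trigger == condition_b &
                        abs(panel$time_h - tt) < 1e-9]
    if (length(va) == 0 || length(vb) == 0) {
      stop("condition/time combination missing at t = ", tt, " h",
           call. = FALSE)
    }
    seed_t <- substream_seed(seed, readout, condition_a, condition_b, tt)
    bt <- bootstrap_test(va, vb, n_boot = n_boot, statistic = statistic,
                         alpha = alpha, seed = seed_t)
    tibble::tibble(
      condition_a = condition_a, condition_b = condition_b,
      readout = readout, time_h = tt,
      stat = bt$observed_stat, p_raw = bt$p_value,
      ci_low = bt$ci_low, ci_high = bt$ci_high,
      n_boot = bt$n_boot, seed = bt$seed
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out[, c("condition_a", "condition_b", "readout", "time_h", "stat",
          "p_raw", "p_bh", "ci_low", "ci_high", "n_boot", "seed")]
}
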