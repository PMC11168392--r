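# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and closed forms only.

# Exact p-value of the pooled-resampling test for two groups of size 3:
# every one of the 6^3 x 6^3 equally likely (a*, b*) draws is enumerated.
enum_pooled_p <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3)
  pool <- c(a, b)
  obs <- mean(a) - mean(b)
  idx <- as.matrix(expand.grid(1:6, 1:6, 1:6))
  ms <- rowMeans(matrix(pool[idx], ncol = 3))
  mean(abs(outer(ms, ms, "-")) >= abs(obs))
}

# Second difference by an explicit double loop.
second_diff_oracle <- function(value) {
  n <- length(value)
  ch <- numeric(n - 1)
  for (i in seq_len(n - 1)) ch[i] <- value[i + 1] - value[i]
  acc <- numeric(n - 2)
  for (i in seq_len(n - 2)) acc[i] <- ch[i + 1] - ch[i]
  list(change = ch, acceleration = acc)
}

# Exhaustive sliding-window search over every (window, point) pair.
sw_oracle <- function(time_h, value, window_h) {
  dt <- time_h[2] - time_h[1]
  steps <- as.integer(round(window_h / dt))
  n <- length(value)
  best_mean <- -Inf
  best_w <- NA
  for (i in seq_len(n - steps)) {
    m <- mean(value[i:(i + steps)])
    if (m > best_mean + 1e-12) {  # strict: ties keep the earliest window
      best_mean <- m
      best_w <- i
    }
  }
  idx <- best_w:(best_w + steps)
  best_i <- idx[1]
  for (j in idx) if (value[j] > value[best_i] + 1e-12) best_i <- j
  list(peak_time_h = time_h[best_i], peak_value = value[best_i],
       window_start_h = time_h[best_w], window_end_h = time_h[best_w + steps])
}

# Small random panel with technical fields, for group-mean oracles.
random_panel <- function(seed, n_rep = 3, n_fields = 2, times = 0:4) {
  withr::with_seed(seed, {
    g <- expand.grid(trigger = c("A", "B"), readout = "speck_count",
                     replicate = seq_len(n_rep), field = seq_len(n_fields),
                     time_h = times, stringsAsFactors = FALSE)
    g$value <- stats::rpois(nrow(g), 20)
    tibble::as_tibble(g)
  })
}

# A noiseless study panel: the generator with noise switched off.
noiseless_profile <- function(name = "X", tp = 3, A = 40, k = 2, ...) {
  trigger_profile(name, speck_peak_time_h = tp, speck_amplitude = A,
                  speck_shape_k = k, count_noise = FALSE, conc_cv = 0, ...)
}
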