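test_that("absolute change matches direct subtraction and the right-edge rule", {
  expect_equal(absolute_change(0:3, c(5, 5, 5, 5))$change, c(0, 0, 0))
  ch <- absolute_change(c(0, 1, 2), c(0, 2, 6))
  expect_equal(ch$change, c(2, 4))
  expect_equal(ch$time_h, c(1, 2))  # anchored to the interval's right edge
  expect_error(absolute_change(1, 5), "at least 2")
  expect_error(absolute_change(c(0, 0), c(1, 2)), "strictly increasing")
})

test_that("per-interval and per-hour variants differ by the grid constant", {
  t <- seq(0, 4, 0.5)
  v <- t^2
  expect_equal(absolute_change(t, v, per_hour = TRUE)$change,
               absolute_change(t, v)$change / 0.5)
})

test_that("telescoping: changes sum to last minus first", {
  for (seed in 1:10) {
    v <- withr::with_seed(seed, rnorm(50))
    ch <- absolute_change(seq_along(v), v)
    expect_equal(sum(ch$change), v[50] - v[1])
  }
})

test_that("acceleration is the exact second difference", {
  expect_equal(acceleration(0:3, c(0, 3, 6, 9))$acceleration, c(0, 0))
  acc <- acceleration(0:3, c(0, 1, 4, 9))
  expect_equal(absolute_change(0:3, c(0, 1, 4, 9))$change, c(1, 3, 5))
  expect_equal(acc$acceleration, c(2, 2))
  expect_error(acceleration(0:1, c(1, 2)), "at least 3")

  for (seed in 1:10) {
    v <- withr::with_seed(seed, rnorm(30))
    oracle <- second_diff_oracle(v)
    expect_equal(absolute_change(seq_along(v), v)$change, oracle$change)
    expect_equal(acceleration(seq_along(v), v)$acceleration,
                 oracle$acceleration)
  }
})

test_that("difference operators are linear", {
  t <- seq(0, 10, 0.5)
  for (seed in 1:5) {
    xy <- withr::with_seed(seed, list(x = rnorm(length(t)),
                                      y = rnorm(length(t)),
                                      a = rnorm(1), b = rnorm(1)))
    lhs_c <- absolute_change(t, xy$a * xy$x + xy$b * xy$y)$change
    rhs_c <- xy$a * absolute_change(t, xy$x)$change +
      xy$b * absolute_change(t, xy$y)$change
    expect_equal(lhs_c, rhs_c)
    lhs_a <- acceleration(t, xy$a * xy$x + xy$b * xy$y)$acceleration
    rhs_a <- xy$a * acceleration(t, xy$x)$acceleration +
      xy$b * acceleration(t, xy$y)$acceleration
    expect_equal(lhs_a, rhs_a)
  }
})

test_that("sliding_window_max selects the documented window and point", {
  # unimodal noiseless series: peak time is the global argmax
  t <- seq(0, 10, 0.5)
  v <- exp(-(t - 4)^2)
  sw <- sliding_window_max(t, v)
  expect_equal(sw$peak_time_h, 4)
  expect_true(sw$window_start_h <= 4 && 4 <= sw$window_end_h)

  # single spike at the first grid point: first window, spike returned
  v2 <- c(10, rep(0, length(t) - 1))
  sw2 <- sliding_window_max(t, v2)
  expect_equal(sw2$peak_time_h, 0)
  expect_equal(sw2$window_start_h, 0)
  expect_equal(sw2$peak_value, 10)

  # ties resolve to the earliest window and earliest point
  v3 <- rep(1, length(t))
  sw3 <- sliding_window_max(t, v3)
  expect_equal(sw3$window_start_h, 0)
  expect_equal(sw3$peak_time_h, 0)

  expect_error(sliding_window_max(c(0, 0.5), c(1, 2), window_h = 2),
               "span")
  expect_error(sliding_window_max(t, v, window_h = 0.7), "multiple")
})

test_that("sliding_window_max equals exhaustive search on random series", {
  for (seed in 1:30) {
    n <- withr::with_seed(seed, sample(8:40, 1))
    v <- withr::with_seed(seed + 100, rnorm(n))
    t <- seq(0, by = 0.5, length.out = n)
    got <- sliding_window_max(t, v, window_h = 2)
    want <- sw_oracle(t, v, 2)
    expect_equal(got$peak_time_h, want$peak_time_h)
    expect_equal(got$peak_value, want$peak_value)
    expect_equal(got$window_start_h, want$window_start_h)
  }
})

test_that("technical fields average into experimental replicates", {
  panel <- tibble::tibble(
    trigger = "A", readout = "speck_count", replicate = 1L,
    field = c(1L, 2L), time_h = 0, value = c(2, 4)
  )
  agg <- aggregate_replicates(panel)
  expect_equal(agg$value, 3)

  # five identical replicates: SEM is zero
  pan5 <- tibble::tibble(
    trigger = "A", readout = "speck_count", replicate = 1:5,
    field = NA_integer_, time_h = 1, value = 7
  )
  expect_equal(replicate_summary(pan5)$sem, 0)

  # random panel agrees with an independent group-mean oracle
  rp <- random_panel(3)
  agg <- aggregate_replicates(rp)
  oracle <- aggregate(value ~ trigger + readout + replicate + time_h,
                      data = rp, FUN = mean)
  merged <- merge(agg, oracle,
                  by = c("trigger", "readout", "replicate", "time_h"))
  expect_equal(merged$value.x, merged$value.y)

  # inconsistent grids across fields are rejected
  bad <- rp[!(rp$field == 2 & rp$time_h == 4), ]
  expect_error(aggregate_replicates(bad), "inconsistent")
})

test_that("per-replicate peaks average the per-replicate maxima", {
  mk <- function(times) {
    dplyr::bind_rows(lapply(seq_along(times), function(r) {
      t <- seq(0, 6, 0.5)
      v <- 40 * exp(-(t - times[r])^2)
      tibble::tibble(trigger = "A", readout = "speck_count",
                     replicate = r, field = NA_integer_, time_h = t,
                     value = v)
    }))
  }
  same <- per_replicate_peak(mk(c(3, 3, 3)))
  expect_equal(same$mean_peak_time_h, 3)
  expect_equal(same$mean_peak_value, 40)
  spread <- per_replicate_peak(mk(c(2.5, 3, 3.5)))
  expect_equal(spread$mean_peak_time_h, 3)

  # ties within one replicate resolve to the earliest time
  flat <- tibble::tibble(trigger = "A", readout = "x", replicate = 1L,
                         field = NA_integer_, time_h = 0:4,
                         value = c(0, 5, 5, 5, 0))
  expect_equal(replicate_peaks(flat)$peak_time_h, 1)
})

test_that("percent_of_max scales to [0, 100] and is idempotent", {
  expect_equal(percent_of_max(c(0, 5, 10)), c(0, 50, 100))
  expect_equal(percent_of_max(rep(3, 4)), rep(100, 4))
  v <- abs(rnorm(20)) + 0.1
  expect_equal(percent_of_max(percent_of_max(v)), percent_of_max(v))
  expect_error(percent_of_max(c(0, 0)), "positive maximum")
})
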