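test_that("zero-amplitude speck profile yields all-zero counts", {
  p <- trigger_profile("null", 3, speck_amplitude = 0)
  panel <- simulate_speck_series(p, study_design(n_replicates = 2,
                                                 n_fields = 2, seed = 1))
  expect_true(all(panel$value == 0))
})

test_that("noiseless speck pulse peaks exactly at speck_peak_time_h", {
  p <- noiseless_profile(tp = 3.0)
  panel <- simulate_speck_series(p, study_design(n_replicates = 1,
                                                 n_fields = 1, seed = 1))
  expect_equal(panel$time_h[which.max(panel$value)], 3.0)
})

test_that("Poisson speck counts track the closed-form mean", {
  p <- trigger_profile("lln", 3, speck_amplitude = 50, speck_shape_k = 2)
  des <- study_design(n_replicates = 200, n_fields = 1,
                      t_end_h = 8, dt_h = 0.5, seed = 42)
  panel <- simulate_speck_series(p, des)
  m <- speck_mean(des$times, p)
  means <- tapply(panel$value, panel$time_h, mean)
  se <- sqrt(m / 200)
  # every per-timepoint sample mean within 3 standard errors of m(t)
  expect_true(all(abs(means - m) <= pmax(3 * se, 1e-9)))
})

test_that("simulators are deterministic and replicate-substreamed", {
  p <- trigger_preset("msu_like")
  d5 <- study_design(n_replicates = 5, n_fields = 3, seed = 9)
  d3 <- study_design(n_replicates = 3, n_fields = 3, seed = 9)
  a <- simulate_speck_series(p, d5)
  b <- simulate_speck_series(p, d5)
  expect_identical(a$value, b$value)
  # adding replicates never perturbs earlier ones
  small <- simulate_speck_series(p, d3)
  expect_identical(small$value, a$value[a$replicate <= 3])
  # cytokine draws are independent of speck draws of the same seed
  il <- simulate_cytokine_series(p, d3, "IL1B")
  il2 <- simulate_cytokine_series(p, d3, "IL1B")
  expect_identical(il$value, il2$value)
})

test_that("signal loss decays the speck curve only after the switch time", {
  p <- trigger_profile("nig", 2, 100, speck_shape_k = 3,
                       signal_loss_time_h = 2.5, signal_loss_tau_h = 0.5,
                       count_noise = FALSE)
  t <- seq(0, 10, 0.5)
  m <- speck_mean(t, p)
  p0 <- trigger_profile("nig0", 2, 100, speck_shape_k = 3,
                        count_noise = FALSE)
  m0 <- speck_mean(t, p0)
  expect_identical(m[t <= 2.5], m0[t <= 2.5])
  expect_true(all(m[t > 2.5] < m0[t > 2.5]))
  expect_lt(m[t == 6], 1e-2 * max(m))
})

test_that("zero-Cmax cytokine profile yields all zeros", {
  p <- trigger_profile("null", 3, 10, cyt_max_il1b = 0)
  panel <- simulate_cytokine_series(p, study_design(n_fields = 1, seed = 1),
                                    "IL1B")
  expect_true(all(panel$value == 0))
})

test_that("noiseless cytokine release is non-decreasing, starts at 0, below Cmax", {
  p <- trigger_profile("c", 3, 10, cyt_max_il1b = 500, cyt_t50_h = 6,
                       cyt_tau_h = 2, conc_cv = 0)
  panel <- simulate_cytokine_series(p, study_design(n_replicates = 1,
                                                    n_fields = 1,
                                                    t_end_h = 24, dt_h = 1,
                                                    seed = 1), "IL1B")
  expect_equal(panel$value[panel$time_h == 0], 0)
  expect_true(all(diff(panel$value) >= 0))
  expect_lte(max(panel$value), 500)
})

test_that("multiplicative concentration noise has the configured CV", {
  p <- trigger_profile("cv", 3, 10, cyt_max_il1b = 1000, cyt_t50_h = 6,
                       cyt_tau_h = 2, conc_cv = 0.1)
  des <- study_design(n_replicates = 500, n_fields = 1,
                      t_end_h = 12, dt_h = 1, seed = 11)
  panel <- simulate_cytokine_series(p, des, "IL1B")
  mid <- panel$value[panel$time_h == 6]  # mid-curve
  expect_gt(sd(mid) / mean(mid), 0.07)
  expect_lt(sd(mid) / mean(mid), 0.13)
})

test_that("LDH triplets round-trip through percent_cytotoxicity", {
  p <- trigger_profile("ldh", 3, 10, ldh_max_frac = 0.6, ldh_t50_h = 4,
                       ldh_tau_h = 1.5, conc_cv = 0)
  des <- study_design(n_replicates = 2, n_fields = 1, t_end_h = 24,
                      dt_h = 1, seed = 2)
  ldh <- simulate_ldh_series(p, des)
  pct <- percent_cytotoxicity(ldh$a_treated, ldh$a_spontaneous,
                              ldh$a_maximum)
  g <- (plogis((ldh$time_h - 4) / 1.5) - plogis(-4 / 1.5)) /
    (1 - plogis(-4 / 1.5))
  expect_equal(pct, 100 * 0.6 * g, tolerance = 1e-10)

  # zero lysis fraction => exactly zero cytotoxicity everywhere
  p0 <- trigger_profile("ldh0", 3, 10, ldh_max_frac = 0, conc_cv = 0)
  ldh0 <- simulate_ldh_series(p0, des)
  expect_true(all(percent_cytotoxicity(ldh0$a_treated, ldh0$a_spontaneous,
                                       ldh0$a_maximum) == 0))

  # full lysis far past t50 approaches 100
  p1 <- trigger_profile("ldh1", 3, 10, ldh_max_frac = 1, ldh_t50_h = 2,
                        ldh_tau_h = 0.5, conc_cv = 0)
  ldh1 <- simulate_ldh_series(p1, des)
  late <- percent_cytotoxicity(ldh1$a_treated, ldh1$a_spontaneous,
                               ldh1$a_maximum)[ldh1$time_h == 24]
  expect_equal(late, rep(100, 2), tolerance = 1e-3)
})

test_that("all simulated values are non-negative and panels are complete", {
  study <- simulate_study(seed = 5, n_replicates = 2, n_fields = 2)
  expect_true(all(study$panel$value >= 0))
  counts <- dplyr::count(study$panel, trigger, readout)
  # same number of cells for every trigger within a readout
  expect_true(all(tapply(counts$n, counts$readout,
                         function(x) length(unique(x))) == 1))
})

test_that("synthetic frames honour their contracts", {
  # blank: no spots, no noise => constant background
  blank <- simulate_speck_image(0, c(32, 32), 1.5, 100, background = 7,
                                noise_sd = 0, seed = 1)
  expect_true(all(blank$frame == 7))
  expect_equal(nrow(blank$truth), 0)

  # determinism: same seed => bit-identical frames
  s1 <- simulate_speck_image(10, c(96, 96), 1.5, 3000, 500, 100, seed = 4)
  s2 <- simulate_speck_image(10, c(96, 96), 1.5, 3000, 500, 100, seed = 4)
  expect_identical(s1$frame, s2$frame)
  expect_identical(s1$truth, s2$truth)

  # spots respect the minimum separation
  d <- as.matrix(dist(cbind(s1$truth$row, s1$truth$col)))
  diag(d) <- Inf
  expect_gte(min(d), 4 * 1.5)

  # impossible packing is refused
  expect_error(simulate_speck_image(500, c(32, 32), 2, 100, 0, 0, seed = 1),
               "separation")
})

test_that("frames survive a TIFF round trip", {
  s <- simulate_speck_image(5, c(48, 48), 1.5, 3000, 500, 100, seed = 6)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame(s$frame, path)
  back <- read_frame(path)
  expect_equal(dim(back), dim(s$frame))
  # 16-bit quantization: intensities agree to within one gray level
  expect_lte(max(abs(back - round(s$frame))), 1)
})
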