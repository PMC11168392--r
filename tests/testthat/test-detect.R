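test_that("fixed threshold above a constant frame gives an empty mask", {
  frame <- matrix(50, 16, 16)
  params <- detection_params(threshold_method = "fixed", fixed_threshold = 100)
  mask <- classify_and_threshold(frame, params)
  expect_false(any(mask))
})

test_that("Otsu on a perfectly bimodal frame recovers the spot support", {
  frame <- matrix(10, 20, 20)
  spots <- cbind(c(5, 5, 6, 12), c(5, 6, 5, 15))
  frame[spots] <- 200
  mask <- classify_and_threshold(frame, detection_params())
  expect_identical(mask & TRUE, frame == 200)
  thr <- attr(mask, "threshold")
  expect_gt(thr, 10)
  expect_lt(thr, 200)
})

test_that("constant frame under Otsu warns and returns an empty mask", {
  frame <- matrix(42, 8, 8)
  expect_warning(mask <- classify_and_threshold(frame, detection_params()),
                 "constant")
  expect_false(any(mask))
  expect_true(is.na(attr(mask, "threshold")))
})

test_that("threshold mask overlaps the true spot support at SNR 10", {
  sim <- simulate_speck_image(20, c(96, 96), 1.5, 3000, 500,
                              noise_sd = 300, seed = 21)
  mask <- classify_and_threshold(sim$frame, detection_params())
  # true support: pixels within 2 sigma of a centroid
  nr <- nrow(sim$frame); nc <- ncol(sim$frame)
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  support <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(sim$truth))) {
    support <- support |
      ((rows - sim$truth$row[i])^2 + (cols - sim$truth$col[i])^2 <= (2 * 1.5)^2)
  }
  jaccard <- sum(mask & support) / sum(mask | support)
  expect_gte(jaccard, 0.5)
})

test_that("component labeling matches EBImage and honours connectivity", {
  # diagonal contact merges under 8-connectivity, splits under 4
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[3, 3] <- TRUE
  expect_equal(max(label_components(m, 8L)), 1L)
  expect_equal(max(label_components(m, 4L)), 2L)

  # random masks: 4-connected labeling agrees with EBImage::bwlabel
  for (seed in 1:5) {
    mask <- withr::with_seed(seed, matrix(runif(400) < 0.3, 20, 20))
    ours <- label_components(mask, 4L)
    ref <- EBImage::bwlabel(mask)
    expect_equal(max(ours), max(ref))
    # same partition: label images agree up to renaming
    expect_equal(length(unique(paste(ours[mask], ref[mask]))), max(ref))
  }
})

test_that("particle measurements follow the area/circularity conventions", {
  # a single pixel: area 1, below the 4-px gate
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  p1 <- measure_particles(m1, detection_params())
  expect_equal(p1$area_px, 1L)
  expect_false(p1$kept)
  expect_gte(p1$circularity, 0)

  # rasterized disc of radius 5: near-circular
  g <- expand.grid(r = -8:8, c = -8:8)
  disc <- matrix(FALSE, 17, 17)
  disc[cbind(g$r + 9, g$c + 9)[g$r^2 + g$c^2 <= 25, ]] <- TRUE
  pd <- measure_particles(disc, detection_params(max_area_px = 200))
  expect_equal(pd$area_px, sum(g$r^2 + g$c^2 <= 25))
  expect_gte(pd$circularity, 0.85)
  expect_lte(pd$circularity, 1.0)
  # perimeter close to the analytic boundary length 2*pi*r
  expect_lt(abs(pd$perimeter_px - 2 * pi * 5) / (2 * pi * 5), 0.15)

  # 1-px-wide line of length 20: elongated, rejected by the gate
  ml <- matrix(FALSE, 5, 30); ml[3, 5:24] <- TRUE
  pl <- measure_particles(ml, detection_params())
  expect_equal(pl$area_px, 20L)
  # out-and-back boundary: P ~ 2 * 20
  expect_equal(pl$perimeter_px, 38, tolerance = 0.15)
  expect_lt(pl$circularity, 0.5)
  expect_false(pl$kept)

  # centroids are 0-based (row, col)
  expect_equal(p1$row, 2)
  expect_equal(p1$col, 2)
})

test_that("count_specks composes the stages and the gates dominate", {
  blank <- matrix(0, 32, 32)
  params <- detection_params(threshold_method = "fixed", fixed_threshold = 10)
  expect_equal(count_specks(blank, params)$count, 0)

  sim <- simulate_speck_image(20, c(96, 96), 1.5, 3000, 500,
                              noise_sd = 0, seed = 8)
  params <- detection_params(threshold_method = "fixed",
                             fixed_threshold = 1500)
  expect_equal(count_specks(sim$frame, params)$count, 20)

  # shrinking max_area below every spot removes all detections
  tight <- detection_params(threshold_method = "fixed",
                            fixed_threshold = 1500, min_area_px = 1,
                            max_area_px = 2)
  expect_equal(count_specks(sim$frame, tight)$count, 0)
})

test_that("widening the particle gates never decreases the count", {
  for (seed in 1:5) {
    sim <- simulate_speck_image(15, c(96, 96), 1.5, 3000, 500,
                                noise_sd = 300, seed = seed)
    narrow <- detection_params(min_area_px = 6, max_area_px = 40,
                               circ_min = 0.7)
    wide <- detection_params(min_area_px = 2, max_area_px = 200,
                             circ_min = 0.1)
    expect_gte(count_specks(sim$frame, wide)$count,
               count_specks(sim$frame, narrow)$count)
  }
})

test_that("detection is a pure function of frame and params", {
  sim <- simulate_speck_image(10, c(64, 64), 1.5, 3000, 500, 300, seed = 13)
  a <- count_specks(sim$frame)
  b <- count_specks(sim$frame)
  expect_identical(a$count, b$count)
  expect_identical(a$particles, b$particles)
})

test_that("detection_params rejects invalid gates and clamps circ_max", {
  expect_error(detection_params(min_area_px = 0), "min_area_px")
  expect_error(detection_params(min_area_px = 50, max_area_px = 10),
               "min_area_px")
  expect_error(detection_params(circ_min = -0.1), "circ_min")
  expect_error(detection_params(connectivity = 6), "connectivity")
  expect_equal(detection_params(circ_max = 1.2)$circ_max, 1.0)
})
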