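test_that("sum projection handles identity, arithmetic and lists", {
  one <- matrix(runif(16), 4)
  expect_equal(sum_project(array(one, dim = c(4, 4, 1))), one)
  expect_equal(sum_project(list(matrix(1, 4, 4), matrix(1, 4, 4))),
               matrix(2, 4, 4))
  expect_error(sum_project(list()), "empty")
})

test_that("extract_profile reproduces constants and painted rows", {
  img <- matrix(7, 10, 20)
  p <- suppressWarnings(extract_profile(img, c(0, 20, 2, 4), 0.28))
  expect_true(all(p$intensities == 7))
  expect_length(p$intensities, 20L)
  img[5, ] <- 1:20
  expect_warning(
    p1 <- extract_profile(img, c(0, 20, 4, 5), 0.28),
    "width"
  )
  expect_equal(p1$intensities, as.numeric(1:20))
  expect_error(extract_profile(img, c(0, 25, 2, 5), 0.28), "bounds")
})

test_that("background subtraction is exact and guarded", {
  p <- intensity_profile(c(5, 5, 5), 1)
  z <- subtract_background(p, 5)
  expect_true(all(z$intensities == 0))
  expect_true(z$background_subtracted)
  ident <- subtract_background(p, 0)
  expect_equal(ident$intensities, p$intensities)
  expect_error(subtract_background(z, 1), "already")
})

test_that("smoothing follows the shrinking-window edge rule", {
  p <- intensity_profile(c(0, 3, 6), 1)
  expect_equal(smooth_profile(p, 3)$intensities, c(1.5, 3, 4.5))
  expect_equal(smooth_profile(p, 1)$intensities, p$intensities)
  expect_error(smooth_profile(p, 2), "odd")
  expect_error(smooth_profile(p, 5), "exceeds")
})

test_that("boundary detection: clamps, degenerate input and guards", {
  const <- intensity_profile(rep(4, 30), 0.5, background_subtracted = TRUE)
  b <- detect_ais_boundaries(const)
  expect_true(b$clamped_start && b$clamped_end)
  expect_identical(b$start_index, 1L)
  expect_identical(b$end_index, 30L)
  expect_equal(b$length_um, 29 * 0.5) # full ROI span
  zero <- intensity_profile(rep(0, 30), 0.5, background_subtracted = TRUE)
  expect_error(detect_ais_boundaries(zero), "no AIS detected")
  raw <- intensity_profile(rep(4, 30), 0.5)
  expect_error(detect_ais_boundaries(raw), "background-subtracted")
})

test_that("Gaussian bump length matches the closed form", {
  sigma <- 8 * 0.28
  b <- detect_ais_boundaries(gaussian_profile(sigma))
  expect_lt(abs(b$length_um - 2 * sigma * sqrt(2 * log(1 / 0.15))), 0.28)
})

test_that("raising the threshold never widens the detected extent", {
  p <- gaussian_profile(2.5, px = 0.28, span_um = 30)
  prev <- detect_ais_boundaries(p, 0.05)
  for (thr in c(0.1, 0.15, 0.25, 0.4, 0.6)) {
    b <- detect_ais_boundaries(p, thr)
    expect_gte(b$start_index, prev$start_index)
    expect_lte(b$end_index, prev$end_index)
    prev <- b
  }
})

test_that("boundaries are scale-equivariant and translation-covariant", {
  p <- gaussian_profile(2, px = 0.28, span_um = 35, center_um = 14)
  b0 <- detect_ais_boundaries(p)
  scaled <- p
  scaled$intensities <- p$intensities * 7.3
  b1 <- detect_ais_boundaries(scaled)
  expect_identical(b1[c("start_index", "end_index", "length_um")],
                   b0[c("start_index", "end_index", "length_um")])
  shift_px <- 10L
  shifted <- p
  shifted$intensities <- c(rep(0, shift_px),
                           p$intensities[1:(length(p$intensities) - shift_px)])
  b2 <- detect_ais_boundaries(shifted)
  expect_identical(b2$start_index, b0$start_index + shift_px)
  expect_identical(b2$end_index, b0$end_index + shift_px)
  expect_equal(b2$length_um, b0$length_um)
})

test_that("integrated sum follows the stated length convention", {
  p <- intensity_profile(rep(10, 50), 0.28, background_subtracted = TRUE)
  expect_equal(integrated_sum(p, 1, 50), 500 / 13.72)
  doubled <- p
  doubled$intensities <- p$intensities * 2
  expect_equal(integrated_sum(doubled, 1, 50), 2 * integrated_sum(p, 1, 50))
  expect_equal(integrated_sum(p, 1, 50, length_unit = "px"), 500 / 49)
  expect_error(integrated_sum(p, 5, 5), "zero-length")
})

test_that("quantify_neuron computes adr by construction and scale-invariantly", {
  cfg <- quiet_cohort_config(background_level = 0)
  rec <- generate_profile(cfg, "control", seed = 4)
  q <- quantify_neuron(rec)
  gt <- rec$ground_truth
  expect_equal(q$adr, gt$adr, tolerance = 1e-12)
  # scaling both compartments by k > 0 leaves adr unchanged
  rec2 <- rec
  rec2$ais_profile$intensities <- rec$ais_profile$intensities * 3
  rec2$dendrite_profile$intensities <- rec$dendrite_profile$intensities * 3
  q2 <- quantify_neuron(rec2)
  expect_equal(q2$adr, q$adr, tolerance = 1e-12)
  expect_equal(q2$ais_integrated_sum, 3 * q$ais_integrated_sum)
  expect_equal(q2$ais_length_um, q$ais_length_um)
})

test_that("noiseless cohort quantification matches generator ground truth", {
  cfg <- cohort_config(n_per_condition = 6, noise_sd = 0, cell_cv = 0.25,
                       length_sd_um = 2, seed = 31,
                       effect = list(length_delta_um = -3, ais_scale = 1.4,
                                     dendrite_scale = 1.1))
  coh <- generate_cohort(cfg)
  for (rec in coh) {
    q <- quantify_neuron(rec)
    expect_lt(abs(q$ais_length_um - rec$ground_truth$length_um),
              cfg$pixel_size_um)
    expect_lt(abs(q$adr - rec$ground_truth$adr), 1e-6)
  }
})

test_that("control normalization yields unit control means", {
  cfg <- cohort_config(n_per_condition = 8, seed = 12,
                       effect = list(length_delta_um = 0, ais_scale = 2,
                                     dendrite_scale = 1))
  q <- quantify_cohort(generate_cohort(cfg))
  nq <- normalize_to_control(q)
  ctrl <- nq$treatment == "control"
  expect_equal(mean(nq$normalized_ais[ctrl]), 1)
  expect_equal(mean(nq$normalized_adr[ctrl]), 1)
  # brute-force groupwise division
  expect_equal(nq$normalized_adr,
               q$adr / mean(q$adr[q$treatment == "control"]))
  # exact 2x treated values normalize to a treated mean of 2
  df <- data.frame(treatment = rep(c("control", "treated"), each = 4),
                   analyte = "a",
                   adr = c(1, 2, 3, 4, 2, 4, 6, 8))
  out <- normalize_to_control(df, value_cols = "adr")
  expect_equal(mean(out$normalized_adr[out$treatment == "treated"]), 2)
  expect_error(normalize_to_control(df, control_label = "DMSO"), "control")
})

test_that("log transform guards non-positive values by record", {
  expect_equal(log_transform(c(1, exp(1))), c(0, 1))
  x <- runif(20) + 0.1
  expect_equal(log_transform(x), log(x))
  expect_error(log_transform(c(1, 0, 3), ids = c("a", "b", "c")), "b")
})
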