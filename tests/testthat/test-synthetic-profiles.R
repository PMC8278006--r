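test_that("noiseless construction hits the designed peak exactly", {
  cfg <- quiet_cohort_config()
  rec <- generate_profile(cfg, "control", seed = 5)
  vals <- rec$ais_profile$intensities
  expect_identical(max(vals), cfg$background_level + cfg$ais_peak_amp)
  peak_pos <- rec$ais_profile$positions[which.max(vals)]
  expect_lt(abs(peak_pos - rec$ground_truth$peak_um), cfg$pixel_size_um)
  # dendrite is flat at background + dendrite level
  expect_true(all(rec$dendrite_profile$intensities ==
                    cfg$background_level + cfg$dendrite_level))
})

test_that("treated intensity scaling is exact in the noiseless limit", {
  cfg <- quiet_cohort_config(effect = list(ais_scale = 2, dendrite_scale = 3,
                                           length_delta_um = 0))
  ctrl <- generate_profile(cfg, "control", seed = 9)
  trt <- generate_profile(cfg, "treated", seed = 9)
  bg <- cfg$background_level
  expect_equal(max(trt$ais_profile$intensities) - bg,
               2 * (max(ctrl$ais_profile$intensities) - bg))
  expect_equal(trt$dendrite_profile$intensities[1] - bg,
               3 * (ctrl$dendrite_profile$intensities[1] - bg))
})

test_that("profile generation is deterministic for a fixed seed", {
  cfg <- cohort_config(n_per_condition = 3, seed = 77) # default noise/cv on
  a <- generate_profile(cfg, "treated", seed = 123)
  b <- generate_profile(cfg, "treated", seed = 123)
  expect_identical(a, b)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1, coh2)
})

test_that("cohorts have the requested size and labels", {
  cfg <- cohort_config(n_per_condition = 40, seed = 1)
  coh <- generate_cohort(cfg)
  labs <- vapply(coh, function(r) r$treatment, character(1))
  expect_length(coh, 80L)
  expect_equal(unname(table(labs)[c("control", "treated")]),
               c(40L, 40L), ignore_attr = TRUE)
})

test_that("per-record streams are stable under cohort enlargement", {
  small <- generate_cohort(cohort_config(n_per_condition = 3, seed = 5))
  large <- generate_cohort(cohort_config(n_per_condition = 6, seed = 5))
  ids <- vapply(small, function(r) r$neuron_id, character(1))
  for (id in ids) {
    i <- which(vapply(large, function(r) r$neuron_id, character(1)) == id)
    expect_identical(small[[which(ids == id)]], large[[i]])
  }
})

test_that("identity-effect conditions are exchangeable in distribution", {
  # With no treatment effect, the standardized difference of per-condition
  # mean adr should exceed 3 SEs only rarely over repeated cohorts.
  z <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_per_condition = 15, seed = s,
                         effect = list(length_delta_um = 0, ais_scale = 1,
                                       dendrite_scale = 1))
    q <- quantify_cohort(generate_cohort(cfg))
    a <- q$adr[q$treatment == "control"]
    b <- q$adr[q$treatment == "treated"]
    abs(mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }, numeric(1))
  expect_gte(mean(z < 3), 0.95)
})

test_that("ground truth is internally consistent at zero noise", {
  cfg <- quiet_cohort_config(n_per_condition = 3)
  coh <- generate_cohort(cfg)
  for (rec in coh) {
    gt <- rec$ground_truth
    expect_equal(gt$end_um - gt$start_um, gt$length_um, tolerance = 1e-8)
    expect_equal(gt$adr,
                 gt$ais_integrated_sum / gt$dendrite_integrated_sum)
  }
})

test_that("rendered images round-trip the painted profile", {
  cfg <- quiet_cohort_config()
  rec <- generate_profile(cfg, "control", seed = 2)
  img <- render_image(rec, width_px = 3L)
  roi <- img$rois$neurite
  prof <- extract_profile(img$image, roi, img$pixel_size_um)
  expect_identical(prof$intensities, rec$ais_profile$intensities)
  bg <- img$rois$background
  bg_mean <- mean(img$image[(bg["y0"] + 1):bg["y1"], (bg["x0"] + 1):bg["x1"]])
  expect_equal(bg_mean, cfg$background_level)
  expect_error(render_image(rec, width_px = 2L), ">= 3")
})

test_that("image round trip recovers ground-truth length at high SNR", {
  skip_if_not_installed("EBImage")
  cfg <- quiet_cohort_config()
  rec <- generate_profile(cfg, "control", seed = 3)
  img <- render_image(rec, width_px = 4L, psf_sd_px = 0.6, noise_sd = 0.5,
                      seed = 8)
  bg <- img$rois$background
  bg_mean <- mean(img$image[(bg["y0"] + 1):bg["y1"], (bg["x0"] + 1):bg["x1"]])
  prof <- extract_profile(img$image, img$rois$neurite, img$pixel_size_um)
  b <- detect_ais_boundaries(subtract_background(prof, bg_mean))
  expect_lt(abs(b$length_um - rec$ground_truth$length_um),
            2 * cfg$pixel_size_um)
})

test_that("bump model calibration places the 15% crossings as designed", {
  for (L in c(8, 14, 20, 26)) {
    bm <- ais_bump_model(L, start_um = 2)
    expect_equal(bm$end_um - bm$start_um, L, tolerance = 1e-6)
    expect_equal(bm$f(bm$peak_um), 1, tolerance = 1e-6)
    expect_equal(bm$f(bm$start_um), 0.15, tolerance = 1e-6)
    expect_equal(bm$f(bm$end_um), 0.15, tolerance = 1e-6)
  }
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_per_condition = 1), ">= 2")
  expect_error(cohort_config(profile_span_um = 20), ">= 25")
  expect_error(cohort_config(noise_sd = -1), ">= 0")
  expect_error(cohort_config(effect = list(ais_scale = 0)), "> 0")
  expect_error(cohort_config(pixel_size_um = 0), "> 0")
})
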