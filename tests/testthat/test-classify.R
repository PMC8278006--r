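test_that("denoising crops to 25 um and shares the smoothing kernel", {
  px <- 0.28
  p <- intensity_profile(rep(3, 120), px)
  d <- denoise_profile(p)
  expect_length(d$intensities, floor(25 / px) + 1L) # 90 samples at 0.28
  expect_true(all(d$intensities == 3))
  r <- intensity_profile(rnorm(120), px)
  cropped <- intensity_profile(r$intensities[1:(floor(25 / px) + 1L)], px)
  expect_equal(denoise_profile(r)$intensities,
               smooth_profile(cropped, 3)$intensities)
  short <- intensity_profile(rnorm(50), px)
  expect_error(denoise_profile(short), "excluded")
})

test_that("feature vectors have 5 entries matching first-principles formulas", {
  p <- intensity_profile(as.numeric(1:9), 0.28)
  fv <- compute_features(p, adr = 2.5)
  expect_length(fv, 5L)
  expect_named(fv, c("iqr", "kurtosis", "skewness", "rms", "adr"))
  expect_equal(fv[["skewness"]], 0) # symmetric profile
  expect_equal(fv[["rms"]], sqrt(sum((1:9)^2) / 9))
  o <- oracle_features(as.numeric(1:9))
  expect_equal(fv[c("iqr", "kurtosis", "skewness", "rms")], o)
  expect_equal(fv[["adr"]], 2.5)
  flat <- intensity_profile(rep(1, 10), 0.28)
  expect_error(compute_features(flat, 1), "zero-variance")
  expect_error(compute_features(p, Inf), "finite")
})

test_that("70/30 splits reproduce the printed sizes and partition the cohort", {
  for (case in list(c(80, 56, 24), c(68, 47, 21), c(72, 50, 22),
                    c(10, 7, 3))) {
    s <- split_cohort(case[1], seed = 99)
    expect_length(s$train, case[2])
    expect_length(s$test, case[3])
    expect_setequal(c(s$train, s$test), seq_len(case[1]))
    expect_length(intersect(s$train, s$test), 0L)
  }
  # partition property over seeds
  for (seed in 1:25) {
    s <- split_cohort(37, seed = seed)
    expect_length(s$train, 25L)
    expect_setequal(c(s$train, s$test), 1:37)
  }
  expect_error(split_cohort(3), ">= 4")
})

test_that("accuracy implements the confusion-count formula", {
  expect_equal(accuracy(8, 7, 3, 2), 0.75)
  expect_equal(accuracy(0, 12, 0, 0), 1)
  expect_error(accuracy(0, 0, 0, 0), "> 0")
  set.seed(1)
  for (i in 1:10) {
    truth <- sample(c("a", "b"), 30, replace = TRUE)
    pred <- sample(c("a", "b"), 30, replace = TRUE)
    cf <- oracle_confusion(truth, pred, "b")
    expect_equal(accuracy(cf["tp"], cf["tn"], cf["fp"], cf["fn"]),
                 mean(truth == pred))
  }
})

test_that("a perfectly separated feature classifies at 100%", {
  n <- 40
  feats <- data.frame(iqr = rep(1, n), kurtosis = rep(0, n),
                      skewness = rep(0, n), rms = rep(1, n),
                      adr = rep(c(1, 10), each = n / 2))
  labels <- rep(c("control", "treated"), each = n / 2)
  res <- suppressWarnings(
    run_repeated_classification(feats, labels, n_repeats = 20, seed = 3)
  )
  expect_equal(res$mean_accuracy, 1)
  expect_equal(res$train_size, 28L)
  expect_equal(res$test_size, 12L)
})

test_that("repeated classification is deterministic and self-consistent", {
  set.seed(10)
  feats <- matrix(rnorm(60 * 5), 60, 5,
                  dimnames = list(NULL, c("iqr", "kurtosis", "skewness",
                                          "rms", "adr")))
  labels <- rep(c("control", "treated"), 30)
  a <- run_repeated_classification(feats, labels, n_repeats = 15, seed = 8)
  b <- run_repeated_classification(feats, labels, n_repeats = 15, seed = 8)
  expect_identical(a$per_repeat_accuracy, b$per_repeat_accuracy)
  expect_equal(a$mean_accuracy, mean(a$per_repeat_accuracy))
  expect_equal(a$sd_accuracy, sd(a$per_repeat_accuracy))
  tot <- sum(a$confusion_totals)
  expect_equal(tot, a$test_size * a$n_repeats)
  expect_equal((a$confusion_totals[["tp"]] + a$confusion_totals[["tn"]]) / tot,
               a$mean_accuracy)
  expect_error(run_repeated_classification(feats, rep("x", 60)), "two classes")
})

test_that("accuracy is symmetric under class relabeling and row permutation", {
  set.seed(4)
  feats <- matrix(rnorm(50 * 5), 50, 5)
  labels <- rep(c("control", "treated"), 25)
  a <- run_repeated_classification(feats, labels, n_repeats = 10, seed = 21)
  # swapping the class names swaps tp<->tn and fp<->fn but not accuracy
  swapped <- ifelse(labels == "control", "treated", "control")
  b <- run_repeated_classification(feats, swapped, n_repeats = 10, seed = 21)
  expect_identical(a$per_repeat_accuracy, b$per_repeat_accuracy)
  expect_equal(a$confusion_totals[c("tp", "tn", "fp", "fn")],
               b$confusion_totals[c("tn", "tp", "fn", "fp")],
               ignore_attr = TRUE)
  # permuting (feature, label) pairs jointly leaves the accuracy
  # distribution unchanged; compare means over the same repeat seeds
  perm <- sample(50)
  c_ <- run_repeated_classification(feats[perm, ], labels[perm],
                                    n_repeats = 40, seed = 21)
  d_ <- run_repeated_classification(feats, labels, n_repeats = 40, seed = 21)
  expect_lt(abs(c_$mean_accuracy - d_$mean_accuracy), 0.15)
})

test_that("degenerate feature columns fall back to unit scale with warning", {
  feats <- data.frame(iqr = rep(1, 20), kurtosis = rnorm(20),
                      skewness = rnorm(20), rms = rnorm(20),
                      adr = rnorm(20))
  labels <- rep(c("control", "treated"), 10)
  expect_warning(
    run_repeated_classification(feats, labels, n_repeats = 1, seed = 1),
    "zero-variance"
  )
})

test_that("feature_table emits one labeled 5-feature row per neuron", {
  cfg <- cohort_config(n_per_condition = 5, seed = 2)
  coh <- generate_cohort(cfg)
  ft <- feature_table(coh)
  expect_equal(nrow(ft), 10L)
  expect_named(ft, c("neuron_id", "label", "iqr", "kurtosis", "skewness",
                     "rms", "adr"))
  expect_true(all(is.finite(as.matrix(ft[, 3:7]))))
  # normalized-adr option rescales the adr column only
  ftn <- feature_table(coh, normalized_adr = TRUE)
  ctrl_mean <- mean(ft$adr[ft$label == "control"])
  expect_equal(ftn$adr, ft$adr / ctrl_mean)
  expect_equal(ftn$rms, ft$rms)
})
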