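#' Denoise and crop a profile for feature extraction
#'
#' Crops the AIS profile to its first 25 um (controlling for length
#' differences between neurons) and applies a size-3 moving-average low-pass
#' filter (shrinking windows at the edges, so the cropped length is
#' preserved). Profiles shorter than 25 um cannot be cropped and raise an
#' error so the neuron is excluded explicitly.
#'
#' @param profile an [intensity_profile()].
#' @param crop_um crop extent from the proximal end, um (default 25).
#' @param window moving-average window (default 3).
#' @return the cropped, denoised profile.
#' @export
denoise_profile <- function(profile, crop_um = 25, window = 3L) {
  assert_profile(profile)
  stopifnot_scalar(crop_um, "crop_um", positive = TRUE)
  if (max(profile$positions) < crop_um - 1e-9) {
    stop(sprintf(
      "profile spans %.2f um (< %g um); neuron must be excluded",
      max(profile$positions), crop_um
    ), call. = FALSE)
  }
  keep <- profile$positions <= crop_um + 1e-9
  profile$positions <- profile$positions[keep]
  profile$intensities <- profile$intensities[keep]
  smooth_profile(profile, window)
}

#' Compute the 5-entry per-neuron feature vector
#'
#' Statistical features of the denoised first-25-um intensity profile —
#' interquartile range, Fisher excess kurtosis, moment-coefficient skewness
#' and root mean square — concatenated with the neuron's axo:dendritic
#' ratio. Quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7); moments are uncorrected central moments
#' (skewness m3/m2^1.5, kurtosis m4/m2^2 - 3).
#'
#' @param denoised a denoised [intensity_profile()] (see
#'   [denoise_profile()]), length >= 4.
#' @param adr finite axo:dendritic ratio.
#' @return a named numeric vector `c(iqr, kurtosis, skewness, rms, adr)`.
#' @export
#' @examples
#' p <- intensity_profile(as.numeric(1:9), pixel_size_um = 0.28)
#' compute_features(p, adr = 2)
compute_features <- function(denoised, adr) {
  assert_profile(denoised)
  x <- denoised$intensities
  if (length(x) < 4L) stop("profile must have >= 4 samples", call. = FALSE)
  if (!is.numeric(adr) || length(adr) != 1L || !is.finite(adr)) {
    stop("`adr` must be a single finite number", call. = FALSE)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) {
    stop("zero-variance profile: skewness and kurtosis are undefined",
         call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(iqr = q[2] - q[1],
    kurtosis = mean((x - m)^4) / m2^2 - 3,
    skewness = mean((x - m)^3) / m2^1.5,
    rms = sqrt(mean(x^2)),
    adr = adr)
}

#' Build the per-neuron feature table for a cohort
#'
#' Runs [quantify_neuron()] (for the adr) and [denoise_profile()] +
#' [compute_features()] on every record of a cohort.
#'
#' @param cohort a `neuron_cohort` or list of [neuron_record()]s.
#' @param threshold_fraction boundary threshold passed to the quantification.
#' @param normalized_adr if `TRUE`, the adr entering the feature vector is
#'   normalized to the control-group mean first (default uses the raw adr).
#' @param control_label control label used when `normalized_adr = TRUE`.
#' @return a data.frame with `neuron_id`, `label` (treatment) and the 5
#'   feature columns `iqr`, `kurtosis`, `skewness`, `rms`, `adr`.
#' @export
feature_table <- function(cohort, threshold_fraction = 0.15,
                          normalized_adr = FALSE,
                          control_label = "control") {
  quant <- quantify_cohort(cohort, threshold_fraction = threshold_fraction)
  adr <- quant$adr
  if (normalized_adr) {
    quant <- normalize_to_control(quant, control_label,
                                  value_cols = "adr")
    adr <- quant$normalized_adr
  }
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    prof <- subtract_background(rec$ais_profile, rec$background_mean)
    fv <- compute_features(denoise_profile(prof), adr[i])
    rows[[i]] <- data.frame(
      neuron_id = rec$neuron_id, label = rec$treatment,
      iqr = fv[["iqr"]], kurtosis = fv[["kurtosis"]],
      skewness = fv[["skewness"]], rms = fv[["rms"]], adr = fv[["adr"]],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Random 70/30 train/test split
#'
#' Uniform, unstratified split: the training set is `floor(train_fraction *
#' n)` indices sampled without replacement; the remainder is the test set.
#' This floor convention reproduces the printed split sizes 56/24, 47/21 and
#' 50/22 for cohorts of 80, 68 and 72 neurons.
#'
#' @param n cohort size (>= 4).
#' @param train_fraction training fraction (default 0.7).
#' @param seed optional seed; when `NULL`, uses the current RNG state.
#' @return a list with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(n, train_fraction = 0.7, seed = NULL) {
  stopifnot_scalar(n, "n", positive = TRUE, integerish = TRUE)
  if (n < 4) stop("`n` must be >= 4", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  do_split <- function() {
    n_train <- floor(train_fraction * n)
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  }
  if (is.null(seed)) do_split() else with_seed(seed, do_split())
}

#' Classification accuracy from confusion counts
#'
#' Combined true positives and true negatives divided by the total number of
#' classifications.
#'
#' @param tp,tn,fp,fn non-negative confusion counts; their total must be > 0.
#' @return accuracy fraction in `[0, 1]`.
#' @export
#' @examples
#' accuracy(8, 7, 3, 2) # 0.75
accuracy <- function(tp, tn, fp, fn) {
  for (v in list(tp = tp, tn = tn, fp = fp, fn = fn)) {
    stopifnot_scalar(v, "count", nonneg = TRUE)
  }
  total <- tp + tn + fp + fn
  if (total <= 0) stop("total classification count must be > 0", call. = FALSE)
  unname((tp + tn) / total)
}

# z-score columns by training statistics; zero-variance columns fall back to
# unit scale with a warning.
standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  degenerate <- !is.finite(sd) | sd <= 0
  if (any(degenerate)) {
    warning(sprintf(
      "zero-variance feature column(s) %s: unit-scale fallback",
      paste(colnames(train)[degenerate], collapse = ", ")
    ), call. = FALSE)
    sd[degenerate] <- 1
  }
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

#' Repeated 70/30 support-vector-machine classification
#'
#' Repeats `n_repeats` times: draw a random 70/30 split, standardize the
#' features by the training-set mean and SD (no test leakage), fit a
#' support-vector classifier, predict the held-out test labels and record
#' the accuracy. Reports the per-repeat accuracies, their mean and SD, and
#' confusion totals summed over repeats. Repeat `i` uses a child seed
#' derived from `seed` by counter-based splitting, so it is reproducible in
#' isolation.
#'
#' @param features numeric matrix or data.frame of feature columns (rows =
#'   neurons).
#' @param labels two-level factor (or coercible) of treatment labels; the
#'   second level is treated as the positive class.
#' @param n_repeats number of repeated splits (default 100).
#' @param seed experiment seed.
#' @param train_fraction training fraction (default 0.7).
#' @param kernel,cost SVM kernel and soft-margin penalty passed to
#'   [e1071::svm]; the kernel coefficient is `1 / n_features` on the
#'   standardized features.
#' @param stratified if `TRUE`, splits are drawn per class (off by default;
#'   the printed split sizes arise from plain unstratified floor splits).
#' @return an object of class `classification_result`: a list with
#'   `per_repeat_accuracy`, `mean_accuracy`, `sd_accuracy`, `n_repeats`,
#'   `train_size`, `test_size`, `confusion_totals` (tp/tn/fp/fn), `levels`
#'   and `seed`.
#' @export
run_repeated_classification <- function(features, labels, n_repeats = 100L,
                                        seed = 1L, train_fraction = 0.7,
                                        kernel = "radial", cost = 1,
                                        stratified = FALSE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- factor(labels)
  if (nlevels(labels) != 2L) {
    stop("`labels` must have exactly two classes", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("need >= 2 records per class", call. = FALSE)
  }
  n <- nrow(features)
  if (length(labels) != n) {
    stop("`features` and `labels` must have the same length", call. = FALSE)
  }
  stopifnot_scalar(n_repeats, "n_repeats", positive = TRUE, integerish = TRUE)
  pos <- levels(labels)[2]
  n_train <- floor(train_fraction * n)

  acc <- numeric(n_repeats)
  conf <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (r in seq_len(n_repeats)) {
    rep_seed <- child_seed(seed, r, stream = 101L)
    split <- with_seed(rep_seed, {
      if (stratified) {
        idx <- lapply(levels(labels), function(lv) {
          i <- which(labels == lv)
          s <- sort(sample(i, floor(train_fraction * length(i))))
          list(train = s, test = setdiff(i, s))
        })
        list(train = sort(c(idx[[1]]$train, idx[[2]]$train)),
             test = sort(c(idx[[1]]$test, idx[[2]]$test)))
      } else {
        split_cohort(n, train_fraction)
      }
    })
    if (length(unique(labels[split$train])) < 2L) {
      # Degenerate single-class draw: chance-level repeat, flagged.
      warning("training split contains a single class; repeat scored 0.5",
              call. = FALSE)
      acc[r] <- 0.5
      next
    }
    z <- standardize_train_test(features[split$train, , drop = FALSE],
                                features[split$test, , drop = FALSE])
    fit <- e1071::svm(x = z$train, y = labels[split$train], kernel = kernel,
                      cost = cost, gamma = 1 / ncol(features), scale = FALSE)
    pred <- stats::predict(fit, z$test)
    truth <- labels[split$test]
    tp <- sum(pred == pos & truth == pos)
    tn <- sum(pred != pos & truth != pos)
    fp <- sum(pred == pos & truth != pos)
    fn <- sum(pred != pos & truth == pos)
    conf <- conf + c(tp = tp, tn = tn, fp = fp, fn = fn)
    acc[r] <- accuracy(tp, tn, fp, fn)
  }
  structure(
    list(per_repeat_accuracy = acc,
         mean_accuracy = mean(acc),
         sd_accuracy = stats::sd(acc),
         n_repeats = as.integer(n_repeats),
         train_size = as.integer(n_train),
         test_size = as.integer(n - n_train),
         confusion_totals = conf,
         levels = levels(labels),
         positive = pos,
         seed = as.integer(seed)),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %d repeats of %d/%d splits: accuracy %.1f%% +/- %.1f%% (mean +/- SD)\n",
    x$n_repeats, x$train_size, x$test_size,
    100 * x$mean_accuracy, 100 * x$sd_accuracy
  ))
  invisible(x)
}
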