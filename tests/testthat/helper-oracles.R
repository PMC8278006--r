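# Brute-force oracle implementations, written independently of the package
# internals (plain loops and first-principles formulas) so they can serve as
# the second route in equivalence tests.

oracle_moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    s <- 0
    for (j in lo:hi) s <- s + x[j]
    out[i] <- s / (hi - lo + 1L)
  }
  out
}

oracle_integrated_sum <- function(x, start, end, px) {
  s <- 0
  for (i in start:end) s <- s + x[i]
  s / ((end - start) * px)
}

# Linear-interpolation quantile (the type-7 convention) from first
# principles: h = (n - 1) p, interpolate between floor and ceiling order
# statistics.
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(x))] - xs[lo + 1])
}

oracle_features <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  c(iqr = oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25),
    kurtosis = m4 / m2^2 - 3,
    skewness = m3 / m2^1.5,
    rms = sqrt(sum(x^2) / n))
}

oracle_confusion <- function(truth, pred, positive) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (pred[i] == positive && truth[i] == positive) tp <- tp + 1L
    else if (pred[i] != positive && truth[i] != positive) tn <- tn + 1L
    else if (pred[i] == positive) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_sum_project <- function(stack) {
  d <- dim(stack)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      s <- 0
      for (k in seq_len(d[3])) s <- s + stack[i, j, k]
      out[i, j] <- s
    }
  }
  out
}

# A noiseless Gaussian bump profile (already background-subtracted).
gaussian_profile <- function(sigma_um, px = 0.28, span_um = 40, amp = 100,
                             center_um = span_um / 2) {
  x <- seq(0, span_um, by = px)
  intensity_profile(amp * exp(-(x - center_um)^2 / (2 * sigma_um^2)), px,
                    background_subtracted = TRUE)
}

# Small deterministic cohort configs used across test files.
quiet_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(n_per_condition = 4, noise_sd = 0, cell_cv = 0, length_sd_um = 0,
         seed = 42),
    list(...)
  )
  do.call(cohort_config, args)
}
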