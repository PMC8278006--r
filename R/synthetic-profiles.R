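#' Configuration for a two-condition synthetic imaging cohort
#'
#' Defines the ground-truth parameters of a simulated cohort of neurons
#' stained for one AIS analyte: a control condition and a "treated" condition
#' whose AIS length, AIS peak intensity and dendritic intensity are perturbed
#' by `effect`. The AIS profile is a smooth single-peak bump (difference of
#' two logistic sigmoids with a multiplicative linear taper, see
#' [ais_bump_model()]) riding on a constant image background; the dendrite is
#' a flat 15-um segment. `ais_length_um` is the true extent between the two
#' points where the noiseless bump falls to 15% of its peak.
#'
#' Between-cell biological variability is controlled by `cell_cv` (lognormal
#' coefficient of variation of the per-cell AIS peak amplitude and dendrite
#' level, unit mean) and `length_sd_um` (Gaussian jitter of the per-cell true
#' AIS length). Set both to 0 for fully deterministic noiseless cohorts.
#'
#' @param n_per_condition neurons per condition (>= 2).
#' @param ais_length_um true 15%-crossing-to-crossing AIS extent, um.
#' @param ais_peak_amp AIS peak amplitude above background, a.u.
#' @param dendrite_level dendritic intensity above background, a.u.
#' @param background_level constant image background, a.u.
#' @param noise_sd additive Gaussian pixel noise, a.u.
#' @param pixel_size_um physical pixel size, um (0.28 matches a 63x confocal
#'   configuration).
#' @param profile_span_um traced AIS ROI length, um; must be >= 25 and >=
#'   `ais_length_um + ais_start_um`.
#' @param effect list with `length_delta_um`, `ais_scale`, `dendrite_scale`
#'   applied to the treated condition.
#' @param cell_cv lognormal CV of per-cell intensity levels (>= 0).
#' @param length_sd_um per-cell SD of true AIS length, um (>= 0).
#' @param ais_start_um position of the proximal 15% crossing, um from the ROI
#'   origin.
#' @param seed integer seed; per-record child seeds are derived from it by
#'   counter-based splitting so records are reproducible in isolation.
#'
#' @return an object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_condition = 5, noise_sd = 0, cell_cv = 0,
#'                      length_sd_um = 0)
#' rec <- generate_profile(cfg, "control")
#' rec$ground_truth$length_um
cohort_config <- function(n_per_condition = 40,
                          ais_length_um = 20,
                          ais_peak_amp = 100,
                          dendrite_level = 20,
                          background_level = 10,
                          noise_sd = 8,
                          pixel_size_um = 0.28,
                          profile_span_um = 30,
                          effect = list(length_delta_um = 0, ais_scale = 1,
                                        dendrite_scale = 1),
                          cell_cv = 0.25,
                          length_sd_um = 2,
                          ais_start_um = 2,
                          seed = 1L) {
  stopifnot_scalar(n_per_condition, "n_per_condition", positive = TRUE,
                   integerish = TRUE)
  if (n_per_condition < 2) stop("`n_per_condition` must be >= 2", call. = FALSE)
  stopifnot_scalar(ais_length_um, "ais_length_um", positive = TRUE)
  stopifnot_scalar(ais_peak_amp, "ais_peak_amp", positive = TRUE)
  stopifnot_scalar(dendrite_level, "dendrite_level", positive = TRUE)
  stopifnot_scalar(background_level, "background_level", nonneg = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar(profile_span_um, "profile_span_um", positive = TRUE)
  stopifnot_scalar(cell_cv, "cell_cv", nonneg = TRUE)
  stopifnot_scalar(length_sd_um, "length_sd_um", nonneg = TRUE)
  stopifnot_scalar(ais_start_um, "ais_start_um", nonneg = TRUE)
  stopifnot_scalar(seed, "seed", integerish = TRUE)
  effect <- utils::modifyList(
    list(length_delta_um = 0, ais_scale = 1, dendrite_scale = 1), effect
  )
  if (effect$ais_scale <= 0 || effect$dendrite_scale <= 0) {
    stop("effect scales must be > 0", call. = FALSE)
  }
  if (profile_span_um < 25) {
    stop("`profile_span_um` must be >= 25 (the classifier crops to 25 um)",
         call. = FALSE)
  }
  if (profile_span_um < ais_length_um + ais_start_um) {
    stop("`profile_span_um` must cover `ais_start_um + ais_length_um`",
         call. = FALSE)
  }
  structure(
    list(n_per_condition = as.integer(n_per_condition),
         ais_length_um = ais_length_um, ais_peak_amp = ais_peak_amp,
         dendrite_level = dendrite_level, background_level = background_level,
         noise_sd = noise_sd, pixel_size_um = pixel_size_um,
         profile_span_um = profile_span_um, effect = effect,
         cell_cv = cell_cv, length_sd_um = length_sd_um,
         ais_start_um = ais_start_um, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Continuous AIS intensity bump model
#'
#' The AIS profile is modeled as a plateau formed by the difference of two
#' logistic sigmoids, multiplied by a linear taper that declines toward the
#' distal end so the profile has a single dominant maximum in the proximal
#' half — qualitatively matching observed AIS immunofluorescence profiles,
#' which rise from the soma to one peak and decay distally. The plateau width
#' is calibrated (by root finding) so that the two 15%-of-peak crossings of
#' the normalized bump are exactly `length_um` apart, with the proximal
#' crossing at `start_um`.
#'
#' @param length_um target 15% crossing-to-crossing extent, um.
#' @param start_um position of the proximal crossing, um.
#' @param threshold_fraction fraction of the peak defining the extent.
#' @param edge_width_frac logistic slope scale as a fraction of `length_um`.
#' @param taper_frac total fractional decline of the linear taper across the
#'   plateau (0 gives a symmetric plateau).
#' @return a list with `f`, a vectorized function of position (um) returning
#'   the unit-peak bump; `peak_um`, the position of the maximum; and
#'   `start_um`/`end_um`, the threshold crossings.
#' @export
ais_bump_model <- function(length_um, start_um = 2, threshold_fraction = 0.15,
                           edge_width_frac = 1 / 12, taper_frac = 0.35) {
  stopifnot_scalar(length_um, "length_um", positive = TRUE)
  w <- edge_width_frac * length_um

  shape <- function(x, d) {
    raw <- stats::plogis((x - 0) / w) - stats::plogis((x - d) / w)
    tap <- pmax(1 - taper_frac * x / d, 0.05)
    raw * tap
  }
  crossings <- function(d) {
    pk <- stats::optimize(function(x) shape(x, d), c(-4 * w, d + 4 * w),
                          maximum = TRUE, tol = 1e-10)
    g <- function(x) shape(x, d) / pk$objective - threshold_fraction
    lo <- stats::uniroot(g, c(-30 * w, pk$maximum), tol = 1e-10)$root
    hi <- stats::uniroot(g, c(pk$maximum, d + 30 * w), tol = 1e-10)$root
    list(lo = lo, hi = hi, peak = pk$maximum, peak_value = pk$objective)
  }
  # Plateau width d is monotone in the crossing extent; solve for the target.
  d <- stats::uniroot(function(d) {
    cr <- crossings(d)
    (cr$hi - cr$lo) - length_um
  }, c(1e-3 * length_um, 2 * length_um), tol = 1e-9)$root
  cr <- crossings(d)
  shift <- start_um - cr$lo
  pv <- cr$peak_value
  list(
    f = function(x) shape(x - shift, d) / pv,
    peak_um = cr$peak + shift,
    start_um = start_um,
    end_um = cr$hi + shift
  )
}

# Brute-force (plain loop) reference quantification used to stamp ground
# truth on synthetic records: 3-point shrinking-window smoothing, first-max
# peak, outward walk to the last sample at or above 15% of the smoothed peak,
# unsmoothed sums divided by segment length in um. Written independently of
# the production path in quantify.R so the two can cross-check each other.
reference_quant <- function(ais_bg_sub, dend_bg_sub, pixel_size_um,
                            threshold_fraction = 0.15) {
  n <- length(ais_bg_sub)
  sm <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L)
    hi <- min(n, i + 1L)
    s <- 0
    for (j in lo:hi) s <- s + ais_bg_sub[j]
    sm[i] <- s / (hi - lo + 1L)
  }
  pk <- 1L
  for (i in seq_len(n)) if (sm[i] > sm[pk]) pk <- i
  if (sm[pk] <= 0) return(NULL)
  thr <- threshold_fraction * sm[pk]
  st <- pk
  while (st > 1L && sm[st - 1L] >= thr) st <- st - 1L
  en <- pk
  while (en < n && sm[en + 1L] >= thr) en <- en + 1L
  if (en == st) return(NULL)
  # Midpoint boundary convention: unclamped boundaries sit half a pixel
  # beyond the last included sample (mirrors detect_ais_boundaries).
  len_px <- (en - st) + (if (st > 1L) 0.5 else 0) + (if (en < n) 0.5 else 0)
  s <- 0
  for (i in st:en) s <- s + ais_bg_sub[i]
  ais_sum <- s / ((en - st) * pixel_size_um)
  m <- length(dend_bg_sub)
  s <- 0
  for (i in seq_len(m)) s <- s + dend_bg_sub[i]
  dend_sum <- s / ((m - 1L) * pixel_size_um)
  list(length_um = len_px * pixel_size_um,
       ais_integrated_sum = ais_sum,
       dendrite_integrated_sum = dend_sum,
       adr = if (dend_sum > 0) ais_sum / dend_sum else NA_real_)
}

#' Generate one synthetic neuron record
#'
#' Draws one neuron of the given condition: per-cell amplitude/level factors
#' (unit-mean lognormal with CV `cfg$cell_cv`), per-cell true AIS length
#' (Gaussian jitter `cfg$length_sd_um`), the calibrated bump sampled on the
#' pixel grid, a flat 15-um dendrite segment, and additive Gaussian pixel
#' noise. The treated condition applies `cfg$effect` (length shift and
#' intensity scalings). Ground truth (true length, peak position, per-cell
#' amplitude and dendrite level, and reference quantification of the
#' noiseless profile) is stored on the record.
#'
#' @param cfg a [cohort_config()].
#' @param condition `"control"` or `"treated"`.
#' @param seed integer seed for this record (defaults to `cfg$seed`).
#' @param neuron_id identifier stamped on the record.
#' @return a [neuron_record()] with `ground_truth`.
#' @export
generate_profile <- function(cfg, condition = c("control", "treated"),
                             seed = cfg$seed, neuron_id = "synthetic") {
  stopifnot(inherits(cfg, "cohort_config"))
  condition <- match.arg(condition)
  treated <- condition == "treated"
  px <- cfg$pixel_size_um

  with_seed(seed, {
    sln <- sqrt(log(1 + cfg$cell_cv^2))
    amp_factor <- if (cfg$cell_cv > 0) {
      exp(stats::rnorm(1, -sln^2 / 2, sln))
    } else 1
    len_base <- cfg$ais_length_um +
      (if (treated) cfg$effect$length_delta_um else 0)
    len <- len_base + (if (cfg$length_sd_um > 0) {
      stats::rnorm(1, 0, cfg$length_sd_um)
    } else 0)
    len <- min(max(len, 5), cfg$profile_span_um - cfg$ais_start_um - 1)
    dend_factor <- if (cfg$cell_cv > 0) {
      exp(stats::rnorm(1, -sln^2 / 2, sln))
    } else 1

    amp <- cfg$ais_peak_amp * (if (treated) cfg$effect$ais_scale else 1) *
      amp_factor
    dend_level <- cfg$dendrite_level *
      (if (treated) cfg$effect$dendrite_scale else 1) * dend_factor

    bump <- ais_bump_model(len, start_um = cfg$ais_start_um)
    n_ais <- floor(cfg$profile_span_um / px) + 1L
    x <- (seq_len(n_ais) - 1) * px
    # Renormalize to the sampled maximum (a pure rescaling, which leaves the
    # threshold crossings untouched) so the designed peak amplitude is hit
    # exactly on the pixel grid.
    v <- bump$f(x)
    v <- v / max(v)
    ais_true <- cfg$background_level + amp * v
    n_dend <- floor(15 / px) + 1L
    dend_true <- rep(cfg$background_level + dend_level, n_dend)

    ais_obs <- ais_true
    dend_obs <- dend_true
    if (cfg$noise_sd > 0) {
      ais_obs <- ais_obs + stats::rnorm(n_ais, 0, cfg$noise_sd)
      dend_obs <- dend_obs + stats::rnorm(n_dend, 0, cfg$noise_sd)
    }

    ref <- reference_quant(ais_true - cfg$background_level,
                           dend_true - cfg$background_level, px)
    gt <- list(
      condition = condition,
      length_um = len,
      peak_um = bump$peak_um,
      start_um = bump$start_um,
      end_um = bump$end_um,
      peak_amp = amp,
      dendrite_level = dend_level,
      background_level = cfg$background_level,
      ais_integrated_sum = ref$ais_integrated_sum,
      dendrite_integrated_sum = ref$dendrite_integrated_sum,
      adr = ref$adr,
      detected_length_noiseless_um = ref$length_um
    )

    neuron_record(
      neuron_id = neuron_id,
      treatment = condition,
      ais_profile = intensity_profile(ais_obs, px, "AIS"),
      dendrite_profile = intensity_profile(dend_obs, px, "dendrite"),
      background_mean = cfg$background_level,
      ground_truth = gt
    )
  })
}

#' Generate a labeled two-condition cohort
#'
#' Produces `2 * cfg$n_per_condition` records, `n_per_condition` per
#' condition, with per-record seeds derived from `cfg$seed` by counter-based
#' splitting (record `i` of each condition always gets the same seed,
#' regardless of cohort size).
#'
#' @param cfg a [cohort_config()].
#' @return an object of class `neuron_cohort`: a list of [neuron_record()]s
#'   with the config attached as attribute `"config"`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  recs <- vector("list", 2L * cfg$n_per_condition)
  k <- 1L
  for (cond in c("control", "treated")) {
    stream <- if (cond == "control") 1L else 2L
    for (i in seq_len(cfg$n_per_condition)) {
      recs[[k]] <- generate_profile(
        cfg, cond,
        seed = child_seed(cfg$seed, i, stream),
        neuron_id = sprintf("%s_%03d", if (stream == 1L) "ctrl" else "trt", i)
      )
      k <- k + 1L
    }
  }
  structure(recs, class = "neuron_cohort", config = cfg)
}

#' @export
print.neuron_cohort <- function(x, ...) {
  tr <- table(vapply(x, function(r) r$treatment, character(1)))
  cat(sprintf("<neuron_cohort> %d records (%s)\n", length(x),
              paste(sprintf("%s: %d", names(tr), tr), collapse = ", ")))
  invisible(x)
}

#' Render a synthetic neuron record as a 2-D image with ROI annotations
#'
#' Paints the record's AIS profile along a straight horizontal neurite of
#' `width_px` rows on a constant-background canvas, optionally blurs it with
#' a Gaussian point-spread approximation and adds pixel noise, and returns
#' the image together with 0-based half-open rectangular ROIs for the neurite
#' and an off-neurite background region.
#'
#' @param record a [neuron_record()].
#' @param width_px neurite width in pixels (>= 3; typical tracing widths are
#'   3 or 4 pixels).
#' @param psf_sd_px Gaussian blur SD in pixels (0 = no blur; requires the
#'   EBImage package when > 0).
#' @param noise_sd additional image noise SD, a.u.
#' @param margin_px background margin rows above/below the neurite.
#' @param seed seed for the image noise.
#' @return a list with `image` (matrix, rows = y), `rois` (list of `neurite`
#'   and `background` rectangles, each `c(x0, x1, y0, y1)` 0-based
#'   half-open), and `pixel_size_um`.
#' @export
render_image <- function(record, width_px = 3L, psf_sd_px = 0, noise_sd = 0,
                         margin_px = 6L, seed = 1L) {
  stopifnot(inherits(record, "neuron_record"))
  stopifnot_scalar(width_px, "width_px", positive = TRUE, integerish = TRUE)
  if (width_px < 3) stop("`width_px` must be >= 3", call. = FALSE)
  stopifnot_scalar(psf_sd_px, "psf_sd_px", nonneg = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(margin_px, "margin_px", positive = TRUE, integerish = TRUE)
  if (margin_px < 2) stop("`margin_px` must be >= 2", call. = FALSE)

  prof <- record$ais_profile$intensities
  n <- length(prof)
  h <- as.integer(width_px + 2L * margin_px)
  img <- matrix(record$background_mean, nrow = h, ncol = n)
  rows <- (margin_px + 1L):(margin_px + width_px)
  for (r in rows) img[r, ] <- prof

  if (psf_sd_px > 0) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("Gaussian blur requires the EBImage package", call. = FALSE)
    }
    # EBImage images are x-major; transpose in and out.
    img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                               sigma = psf_sd_px)))
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(h * n, 0, noise_sd),
                                        nrow = h))
  }
  list(
    image = img,
    rois = list(
      neurite = c(x0 = 0L, x1 = n, y0 = margin_px,
                  y1 = margin_px + as.integer(width_px)),
      background = c(x0 = 0L, x1 = n, y0 = 0L, y1 = margin_px - 1L)
    ),
    pixel_size_um = record$ais_profile$pixel_size_um
  )
}
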