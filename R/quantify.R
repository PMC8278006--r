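#' Sum-project a Z-stack
#'
#' Pixelwise sum of all planes of a confocal Z-stack, the standard projection
#' applied before line-profile extraction.
#'
#' @param stack a 3-D numeric array (rows x cols x planes) or a list of
#'   equally sized matrices (as returned by [tiff::readTIFF] with
#'   `all = TRUE`).
#' @return a numeric matrix of pixelwise sums (stored as double, so integer
#'   inputs cannot overflow).
#' @export
#' @examples
#' sum_project(array(1, dim = c(4, 4, 2)))[1, 1] # 2
sum_project <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0L) stop("empty stack", call. = FALSE)
    dims <- vapply(stack, dim, integer(2))
    if (any(dims != dims[, 1])) {
      stop("all planes must have identical dimensions", call. = FALSE)
    }
    stack <- array(unlist(stack, use.names = FALSE),
                   dim = c(dims[1, 1], dims[2, 1], length(stack)))
  }
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    stop("`stack` must be a 3-D array with >= 1 plane", call. = FALSE)
  }
  storage.mode(stack) <- "double"
  rowSums(stack, dims = 2L)
}

#' Extract an intensity line profile from a rectangular ROI
#'
#' Averages the image across the ROI width and returns one intensity value
#' per position along the ROI axis, at physical spacing `pixel_size_um`.
#' Tracing widths of 3 or 4 pixels are conventional; other widths are
#' accepted with a warning.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param roi rectangle `c(x0, x1, y0, y1)`, 0-based half-open pixel bounds.
#' @param pixel_size_um physical pixel size, um.
#' @param axis profile direction: `"x"` (along columns, averaging over rows)
#'   or `"y"`.
#' @param compartment,analyte labels stamped on the returned profile.
#' @return an [intensity_profile()].
#' @export
extract_profile <- function(image, roi, pixel_size_um,
                            axis = c("x", "y"),
                            compartment = c("AIS", "dendrite"),
                            analyte = "analyte") {
  axis <- match.arg(axis)
  compartment <- match.arg(compartment)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  roi <- as.integer(round(roi))
  if (length(roi) != 4L) {
    stop("`roi` must be c(x0, x1, y0, y1)", call. = FALSE)
  }
  x0 <- roi[1]; x1 <- roi[2]; y0 <- roi[3]; y1 <- roi[4]
  if (x0 < 0L || y0 < 0L || x1 > ncol(image) || y1 > nrow(image) ||
      x0 >= x1 || y0 >= y1) {
    stop("`roi` out of image bounds or empty", call. = FALSE)
  }
  sub <- image[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
  width <- if (axis == "x") nrow(sub) else ncol(sub)
  if (width < 1L) stop("ROI width must be >= 1 pixel", call. = FALSE)
  if (!width %in% c(3L, 4L)) {
    warning(sprintf("ROI width is %d pixels; tracing convention is 3 or 4",
                    width), call. = FALSE)
  }
  vals <- if (axis == "x") colMeans(sub) else rowMeans(sub)
  intensity_profile(vals, pixel_size_um, compartment = compartment,
                    analyte = analyte)
}

#' Subtract the image background from a profile
#'
#' Removes the mean intensity of an off-neurite background region from every
#' point of the profile. Negative values are retained. Applying the
#' subtraction twice is an error.
#'
#' @param profile an [intensity_profile()].
#' @param background_mean background mean, a.u.
#' @return the profile with `background_subtracted = TRUE`.
#' @export
subtract_background <- function(profile, background_mean) {
  assert_profile(profile)
  stopifnot_scalar(background_mean, "background_mean")
  if (profile$background_subtracted) {
    stop("profile is already background-subtracted", call. = FALSE)
  }
  profile$intensities <- profile$intensities - background_mean
  profile$background_subtracted <- TRUE
  profile
}

#' Centered moving-average smoothing
#'
#' The three-point average used before peak and boundary detection. Windows
#' shrink at the profile edges (the first and last points average over the
#' available samples), so the output has the same length as the input.
#'
#' @param profile an [intensity_profile()].
#' @param window odd window size, `1 <= window <= length(profile)`.
#' @return the smoothed profile.
#' @export
#' @examples
#' p <- intensity_profile(c(0, 3, 6), pixel_size_um = 1)
#' smooth_profile(p)$intensities # 1.5 3.0 4.5
smooth_profile <- function(profile, window = 3L) {
  assert_profile(profile)
  stopifnot_scalar(window, "window", positive = TRUE, integerish = TRUE)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  n <- length(profile$intensities)
  if (window > n) stop("`window` exceeds profile length", call. = FALSE)
  if (window > 1L) {
    profile$intensities <- as.numeric(
      zoo::rollapply(profile$intensities, window, mean, partial = TRUE,
                     align = "center")
    )
  }
  profile
}

#' Detect AIS boundaries by the 15%-of-peak rule
#'
#' Smooths the background-subtracted profile with a centered three-point
#' average, locates the peak (first index attaining the smoothed maximum),
#' and walks outward in both directions: each boundary is the last sample
#' whose smoothed value is still at or above `threshold_fraction` of the
#' smoothed peak, i.e. the sample immediately before the signal first drops
#' strictly below the threshold. If the signal never drops below the
#' threshold before the ROI edge, the boundary is clamped to the edge and
#' flagged. The extent between the two boundaries is the analyte-specific
#' AIS length; each unclamped boundary position is reported at the midpoint
#' between the last above-threshold sample and its below-threshold
#' neighbour (half a pixel beyond the included sample), the unbiased
#' estimate of the continuous threshold crossing, so `length_um` agrees
#' with the continuous crossing-to-crossing extent to within one pixel.
#'
#' @param profile a background-subtracted [intensity_profile()].
#' @param threshold_fraction fraction of the smoothed peak (default 0.15).
#' @param smooth_window smoothing window used internally (default 3).
#' @return an object of class `ais_boundaries`: a list with `peak_index`,
#'   `start_index`, `end_index` (1-based sample indices), `peak_value`
#'   (smoothed, background-subtracted), `peak_um`, `start_um`, `end_um`,
#'   `length_um`, and flags `clamped_start`, `clamped_end`.
#' @export
detect_ais_boundaries <- function(profile, threshold_fraction = 0.15,
                                  smooth_window = 3L) {
  assert_profile(profile)
  if (!profile$background_subtracted) {
    stop("`profile` must be background-subtracted before boundary detection",
         call. = FALSE)
  }
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1) {
    stop("`threshold_fraction` must be in (0, 1)", call. = FALSE)
  }
  sm <- smooth_profile(profile, smooth_window)$intensities
  peak <- which.max(sm) # first index attaining the maximum
  peak_value <- sm[peak]
  if (peak_value <= 0) {
    stop("no AIS detected: smoothed profile has no positive peak",
         call. = FALSE)
  }
  thr <- threshold_fraction * peak_value
  n <- length(sm)
  start <- peak
  while (start > 1L && sm[start - 1L] >= thr) start <- start - 1L
  end <- peak
  while (end < n && sm[end + 1L] >= thr) end <- end + 1L
  clamped_start <- start == 1L
  clamped_end <- end == n
  px <- profile$pixel_size_um
  # The true threshold crossing lies between the last above-threshold sample
  # and its below-threshold neighbour; an unclamped boundary is placed at the
  # midpoint (half a pixel outward), which keeps the length estimate within
  # one pixel of the continuous crossing-to-crossing extent. Clamped
  # boundaries stay at the ROI edge.
  start_um <- profile$positions[start] - (if (clamped_start) 0 else px / 2)
  end_um <- profile$positions[end] + (if (clamped_end) 0 else px / 2)
  structure(
    list(peak_index = peak, peak_value = peak_value,
         start_index = start, end_index = end,
         peak_um = profile$positions[peak],
         start_um = start_um,
         end_um = end_um,
         length_um = end_um - start_um,
         clamped_start = clamped_start,
         clamped_end = clamped_end),
    class = "ais_boundaries"
  )
}

#' @export
print.ais_boundaries <- function(x, ...) {
  cat(sprintf(
    "<ais_boundaries> peak %.2f um (%.3g a.u.), extent [%.2f, %.2f] um, length %.2f um%s\n",
    x$peak_um, x$peak_value, x$start_um, x$end_um, x$length_um,
    if (x$clamped_start || x$clamped_end) " [clamped]" else ""
  ))
  invisible(x)
}

#' Integrated sum of a profile segment
#'
#' Summed (unsmoothed) background-subtracted pixel intensity over the
#' inclusive segment `[start_index, end_index]`, divided by the segment
#' length — a mean intensity per unit length. The denominator is the segment
#' length in micrometres (`(end - start) * pixel_size_um`) by default, or the
#' pixel count (`end - start`) with `length_unit = "px"`.
#'
#' @param profile a background-subtracted [intensity_profile()].
#' @param start_index,end_index 1-based inclusive sample bounds,
#'   `start_index < end_index`.
#' @param length_unit `"um"` or `"px"`.
#' @return the integrated sum, a.u. per um (or per pixel).
#' @export
integrated_sum <- function(profile, start_index, end_index,
                           length_unit = c("um", "px")) {
  assert_profile(profile)
  length_unit <- match.arg(length_unit)
  if (!profile$background_subtracted) {
    stop("`profile` must be background-subtracted", call. = FALSE)
  }
  n <- length(profile$intensities)
  stopifnot_scalar(start_index, "start_index", positive = TRUE,
                   integerish = TRUE)
  stopifnot_scalar(end_index, "end_index", positive = TRUE, integerish = TRUE)
  if (start_index >= end_index || end_index > n) {
    stop("need 1 <= start_index < end_index <= length(profile); ",
         "zero-length segments have no defined integrated sum", call. = FALSE)
  }
  len <- (end_index - start_index) *
    (if (length_unit == "um") profile$pixel_size_um else 1)
  sum(profile$intensities[start_index:end_index]) / len
}

#' Quantify one neuron: AIS length, integrated sums and axo:dendritic ratio
#'
#' Applies the full single-neuron quantification: background subtraction of
#' both profiles, boundary detection on the AIS (15%-of-peak rule on the
#' three-point-smoothed profile), the AIS integrated sum over the detected
#' extent, the dendrite integrated sum over the full 15-um trace (no
#' boundary rule), and their ratio (adr). Integrated sums use the unsmoothed
#' background-subtracted intensities.
#'
#' @param record a [neuron_record()].
#' @param background_mean_ais,background_mean_dend background means for each
#'   compartment; default to the record's stored `background_mean`.
#' @param threshold_fraction boundary threshold (default 0.15).
#' @param length_unit integrated-sum denominator unit, `"um"` or `"px"`.
#' @return an object of class `quant_result`: a list with `neuron_id`,
#'   `treatment`, `analyte`, `ais_length_um`, `ais_integrated_sum`,
#'   `dendrite_integrated_sum`, `adr`, `adr_defined`, `clamped_start`,
#'   `clamped_end` and the detected `boundaries`.
#' @export
quantify_neuron <- function(record,
                            background_mean_ais = record$background_mean,
                            background_mean_dend = record$background_mean,
                            threshold_fraction = 0.15,
                            length_unit = c("um", "px")) {
  stopifnot(inherits(record, "neuron_record"))
  length_unit <- match.arg(length_unit)
  ais <- subtract_background(record$ais_profile, background_mean_ais)
  dend <- subtract_background(record$dendrite_profile, background_mean_dend)
  b <- detect_ais_boundaries(ais, threshold_fraction)
  ais_sum <- integrated_sum(ais, b$start_index, b$end_index, length_unit)
  dend_sum <- integrated_sum(dend, 1L, length(dend$intensities), length_unit)
  adr_defined <- is.finite(dend_sum) && dend_sum > 0
  structure(
    list(neuron_id = record$neuron_id,
         treatment = record$treatment,
         analyte = record$analyte,
         ais_length_um = b$length_um,
         ais_integrated_sum = ais_sum,
         dendrite_integrated_sum = dend_sum,
         adr = if (adr_defined) ais_sum / dend_sum else NA_real_,
         adr_defined = adr_defined,
         clamped_start = b$clamped_start,
         clamped_end = b$clamped_end,
         boundaries = b),
    class = "quant_result"
  )
}

#' Quantify a cohort of neuron records into a table
#'
#' @param cohort a `neuron_cohort` or list of [neuron_record()]s.
#' @param ... passed to [quantify_neuron()].
#' @return a data.frame with one row per neuron: `neuron_id`, `treatment`,
#'   `analyte`, `ais_length_um`, `ais_integrated_sum`,
#'   `dendrite_integrated_sum`, `adr`, `adr_defined`, `clamped_start`,
#'   `clamped_end`.
#' @export
quantify_cohort <- function(cohort, ...) {
  rows <- lapply(cohort, function(rec) {
    q <- quantify_neuron(rec, ...)
    data.frame(neuron_id = q$neuron_id, treatment = q$treatment,
               analyte = q$analyte, ais_length_um = q$ais_length_um,
               ais_integrated_sum = q$ais_integrated_sum,
               dendrite_integrated_sum = q$dendrite_integrated_sum,
               adr = q$adr, adr_defined = q$adr_defined,
               clamped_start = q$clamped_start, clamped_end = q$clamped_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalize quantification values to the control-group mean
#'
#' Divides each value column by the mean of the control group, per analyte,
#' mirroring normalization of treated intensities to the vehicle (DMSO)
#' control. The control-group mean of each normalized column is 1 by
#' construction.
#'
#' @param results data.frame from [quantify_cohort()] (columns `treatment`,
#'   `analyte` and the value columns).
#' @param control_label treatment label of the control group.
#' @param value_cols columns to normalize; normalized columns are appended
#'   as `normalized_ais`, `normalized_dendrite`, `normalized_adr` (or
#'   `normalized_<col>` for other columns).
#' @return `results` with the normalized columns appended.
#' @export
normalize_to_control <- function(results, control_label = "control",
                                 value_cols = c("ais_integrated_sum",
                                                "dendrite_integrated_sum",
                                                "adr")) {
  stopifnot(is.data.frame(results))
  if (!control_label %in% results$treatment) {
    stop(sprintf("no records with control label '%s'", control_label),
         call. = FALSE)
  }
  short <- c(ais_integrated_sum = "normalized_ais",
             dendrite_integrated_sum = "normalized_dendrite",
             adr = "normalized_adr")
  for (col in value_cols) {
    if (!col %in% names(results)) {
      stop(sprintf("column '%s' not found", col), call. = FALSE)
    }
    out_col <- if (col %in% names(short)) short[[col]] else
      paste0("normalized_", col)
    results[[out_col]] <- NA_real_
    for (an in unique(results$analyte)) {
      sel <- results$analyte == an
      ctrl <- results[[col]][sel & results$treatment == control_label]
      ctrl_mean <- mean(ctrl, na.rm = TRUE)
      if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
        stop(sprintf(
          "control mean of '%s' for analyte '%s' is not positive", col, an
        ), call. = FALSE)
      }
      results[[out_col]][sel] <- results[[col]][sel] / ctrl_mean
    }
  }
  results
}

#' Natural-log transform of positive quantification values
#'
#' Intensity-derived quantities are log transformed before group statistics.
#' Non-positive values are an error naming the offending record.
#'
#' @param values numeric vector, all > 0.
#' @param ids optional identifiers used in error messages.
#' @return `log(values)`.
#' @export
log_transform <- function(values, ids = NULL) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0L) {
    who <- if (!is.null(ids)) ids[bad[1]] else sprintf("element %d", bad[1])
    stop(sprintf("log transform requires positive values; first offender: %s",
                 who), call. = FALSE)
  }
  log(values)
}
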