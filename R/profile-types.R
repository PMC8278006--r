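#' Construct a fluorescence intensity line profile
#'
#' An `intensity_profile` is a 1-D fluorescence trace sampled at uniform
#' physical spacing along a traced neurite (the axon initial segment or a
#' dendrite). Positions are in micrometres from the proximal end of the
#' traced region of interest, starting at 0.
#'
#' @param intensities numeric vector of fluorescence values (arbitrary
#'   units), length >= 3.
#' @param pixel_size_um physical sample spacing in micrometres (> 0).
#' @param compartment `"AIS"` or `"dendrite"`.
#' @param analyte label of the stained protein (e.g. `"bIV-spectrin"`).
#' @param background_subtracted logical; whether the image background mean
#'   has already been removed.
#' @param positions optional explicit positions in micrometres; must be
#'   uniformly spaced by `pixel_size_um` and start at 0. Defaults to
#'   `(seq_along(intensities) - 1) * pixel_size_um`.
#'
#' @return an object of class `intensity_profile`: a list with fields
#'   `positions`, `intensities`, `pixel_size_um`, `compartment`, `analyte`,
#'   `background_subtracted`.
#' @export
#' @examples
#' p <- intensity_profile(c(1, 5, 9, 5, 1), pixel_size_um = 0.28)
#' p$positions
intensity_profile <- function(intensities, pixel_size_um,
                              compartment = c("AIS", "dendrite"),
                              analyte = "analyte",
                              background_subtracted = FALSE,
                              positions = NULL) {
  compartment <- match.arg(compartment)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!is.numeric(intensities) || length(intensities) < 3L) {
    stop("`intensities` must be a numeric vector of length >= 3", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("`intensities` must be finite", call. = FALSE)
  }
  if (is.null(positions)) {
    positions <- (seq_along(intensities) - 1) * pixel_size_um
  } else {
    if (length(positions) != length(intensities)) {
      stop("`positions` and `intensities` must have the same length",
           call. = FALSE)
    }
    sp <- diff(positions)
    if (any(abs(sp - pixel_size_um) > 1e-9)) {
      stop("`positions` must be uniformly spaced by `pixel_size_um`",
           call. = FALSE)
    }
  }
  structure(
    list(positions = positions,
         intensities = as.numeric(intensities),
         pixel_size_um = pixel_size_um,
         compartment = compartment,
         analyte = analyte,
         background_subtracted = isTRUE(background_subtracted)),
    class = "intensity_profile"
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "<intensity_profile> %s / %s: %d samples, %.3g um/px, span %.2f um%s\n",
    x$analyte, x$compartment, length(x$intensities), x$pixel_size_um,
    max(x$positions), if (x$background_subtracted) ", bg-subtracted" else ""
  ))
  invisible(x)
}

is_intensity_profile <- function(x) inherits(x, "intensity_profile")

assert_profile <- function(x, name = "profile") {
  if (!is_intensity_profile(x)) {
    stop(sprintf("`%s` must be an intensity_profile", name), call. = FALSE)
  }
  invisible(x)
}

#' Construct a per-neuron record of AIS and dendrite profiles
#'
#' Bundles the two traced profiles of one neuron together with its treatment
#' label and, for synthetic neurons, the generator ground truth.
#'
#' @param neuron_id character identifier.
#' @param treatment treatment label (e.g. `"control"`, `"treated"`).
#' @param ais_profile,dendrite_profile [intensity_profile()] objects tagged
#'   with the matching compartment; the dendrite trace must span 15 um
#'   (within one pixel), mirroring the standard 15-um dendrite tracing
#'   convention.
#' @param analyte analyte label.
#' @param background_mean mean intensity of an off-neurite background region
#'   of the source image (used for background subtraction downstream).
#' @param ground_truth optional list of generator ground-truth values.
#'
#' @return an object of class `neuron_record`.
#' @export
neuron_record <- function(neuron_id, treatment, ais_profile, dendrite_profile,
                          analyte = "analyte", background_mean = 0,
                          ground_truth = NULL) {
  assert_profile(ais_profile, "ais_profile")
  assert_profile(dendrite_profile, "dendrite_profile")
  if (ais_profile$compartment != "AIS") {
    stop("`ais_profile` must be tagged compartment = 'AIS'", call. = FALSE)
  }
  if (dendrite_profile$compartment != "dendrite") {
    stop("`dendrite_profile` must be tagged compartment = 'dendrite'",
         call. = FALSE)
  }
  dspan <- max(dendrite_profile$positions)
  if (abs(dspan - 15) > dendrite_profile$pixel_size_um + 1e-9) {
    stop(sprintf(
      "dendrite profile must span 15 um within one pixel (got %.3f um)", dspan
    ), call. = FALSE)
  }
  stopifnot_scalar(background_mean, "background_mean", nonneg = TRUE)
  structure(
    list(neuron_id = as.character(neuron_id),
         treatment = as.character(treatment),
         analyte = as.character(analyte),
         ais_profile = ais_profile,
         dendrite_profile = dendrite_profile,
         background_mean = background_mean,
         ground_truth = ground_truth),
    class = "neuron_record"
  )
}

#' @export
print.neuron_record <- function(x, ...) {
  cat(sprintf("<neuron_record> %s [%s, %s]: AIS %d px, dendrite %d px\n",
              x$neuron_id, x$treatment, x$analyte,
              length(x$ais_profile$intensities),
              length(x$dendrite_profile$intensities)))
  invisible(x)
}
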