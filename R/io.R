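# File formats: profile cohorts as long CSV + JSON ground-truth sidecar;
# images as TIFF + JSON ROI sidecar (0-based half-open rectangles); sweep
# families as one CSV per cell (time_ms, one voltage column per sweep) + JSON
# protocol sidecar. CSV files may carry a leading '# key=value' comment line
# (the pipeline stamps its config hash there).

json_sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", ".json", path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
}

# write.csv with an optional '# key=value' header comment.
write_csv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_csv_commented <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a neuron cohort as CSV plus a JSON ground-truth sidecar
#'
#' The CSV is long format with columns `neuron_id`, `condition`,
#' `compartment`, `position_um`, `intensity`; the JSON sidecar stores per
#' record the pixel size, analyte, background mean and generator ground
#' truth (when present).
#'
#' @param cohort a `neuron_cohort` or list of [neuron_record()]s.
#' @param csv_path output CSV path.
#' @param json_path sidecar path; defaults to the CSV path with a `.json`
#'   extension.
#' @param comment optional `key=value` comment stamped as the first CSV line.
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(cohort, csv_path,
                         json_path = json_sidecar_path(csv_path),
                         comment = NULL) {
  rows <- lapply(cohort, function(rec) {
    rbind(
      data.frame(neuron_id = rec$neuron_id, condition = rec$treatment,
                 compartment = "AIS",
                 position_um = rec$ais_profile$positions,
                 intensity = rec$ais_profile$intensities,
                 stringsAsFactors = FALSE),
      data.frame(neuron_id = rec$neuron_id, condition = rec$treatment,
                 compartment = "dendrite",
                 position_um = rec$dendrite_profile$positions,
                 intensity = rec$dendrite_profile$intensities,
                 stringsAsFactors = FALSE)
    )
  })
  write_csv_commented(do.call(rbind, rows), csv_path, comment)
  meta <- lapply(cohort, function(rec) {
    list(neuron_id = rec$neuron_id, condition = rec$treatment,
         analyte = rec$analyte,
         pixel_size_um = rec$ais_profile$pixel_size_um,
         background_mean = rec$background_mean,
         ground_truth = rec$ground_truth)
  })
  write_json_file(meta, json_path)
  invisible(csv_path)
}

#' @rdname write_cohort
#' @return `read_cohort`: a `neuron_cohort`.
#' @export
read_cohort <- function(csv_path, json_path = json_sidecar_path(csv_path)) {
  df <- read_csv_commented(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  recs <- lapply(meta, function(m) {
    sel <- df$neuron_id == m$neuron_id
    ais <- df[sel & df$compartment == "AIS", ]
    dend <- df[sel & df$compartment == "dendrite", ]
    neuron_record(
      neuron_id = m$neuron_id, treatment = m$condition,
      analyte = m$analyte,
      ais_profile = intensity_profile(ais$intensity, m$pixel_size_um, "AIS"),
      dendrite_profile = intensity_profile(dend$intensity, m$pixel_size_um,
                                           "dendrite"),
      background_mean = m$background_mean,
      ground_truth = m$ground_truth
    )
  })
  structure(recs, class = "neuron_cohort")
}

#' Write / read an image (or Z-stack) as TIFF plus a JSON ROI sidecar
#'
#' Images are stored as 32-bit float TIFF rescaled to `[0, 1]`; the affine
#' intensity scale (`lo`, `hi`) is recorded in the sidecar and undone on
#' read, so arbitrary-unit intensities round-trip. Multi-plane stacks are
#' written as multi-page TIFF. ROI rectangles are 0-based, half-open
#' `c(x0, x1, y0, y1)` pixel bounds.
#'
#' @param image numeric matrix, or list of matrices for a stack.
#' @param tiff_path output TIFF path.
#' @param rois named list of ROI rectangles (may be empty).
#' @param pixel_size_um physical pixel size recorded in the sidecar.
#' @param json_path sidecar path; defaults to the TIFF path with `.json`.
#' @return `tiff_path`, invisibly.
#' @export
write_image <- function(image, tiff_path, rois = list(), pixel_size_um = NA,
                        json_path = json_sidecar_path(tiff_path)) {
  planes <- if (is.list(image)) image else list(image)
  lo <- min(vapply(planes, min, numeric(1)))
  hi <- max(vapply(planes, max, numeric(1)))
  span <- if (hi > lo) hi - lo else 1
  scaled <- lapply(planes, function(m) (m - lo) / span)
  tiff::writeTIFF(if (length(scaled) == 1L) scaled[[1]] else scaled,
                  tiff_path, bits.per.sample = 32L)
  write_json_file(list(lo = lo, hi = hi,
                       pixel_size_um = pixel_size_um,
                       rois = rois), json_path)
  invisible(tiff_path)
}

#' @rdname write_image
#' @return `read_image`: a list with `image` (matrix, or list of matrices
#'   for multi-page TIFF), `rois`, `pixel_size_um`.
#' @export
read_image <- function(tiff_path, json_path = json_sidecar_path(tiff_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  span <- if (meta$hi > meta$lo) meta$hi - meta$lo else 1
  planes <- tiff::readTIFF(tiff_path, all = TRUE)
  planes <- lapply(planes, function(m) m * span + meta$lo)
  list(image = if (length(planes) == 1L) planes[[1]] else planes,
       rois = meta$rois, pixel_size_um = meta$pixel_size_um)
}

#' Write / read a current-clamp sweep family as CSV plus a JSON sidecar
#'
#' The CSV has a `time_ms` column and one voltage column per sweep
#' (`sweep_1`, `sweep_2`, ... in order of increasing amplitude); the sidecar
#' stores the per-sweep current amplitudes, the step window, the cell id and
#' any generator ground truth.
#'
#' @param recording a [current_clamp_recording()].
#' @param csv_path output CSV path.
#' @param json_path sidecar path; defaults to the CSV path with `.json`.
#' @param comment optional `key=value` comment stamped as the first CSV line.
#' @return `csv_path`, invisibly.
#' @export
write_sweeps <- function(recording, csv_path,
                         json_path = json_sidecar_path(csv_path),
                         comment = NULL) {
  df <- data.frame(time_ms = recording$time_ms)
  for (i in seq_along(recording$current_pa)) {
    df[[sprintf("sweep_%d", i)]] <- recording$sweeps[, i]
  }
  write_csv_commented(df, csv_path, comment)
  write_json_file(
    list(cell_id = recording$cell_id,
         current_pa = recording$current_pa,
         step_onset_ms = recording$step_onset_ms,
         step_offset_ms = recording$step_offset_ms,
         ground_truth = recording$ground_truth),
    json_path
  )
  invisible(csv_path)
}

#' @rdname write_sweeps
#' @return `read_sweeps`: a [current_clamp_recording()].
#' @export
read_sweeps <- function(csv_path, json_path = json_sidecar_path(csv_path)) {
  df <- read_csv_commented(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  gt <- meta$ground_truth
  if (!is.null(gt)) gt <- lapply(gt, function(x) {
    if (is.list(x)) lapply(x, unlist) else unlist(x)
  })
  current_clamp_recording(
    time_ms = df$time_ms,
    sweeps = as.matrix(df[, -1, drop = FALSE]),
    current_pa = unlist(meta$current_pa),
    step_onset_ms = meta$step_onset_ms,
    step_offset_ms = meta$step_offset_ms,
    cell_id = meta$cell_id,
    ground_truth = gt
  )
}
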