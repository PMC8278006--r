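#' Default pipeline configuration
#'
#' Returns the fully defaulted run configuration as a nested list. The
#' `cohort` block is the [cohort_config()] field set; `ephys` holds the
#' [cell_config()] passive/active parameters plus the number of simulated
#' cells; `quantify` and `classify` expose the quantification and classifier
#' options.
#'
#' @return a nested list of defaults (with `seed = NULL`, meaning "generate
#'   one and record it in the manifest").
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "quantify", "features", "classify", "ephys"),
    seed = NULL,
    log_level = "info",
    paths = list(cohort_csv = NULL),
    cohort = list(
      n_per_condition = 40, ais_length_um = 20, ais_peak_amp = 100,
      dendrite_level = 20, background_level = 10, noise_sd = 8,
      pixel_size_um = 0.28, profile_span_um = 30,
      effect = list(length_delta_um = -4, ais_scale = 1.5,
                    dendrite_scale = 1.2),
      cell_cv = 0.25, length_sd_um = 2, ais_start_um = 2
    ),
    quantify = list(threshold_fraction = 0.15, length_unit = "um",
                    control_label = "control"),
    classify = list(kernel = "radial", cost = 1, n_repeats = 100,
                    train_fraction = 0.7, stratified = FALSE,
                    normalized_adr = FALSE),
    ephys = list(
      n_cells = 2, rin_mohm = 600, tau_ms = 50, rest_mv = -60,
      spike_threshold_mv = -40, noise_sd_mv = 0.5,
      sample_interval_ms = 0.1
    )
  )
}

# Recursively reject keys absent from the default template.
check_unknown_keys <- function(cfg, template, path = "") {
  if (!is.list(cfg) || is.null(names(cfg))) return(invisible(NULL))
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      check_unknown_keys(cfg[[nm]], template[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(NULL)
}

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path, a YAML text string, or a nested list; merges it
#' over [default_config()], rejects unknown keys, range-checks the
#' invariants (threshold and train fractions in (0, 1), positive sizes,
#' existing input paths for non-simulated stages) and, when no seed is
#' given, generates one (recorded in the run manifest).
#'
#' @param input config source; `NULL` or an empty document yields all
#'   defaults.
#' @return a validated config list with attribute `"seed_generated"`.
#' @export
validate_config <- function(input = NULL) {
  raw <- if (is.null(input)) {
    list()
  } else if (is.list(input)) {
    input
  } else if (is.character(input) && length(input) == 1L) {
    parsed <- if (file.exists(input)) yaml::read_yaml(input) else
      yaml::yaml.load(input)
    if (is.null(parsed)) list() else parsed
  } else {
    stop("`input` must be a YAML path/text, a list, or NULL", call. = FALSE)
  }
  if (!is.list(raw)) stop("config must parse to a mapping", call. = FALSE)
  template <- default_config()
  check_unknown_keys(raw, template)
  cfg <- utils::modifyList(template, raw)
  if (length(raw$stages) > 0L) cfg$stages <- unlist(raw$stages)

  known_stages <- c("simulate", "quantify", "features", "classify", "ephys")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if ("classify" %in% cfg$stages && !"features" %in% cfg$stages) {
    cfg$stages <- c(cfg$stages, "features") # classify consumes the features
  }
  tf <- cfg$quantify$threshold_fraction
  if (!is.numeric(tf) || tf <= 0 || tf >= 1) {
    stop("`quantify.threshold_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (!cfg$quantify$length_unit %in% c("um", "px")) {
    stop("`quantify.length_unit` must be 'um' or 'px'", call. = FALSE)
  }
  trf <- cfg$classify$train_fraction
  if (!is.numeric(trf) || trf <= 0 || trf >= 1) {
    stop("`classify.train_fraction` must be in (0, 1)", call. = FALSE)
  }
  stopifnot_scalar(cfg$classify$n_repeats, "classify.n_repeats",
                   positive = TRUE, integerish = TRUE)
  stopifnot_scalar(cfg$ephys$n_cells, "ephys.n_cells", positive = TRUE,
                   integerish = TRUE)
  if (!"simulate" %in% cfg$stages &&
      any(c("quantify", "features", "classify") %in% cfg$stages)) {
    if (is.null(cfg$paths$cohort_csv)) {
      stop("`paths.cohort_csv` is required when the simulate stage is off",
           call. = FALSE)
    }
    if (!file.exists(cfg$paths$cohort_csv)) {
      stop(sprintf("input path does not exist: %s", cfg$paths$cohort_csv),
           call. = FALSE)
    }
  }
  # Normalize the paths block (YAML serialization drops NULL-valued keys).
  if (is.null(cfg$paths$cohort_csv)) {
    cfg$paths <- stats::setNames(list(NULL), "cohort_csv")
  }
  seed_generated <- is.null(cfg$seed)
  if (seed_generated) {
    cfg$seed <- as.integer((as.numeric(Sys.time()) * 1000) %% 2147483646) + 1L
  }
  stopifnot_scalar(cfg$seed, "seed", integerish = TRUE)
  # Validate the cohort block eagerly so config errors precede any stage.
  do.call(cohort_config, c(cfg$cohort, list(seed = cfg$seed)))
  structure(cfg, seed_generated = seed_generated)
}

pipeline_logger <- function(log_path, level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  min_level <- levels[[match.arg(level, names(levels))]]
  function(msg, lvl = "info") {
    if (levels[[lvl]] >= min_level) {
      line <- sprintf("%s [%s] %s",
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                      toupper(lvl), msg)
      cat(line, "\n", sep = "", file = log_path, append = TRUE)
    }
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> quantify -> features -> classify -> ephys on a
#' validated configuration, writing all tables (CSV), reports (JSON), a log
#' and a machine-readable manifest to `out_dir`. Every CSV/JSON output is
#' stamped with the md5 hash of the canonical config serialization; outputs
#' are bit-identical across runs with the same config and seed (the log file
#' carries wall-clock timestamps and is exempt).
#'
#' @param config a config accepted by [validate_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest list, invisibly. Output files: `config_echo.json`,
#'   `cohort_profiles.csv`/`.json`, `quant_results.csv`, `features.csv`,
#'   `classification_report.json`, `ephys_sweeps_*.csv`/`.json`,
#'   `ephys_features.csv`, `manifest.json`, `run.log`.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (is.list(config) && !is.null(attr(config, "seed_generated"))) {
    config
  } else {
    validate_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- pipeline_logger(file.path(out_dir, "run.log"), cfg$log_level)
  hash <- config_hash(unclass(cfg))
  stamp <- paste0("config_hash=", hash)
  outputs <- character(0)
  emit <- function(name) outputs <<- c(outputs, name)

  log(sprintf("run start: seed=%d config_hash=%s stages=%s", cfg$seed, hash,
              paste(cfg$stages, collapse = ",")))
  write_json_file(c(list(config_hash = hash), unclass(cfg)),
                  file.path(out_dir, "config_echo.json"))
  emit("config_echo.json")

  cohort <- NULL
  if ("simulate" %in% cfg$stages) {
    log("stage simulate: generating cohort")
    ccfg <- do.call(cohort_config, c(cfg$cohort, list(seed = cfg$seed)))
    cohort <- generate_cohort(ccfg)
    write_cohort(cohort, file.path(out_dir, "cohort_profiles.csv"),
                 comment = stamp)
    emit("cohort_profiles.csv")
    emit("cohort_profiles.json")
  } else if (!is.null(cfg$paths$cohort_csv)) {
    log(sprintf("loading cohort from %s", cfg$paths$cohort_csv))
    cohort <- read_cohort(cfg$paths$cohort_csv)
  }

  quant <- NULL
  if ("quantify" %in% cfg$stages) {
    log("stage quantify")
    quant <- tryCatch(
      quantify_cohort(cohort,
                      threshold_fraction = cfg$quantify$threshold_fraction,
                      length_unit = cfg$quantify$length_unit),
      error = function(e) {
        log(sprintf("quantify failed: %s", conditionMessage(e)), "error")
        stop(e)
      }
    )
    quant <- normalize_to_control(quant, cfg$quantify$control_label)
    write_csv_commented(quant, file.path(out_dir, "quant_results.csv"), stamp)
    emit("quant_results.csv")
  }

  feats <- NULL
  if ("features" %in% cfg$stages) {
    log("stage features")
    feats <- feature_table(
      cohort, threshold_fraction = cfg$quantify$threshold_fraction,
      normalized_adr = cfg$classify$normalized_adr,
      control_label = cfg$quantify$control_label
    )
    write_csv_commented(feats, file.path(out_dir, "features.csv"), stamp)
    emit("features.csv")
  }

  if ("classify" %in% cfg$stages) {
    log("stage classify")
    res <- run_repeated_classification(
      feats[, c("iqr", "kurtosis", "skewness", "rms", "adr")],
      feats$label,
      n_repeats = cfg$classify$n_repeats,
      seed = cfg$seed,
      train_fraction = cfg$classify$train_fraction,
      kernel = cfg$classify$kernel,
      cost = cfg$classify$cost,
      stratified = cfg$classify$stratified
    )
    report <- list(
      config_hash = hash, seed = cfg$seed,
      classifier = cfg$classify,
      mean_accuracy = res$mean_accuracy, sd_accuracy = res$sd_accuracy,
      n_repeats = res$n_repeats, train_size = res$train_size,
      test_size = res$test_size,
      confusion_totals = as.list(res$confusion_totals),
      per_repeat_accuracy = res$per_repeat_accuracy
    )
    write_json_file(report, file.path(out_dir, "classification_report.json"))
    emit("classification_report.json")
    log(sprintf("classification: %.1f%% +/- %.1f%%", 100 * res$mean_accuracy,
                100 * res$sd_accuracy))
  }

  if ("ephys" %in% cfg$stages) {
    log("stage ephys")
    erows <- vector("list", cfg$ephys$n_cells)
    for (i in seq_len(cfg$ephys$n_cells)) {
      base <- list(rin_mohm = cfg$ephys$rin_mohm, tau_ms = cfg$ephys$tau_ms,
                   rest_mv = cfg$ephys$rest_mv,
                   spike_threshold_mv = cfg$ephys$spike_threshold_mv,
                   noise_sd_mv = cfg$ephys$noise_sd_mv,
                   sample_interval_ms = cfg$ephys$sample_interval_ms)
      firing <- generate_sweep_family(
        do.call(cell_config, c(base, list(
          protocol = firing_protocol(),
          seed = child_seed(cfg$seed, i, stream = 201L)
        ))),
        cell_id = sprintf("cell_%02d", i)
      )
      passive <- generate_sweep_family(
        do.call(cell_config, c(base, list(
          protocol = passive_protocol(),
          seed = child_seed(cfg$seed, i, stream = 202L)
        ))),
        cell_id = sprintf("cell_%02d", i)
      )
      write_sweeps(firing,
                   file.path(out_dir, sprintf("ephys_sweeps_firing_%02d.csv", i)),
                   comment = stamp)
      write_sweeps(passive,
                   file.path(out_dir, sprintf("ephys_sweeps_passive_%02d.csv", i)),
                   comment = stamp)
      emit(sprintf("ephys_sweeps_firing_%02d.csv", i))
      emit(sprintf("ephys_sweeps_firing_%02d.json", i))
      emit(sprintf("ephys_sweeps_passive_%02d.csv", i))
      emit(sprintf("ephys_sweeps_passive_%02d.json", i))
      erows[[i]] <- extract_ephys_features(firing, passive)
    }
    write_csv_commented(do.call(rbind, erows),
                        file.path(out_dir, "ephys_features.csv"), stamp)
    emit("ephys_features.csv")
  }

  manifest <- list(
    package = "aisquant",
    version = as.character(utils::packageVersion("aisquant")),
    seed = cfg$seed,
    seed_generated = isTRUE(attr(cfg, "seed_generated")),
    config_hash = hash,
    config = unclass(cfg),
    inputs = if (is.null(cfg$paths$cohort_csv)) list() else
      list(cohort_csv = cfg$paths$cohort_csv),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs
    ))
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  log("run complete")
  invisible(manifest)
}
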