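# Readers/writers and the end-to-end pipeline runner. All gaze times are in
# ms, screen coordinates in px, derived kinematics in deg and deg/s; column
# names carry the unit suffix.

#' Read / write a gaze recording as CSV
#'
#' The on-disk format is one trial per file with header `t_ms,x_px,y_px`.
#' Malformed rows (non-numeric or incomplete) are dropped with a warning
#' reporting the count; the write/read round trip is lossless for finite
#' values.
#'
#' @param path CSV file path.
#' @param geometry a [screen_geometry()].
#' @param participant_id,trial_index recording identity.
#' @return `read_gaze_csv` returns a [gaze_recording()].
#' @export
read_gaze_csv <- function(path, geometry = screen_geometry(),
                          participant_id = "p0", trial_index = 0L) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (!all(c("t_ms", "x_px", "y_px") %in% names(raw))) {
    stop("gaze CSV must have columns t_ms, x_px, y_px")
  }
  if (nrow(raw) == 0) stop("empty gaze file: ", path)
  num <- data.frame(
    t_ms = suppressWarnings(as.numeric(raw$t_ms)),
    x_px = suppressWarnings(as.numeric(raw$x_px)),
    y_px = suppressWarnings(as.numeric(raw$y_px))
  )
  bad <- !stats::complete.cases(num)
  if (any(bad)) {
    warning(sprintf("dropped %d malformed row(s) from %s", sum(bad), path))
    num <- num[!bad, , drop = FALSE]
  }
  gaze_recording(num, geometry, participant_id, trial_index)
}

#' @rdname read_gaze_csv
#' @param recording a [gaze_recording()].
#' @export
write_gaze_csv <- function(recording, path) {
  utils::write.csv(recording$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Per-trial gaze CSVs plus a manifest JSON (participants, trials, seed) and
#' the inventory CSV `participant_id,TYa,SYa,Yy,SYi,TYi,masking`.
#'
#' @param cohort a `gaze_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (rec in cohort$recordings) {
    f <- sprintf("%s_trial%02d.csv", rec$participant_id, rec$trial_index)
    write_gaze_csv(rec, file.path(dir, f))
    files <- c(files, f)
  }
  utils::write.csv(cohort$inventory, file.path(dir, "inventory.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(participants = unique(cohort$inventory$participant_id),
         n_trials = cohort$protocol$n_trials,
         trial_duration_s = cohort$protocol$trial_duration_s,
         coupling_strength = cohort$coupling_strength,
         seed = cohort$seed,
         files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with documented defaults.
#' Any field left unspecified takes its default; the resolved configuration
#' is echoed into the output directory of [run_pipeline()].
#'
#' @param n_participants cohort size.
#' @param coupling_strength trait-to-gaze coupling in `[0,1]`.
#' @param seed master seed.
#' @param geometry a [screen_geometry()].
#' @param protocol a [stimulus_protocol()].
#' @param synth a [synth_config()].
#' @param detector list of [detect_events()] parameters.
#' @param heatmap list with `grid` and `sigma_px`.
#' @param classifiers classifier names for the benchmark.
#' @param selections named list of [selection_spec()]s.
#' @param n_folds outer CV folds.
#' @param masking_threshold masking-scale exclusion threshold.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 40L, coupling_strength = 1,
                            seed = 1L,
                            geometry = screen_geometry(),
                            protocol = stimulus_protocol(),
                            synth = synth_config(),
                            detector = list(velocity_threshold_dps = 30,
                                            min_fixation_ms = 60,
                                            min_saccade_amplitude_deg = 0.5,
                                            merge_gap_ms = 75),
                            heatmap = list(grid = c(64L, 36L), sigma_px = 30),
                            classifiers = classifier_names,
                            selections = list(
                              none = selection_spec("none"),
                              mutual_information = selection_spec("mutual_information"),
                              lasso = selection_spec("lasso")),
                            n_folds = 5L,
                            masking_threshold = 5L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields present in the file override [pipeline_config()] defaults;
#' nested `geometry`, `protocol`, `synth`, `detector` and `heatmap` blocks
#' override field-wise.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- pipeline_config()
  for (nm in intersect(names(obj),
                       c("n_participants", "coupling_strength", "seed",
                         "n_folds", "masking_threshold", "classifiers"))) {
    cfg[[nm]] <- obj[[nm]]
  }
  for (block in c("geometry", "protocol", "synth", "detector", "heatmap")) {
    if (!is.null(obj[[block]])) {
      for (nm in names(obj[[block]])) cfg[[block]][[nm]] <- obj[[block]][[nm]]
    }
  }
  cfg
}

config_hash <- function(config) {
  # stable content hash without external digest dependencies
  s <- paste(utils::capture.output(utils::str(config, give.attr = FALSE)),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the full pipeline
#'
#' Synthesizes a cohort, applies the masking-scale filter, extracts the
#' feature table, discretizes the inventory into trait labels, runs the
#' classifier x selection benchmark, and compares selection methods with a
#' Friedman test on the per-classifier accuracy matrix. All artifacts
#' (feature table, labels, benchmark grid CSV/JSON, comparison report,
#' resolved config with hash, log) are written to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return A list of class `pipeline_result` with `features`, `labels`,
#'   `benchmark`, `comparison`, `excluded` and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("fivegaze_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "pipeline.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = log_file, append = TRUE)
  }
  hash <- config_hash(config)
  logline("pipeline start, config hash %s", hash)

  cohort <- generate_cohort(config$n_participants, config$coupling_strength,
                            config$geometry, config$protocol, config$seed,
                            config$synth)
  filt <- apply_masking_filter(cohort$inventory, config$masking_threshold)
  keep <- filt$retained$participant_id
  logline("cohort: %d participants, %d excluded by masking filter",
          config$n_participants, nrow(filt$excluded))

  cohort$recordings <- Filter(function(r) r$participant_id %in% keep,
                              cohort$recordings)
  features <- extract_features(
    cohort,
    heatmap_grid = config$heatmap$grid,
    heatmap_sigma_px = config$heatmap$sigma_px,
    velocity_threshold_dps = config$detector$velocity_threshold_dps,
    min_fixation_ms = config$detector$min_fixation_ms,
    min_saccade_amplitude_deg = config$detector$min_saccade_amplitude_deg,
    merge_gap_ms = config$detector$merge_gap_ms
  )
  labels_long <- label_table(filt$retained)
  labels_by_trait <- as.data.frame(lapply(trait_names(), function(tr) {
    sub <- labels_long[labels_long$trait == tr, ]
    sub$level[match(rownames(features), sub$participant_id)]
  }))
  names(labels_by_trait) <- trait_names()

  bench <- run_benchmark(features, labels_by_trait,
                         classifiers = config$classifiers,
                         selections = config$selections,
                         n_folds = config$n_folds, seed = config$seed)
  acc <- stats::reshape(
    bench$by_method[, c("classifier", "selection", "accuracy")],
    idvar = "classifier", timevar = "selection", direction = "wide")
  m <- as.matrix(acc[, -1, drop = FALSE])
  rownames(m) <- acc$classifier
  colnames(m) <- sub("^accuracy\\.", "", colnames(m))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) >= 2 && ncol(m) >= 2) {
    comparison <- comparison_report(m, posthoc = "dunn",
                                    path = file.path(out_dir, "comparison.json"))
    logline("Friedman over selection methods: chi2 = %.3f, p = %.4f",
            comparison$friedman$statistic, comparison$friedman$p_value)
  } else {
    comparison <- NULL
    logline("comparison skipped: too few complete classifier rows")
  }

  utils::write.csv(cbind(participant_id = rownames(features),
                         as.data.frame(features)),
                   file.path(out_dir, "feature_table.csv"), row.names = FALSE)
  utils::write.csv(labels_long, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  grid_out <- bench$grid
  grid_out$config_hash <- hash
  utils::write.csv(grid_out, file.path(out_dir, "benchmark_grid.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = hash, by_method = bench$by_method, grid = bench$grid),
    file.path(out_dir, "benchmark_grid.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg_echo <- config
  cfg_echo$selections <- lapply(cfg_echo$selections, unclass)
  jsonlite::write_json(
    c(list(config_hash = hash), rapply(unclass(cfg_echo), unclass, how = "replace")),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  logline("pipeline done")

  structure(list(features = features, labels = labels_by_trait,
                 benchmark = bench, comparison = comparison,
                 excluded = filt$excluded, config_hash = hash,
                 out_dir = out_dir),
            class = "pipeline_result")
}
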