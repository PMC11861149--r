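# Workflow commands chaining the modules: simulate -> preprocess ->
# train/evaluate, driven by a YAML-able config list. These functions back
# the command-line wrapper in inst/cli/grfnet-cli.R.

#' Default run configuration
#'
#' All knobs of the end-to-end workflow with their defaults: the generator
#' (530 trials over the five speeds), the preprocessing chain (10/20 Hz
#' cutoffs, 10 N threshold, 101 points), and the evaluation (all four
#' architectures on all seven datasets, 10 folds). Values from `overrides`
#' (e.g. a parsed YAML file) replace defaults; unknown keys are rejected.
#'
#' @param overrides named list of overrides.
#' @return config list.
#' @export
default_run_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1,
    n_trials = 530,
    speeds = GAIT_SPEEDS,
    n_subjects = 12,
    generator = list(),        # gait_params() overrides
    trials_dir = "trials",
    datasets_dir = "datasets",
    reports_dir = "reports",
    force_cutoff_hz = 10,
    angle_cutoff_hz = 20,
    threshold_n = 10,
    n_points = 101,
    models = c("xlstm", "slstm", "mlstm", "lstm"),
    datasets = paste0("M", 1:7),
    K = 10,
    epochs = NULL,             # NULL = per-architecture defaults
    lr = NULL,
    speed_cases = c("M1", "M2", "M5", "M6")
  )
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, overrides)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys as in [default_run_config()].
#' @return merged config list.
#' @export
read_run_config <- function(path) {
  default_run_config(yaml::read_yaml(path))
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Generate and write a synthetic trial dataset
#'
#' @param config a [default_run_config()] list.
#' @param force overwrite an existing trial directory.
#' @return the manifest data.frame, invisibly.
#' @export
run_simulate <- function(config = default_run_config(), force = FALSE) {
  dir <- config$trials_dir
  if (file.exists(file.path(dir, "manifest.csv")) && !force) {
    stop("output ", dir, " already contains a dataset; use force = TRUE ",
         "to overwrite", call. = FALSE)
  }
  log_stage("simulate", "seed %d: %d trials at speeds {%s} km/h",
            config$seed, config$n_trials,
            paste(config$speeds, collapse = ","))
  ds <- generate_gait_dataset(
    n_trials = config$n_trials, speeds = config$speeds,
    base_params = config$generator, seed = config$seed,
    dir = dir, n_subjects = config$n_subjects)
  log_stage("simulate", "wrote %d trials + manifest to %s",
            nrow(ds$manifest), dir)
  invisible(ds$manifest)
}

#' Preprocess trials into the seven design matrices
#'
#' Reads the trial directory, runs the filter/segment/normalize chain, and
#' writes one CSV per design (metadata + features + targets) plus a JSON
#' sidecar recording the channel layouts, filter specs and threshold.
#'
#' @param config a [default_run_config()] list.
#' @return named list of `grf_design` objects, invisibly.
#' @export
run_preprocess <- function(config = default_run_config()) {
  ds <- read_gait_dataset(config$trials_dir)
  log_stage("preprocess", "read %d trials from %s", length(ds$trials),
            config$trials_dir)
  designs <- assemble_designs(
    ds$trials,
    force_filter = filter_spec(config$force_cutoff_hz, 1000),
    angle_filter = filter_spec(config$angle_cutoff_hz, 200),
    threshold_n = config$threshold_n,
    n_points = config$n_points)
  dir.create(config$datasets_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(designs)) {
    write_design(designs[[nm]], file.path(config$datasets_dir,
                                          paste0(nm, ".csv")))
  }
  sidecar <- list(
    pipeline_version = as.character(utils::packageVersion("grfnet")),
    threshold_n = config$threshold_n,
    n_points = config$n_points,
    filters = list(
      force = list(order = 4, cutoff_hz = config$force_cutoff_hz,
                   sample_rate_hz = 1000, zero_phase = TRUE),
      angles = list(order = 4, cutoff_hz = config$angle_cutoff_hz,
                    sample_rate_hz = 200, zero_phase = TRUE)
    ),
    channel_layouts = lapply(designs, function(d)
      paste(d$channel_layout$joint, d$channel_layout$plane, sep = "_")),
    n_trials_in = length(ds$trials),
    n_trials_kept = nrow(designs$M1$X)
  )
  jsonlite::write_json(sidecar, file.path(config$datasets_dir,
                                          "preprocess.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("preprocess", "kept %d/%d trials; wrote %d datasets to %s",
            sidecar$n_trials_kept, sidecar$n_trials_in, length(designs),
            config$datasets_dir)
  invisible(designs)
}

#' Write / read one design matrix as CSV
#'
#' Metadata columns (`trial_id`, `speed_kmh`, `body_mass_kg`), then the
#' flattened feature columns, then the 101 target columns.
#'
#' @param design a `grf_design`.
#' @param path CSV path.
#' @return `path` (write) or a `grf_design` (read).
#' @export
write_design <- function(design, path) {
  df <- data.frame(trial_id = design$trial_id,
                   speed_kmh = design$speed_kmh,
                   body_mass_kg = design$body_mass_kg,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(design$X), as.data.frame(design$y))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ycols <- grep("^y_pct", names(df))
  meta <- c("trial_id", "speed_kmh", "body_mass_kg")
  xcols <- setdiff(seq_along(df), c(ycols, match(meta, names(df))))
  n_points <- length(ycols)
  X <- as.matrix(df[, xcols, drop = FALSE])
  ch <- sub("_pct[0-9]+$", "", colnames(X))
  ch <- ch[!duplicated(ch)]
  parts <- strsplit(ch, "_")
  layout <- data.frame(joint = vapply(parts, `[`, "", 1),
                       plane = vapply(parts, `[`, "", 2),
                       stringsAsFactors = FALSE)
  structure(list(
    name = sub("\\.csv$", "", basename(path)),
    X = X,
    y = as.matrix(df[, ycols, drop = FALSE]),
    channel_layout = layout,
    trial_id = df$trial_id,
    speed_kmh = df$speed_kmh,
    body_mass_kg = df$body_mass_kg,
    n_points = n_points
  ), class = "grf_design")
}

#' Train and evaluate the experiment grid from written datasets
#'
#' @param config a [default_run_config()] list.
#' @return the `grf_grid` result, invisibly.
#' @export
run_train_eval <- function(config = default_run_config()) {
  paths <- file.path(config$datasets_dir, paste0(config$datasets, ".csv"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing dataset file(s): ", paste(paths[missing], collapse = ", "),
         call. = FALSE)
  }
  designs <- lapply(paths, read_design)
  names(designs) <- config$datasets
  log_stage("train-eval", "grid: %d models x %d datasets, K = %d",
            length(config$models), length(designs), config$K)
  extra <- list()
  if (!is.null(config$epochs)) extra$epochs <- config$epochs
  if (!is.null(config$lr)) extra$lr <- config$lr
  grid <- do.call(experiment_grid, c(list(
    designs = designs, architectures = config$models,
    K = config$K, seed = config$seed,
    speed_cases = intersect(config$speed_cases, config$datasets)), extra))
  dir.create(config$reports_dir, recursive = TRUE, showWarnings = FALSE)
  write_grid_report(grid, file.path(config$reports_dir, "grid_report.csv"))
  summary_json <- list(
    seed = config$seed, K = config$K,
    grid = grid$grid, per_speed = grid$per_speed)
  jsonlite::write_json(summary_json,
                       file.path(config$reports_dir, "grid_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  log_stage("train-eval", "wrote reports to %s", config$reports_dir)
  invisible(grid)
}

#' Run the full workflow: simulate, preprocess, train and evaluate
#'
#' @param config a [default_run_config()] list.
#' @param force overwrite existing outputs.
#' @return the `grf_grid` result, invisibly.
#' @export
run_reproduce <- function(config = default_run_config(), force = FALSE) {
  run_simulate(config, force = force)
  run_preprocess(config)
  run_train_eval(config)
}
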