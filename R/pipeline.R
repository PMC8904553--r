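#' Pipeline configuration
#'
#' Validated bundle of every stage's settings: the simulator (cavity model
#' and liquid panel), preprocessing (threshold), splitting (k, validation
#' fraction, group-aware flag), the classifier families to run, and the
#' master seed from which all per-stage seeds are derived. Each component is
#' validated through its own constructor before any stage runs.
#'
#' @param cavity A [cavity_model()].
#' @param panel A [liquid_panel()].
#' @param threshold Maxima-analysis threshold fraction.
#' @param k Number of cross-validation folds.
#' @param validation_fraction Held-out validation fraction.
#' @param group_by_liquid Keep replicates of a liquid together in the
#'   validation split.
#' @param classifiers Character vector of classifier families (see
#'   [classifier_spec()]).
#' @param fold_score `"holdout"` or `"train"` per-fold reporting.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cavity = cavity_model(),
                            panel = liquid_panel(),
                            threshold = 0.05,
                            k = 3L,
                            validation_fraction = 0.2,
                            group_by_liquid = FALSE,
                            classifiers = c("random-forest",
                                            "gradient-boosted-trees",
                                            "gaussian-naive-bayes",
                                            "neural-net"),
                            fold_score = "holdout",
                            seed = 1L) {
  if (!inherits(cavity, "cavity_model")) cavity <- do.call(cavity_model, cavity)
  if (!inherits(panel, "liquid_panel")) panel <- do.call(liquid_panel, panel)
  stopifnot_scalar(threshold, "threshold")
  if (threshold < 0 || threshold >= 1) {
    stop("`threshold` must lie in [0, 1)", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("`k` must be an integer >= 2", call. = FALSE)
  stopifnot_scalar(validation_fraction, "validation_fraction")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("`validation_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  classifiers <- match.arg(classifiers, classifier_families,
                           several.ok = TRUE)
  fold_score <- match.arg(fold_score, c("holdout", "train"))
  structure(
    list(cavity = cavity, panel = panel, threshold = threshold, k = k,
         validation_fraction = validation_fraction,
         group_by_liquid = isTRUE(group_by_liquid),
         classifiers = classifiers, fold_score = fold_score,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' The file mirrors the [pipeline_config()] fields with nested `cavity` and
#' `panel` sections; a configuration round-trips through serialisation
#' unchanged.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return The config (reader) or `path` invisibly (writer).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(
    list(
      cavity = unclass(config$cavity),
      panel = unclass(config$panel),
      threshold = config$threshold,
      k = config$k,
      validation_fraction = config$validation_fraction,
      group_by_liquid = config$group_by_liquid,
      classifiers = as.list(config$classifiers),
      fold_score = config$fold_score,
      seed = config$seed
    ),
    path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    cavity = raw$cavity %||% cavity_model(),
    panel = raw$panel %||% liquid_panel(),
    threshold = raw$threshold %||% 0.05,
    k = raw$k %||% 3L,
    validation_fraction = raw$validation_fraction %||% 0.2,
    group_by_liquid = raw$group_by_liquid %||% FALSE,
    classifiers = unlist(raw$classifiers %||% classifier_families),
    fold_score = raw$fold_score %||% "holdout",
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full screening pipeline
#'
#' Orchestrates all stages end to end: simulate (or load) the spectra, map
#' them to the 18-feature table, label rows by refractive index, take the
#' stratified held-out validation split, build the stratified k-fold plan,
#' train and evaluate each configured classifier, and (optionally) write
#' every artifact plus a run manifest to `out_dir`. Per-stage seeds
#' (simulation noise, splitting, classifier fitting) are derived
#' deterministically from the master seed, so a single integer reproduces
#' the whole run.
#'
#' @param config A [pipeline_config()].
#' @param input `"synthetic"` (default) to generate the study design, or a
#'   path to a spectrum manifest CSV / directory of measured spectra.
#' @param out_dir Optional output directory for spectra, `features.csv`,
#'   `plan.csv`, the `report/` directory and `run_manifest.json`.
#' @return List with the `fp_experiment` (`experiment`), the labeled
#'   dataset, the split, the fold plan and the feature table.
#' @export
run_pipeline <- function(config, input = "synthetic", out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  stage_seeds <- derive_seeds(config$seed, 3L)
  spectra <- if (identical(input, "synthetic")) {
    generate_study_design(config$panel, config$cavity, stage_seeds[1L])
  } else {
    read_study_design(input)
  }
  if (!length(spectra)) stop("no input spectra", call. = FALSE)
  features <- extract_feature_table(spectra, config$cavity, config$threshold)
  ds <- build_dataset(features)
  split <- split_validation(ds, config$validation_fraction,
                            seed = stage_seeds[2L],
                            group_by_liquid = config$group_by_liquid)
  plan <- stratified_kfold(split$train, config$k, seed = stage_seeds[2L])
  specs <- lapply(config$classifiers, function(fam) {
    classifier_spec(fam, seed = stage_seeds[3L])
  })
  experiment <- run_experiment(split$train, plan, specs, split$validation,
                               fold_score = config$fold_score)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (identical(input, "synthetic")) {
      write_study_design(spectra, file.path(out_dir, "spectra"))
    }
    write_feature_table(features, file.path(out_dir, "features.csv"))
    write_fold_plan(split, plan, nrow(features),
                    file.path(out_dir, "plan.csv"))
    write_report(experiment, file.path(out_dir, "report"))
    cfg_path <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_path)
    jsonlite::write_json(
      list(config_file = "config.yaml",
           config_md5 = unname(tools::md5sum(cfg_path)),
           seed = config$seed,
           stage_seeds = as.list(stats::setNames(
             stage_seeds, c("simulate", "split", "classify"))),
           n_spectra = length(spectra),
           n_features = nrow(features),
           package_version = as.character(utils::packageVersion("fpscreen"))),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  }
  list(experiment = experiment, dataset = ds, split = split, plan = plan,
       features = features)
}

#' Generate deterministic test fixtures
#'
#' `scale = "small"` produces 3 liquids (1.30, 1.38, 1.50) x 2 replicates on
#' a 201-point grid for fast tests; `scale = "full"` produces the complete
#' 21 x 10 study design. Regeneration with the same seed is idempotent.
#'
#' @param seed Master seed.
#' @param scale `"small"` or `"full"`.
#' @param dir Optional directory to write the spectra and manifest to.
#' @return List of [interferogram()] objects.
#' @export
generate_fixtures <- function(seed = 1L, scale = c("small", "full"),
                              dir = NULL) {
  scale <- match.arg(scale)
  if (scale == "small") {
    panel <- liquid_panel(label_indices = c(1.30, 1.38, 1.50),
                          replicates = 2L)
    model <- cavity_model(
      wavelength_grid = default_wavelength_grid(n = 201L))
  } else {
    panel <- liquid_panel()
    model <- cavity_model()
  }
  spectra <- generate_study_design(panel, model, seed)
  if (!is.null(dir)) write_study_design(spectra, dir)
  spectra
}
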