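#' Extract the full 15-feature table from a list of records
#'
#' For every record: trim to the 120-s analysis window
#' ([required_window()]), derive the RR series from the annotated beats,
#' compute the 11 HRV features, and compute the 4 QRS shape features from
#' the trimmed trace. Records that fail their window precondition are
#' excluded and reported via the `"excluded"` attribute (mirroring how
#' too-short recordings are dropped from a study), unless
#' `on_exclusion = "error"`.
#'
#' @param records A list of [ecg_record()]s (e.g. from
#'   [generate_cohort()]).
#' @param control_offset See [required_window()].
#' @param on_exclusion `"warn"` (drop the record with a warning) or
#'   `"error"`.
#' @param ... Passed to [hrv_features()].
#' @return A tibble with columns `record_id`, `label` and the 15 feature
#'   columns; excluded record ids in `attr(, "excluded")`.
#' @export
#' @examples
#' cohort <- generate_cohort(2, 2, seed = 1)
#' extract_features(cohort)
extract_features <- function(records, control_offset = 0,
                             on_exclusion = c("warn", "error"), ...) {
  on_exclusion <- match.arg(on_exclusion)
  excluded <- character()
  rows <- lapply(records, function(rec) {
    win <- tryCatch(
      required_window(rec, control_offset = control_offset),
      vf_exclusion_error = function(e) {
        if (on_exclusion == "error") stop(e)
        warn(conditionMessage(e))
        excluded <<- c(excluded, rec$record_id)
        NULL
      }
    )
    if (is.null(win)) return(NULL)
    rr <- rr_from_beats(win)
    dplyr::bind_cols(
      tibble(record_id = win$record_id, label = win$label),
      hrv_features(rr, ...),
      qrs_features(win)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  out
}

#' Per-feature group comparison table
#'
#' Welch two-tailed t-tests of every feature between the VF and control
#' rows of a feature table, with group means/SDs and the direction of the
#' difference.
#'
#' @param features A feature table from [extract_features()].
#' @param var_equal See [compare_groups_ttest()].
#' @return A tibble with one row per feature: group means and SDs,
#'   `statistic`, `p_value`, and `vf_greater` (logical).
#' @export
compare_feature_groups <- function(features, var_equal = FALSE) {
  cols <- intersect(c(hrv_feature_names(), qrs_feature_names()),
                    names(features))
  vf <- features[features$label == "VF", ]
  ct <- features[features$label == "control", ]
  rows <- lapply(cols, function(cl) {
    x <- vf[[cl]]; y <- ct[[cl]]
    tt <- compare_groups_ttest(x[is.finite(x)], y[is.finite(y)],
                               var_equal = var_equal)
    tibble(feature = cl,
           vf_mean = mean(x, na.rm = TRUE), vf_sd = sd(x, na.rm = TRUE),
           control_mean = mean(y, na.rm = TRUE),
           control_sd = sd(y, na.rm = TRUE),
           statistic = tt$statistic, p_value = tt$p_value,
           vf_greater = mean(x, na.rm = TRUE) > mean(y, na.rm = TRUE))
  })
  dplyr::bind_rows(rows)
}

#' Default pipeline configuration
#'
#' @param preset Synthetic preset, see [preset_params()].
#' @param n_vf,n_control Cohort sizes.
#' @param fs Sampling rate, Hz.
#' @param feature_sets Feature sets to evaluate.
#' @param algorithms Algorithms to evaluate.
#' @param k,repeats Cross-validation schedule.
#' @param stratified,scaler_scope See [run_experiment()].
#' @param seed Master seed for the whole run.
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @return A named list of class `vf_config`.
#' @export
pipeline_config <- function(preset = "calibrated", n_vf = 27, n_control = 28,
                            fs = 250, feature_sets = c("hrv", "qrs"),
                            algorithms = "ANN", k = 10, repeats = 10,
                            stratified = TRUE, scaler_scope = "fold",
                            seed = 1, out_dir = NULL) {
  structure(list(preset = preset, n_vf = n_vf, n_control = n_control,
                 fs = fs, feature_sets = feature_sets,
                 algorithms = algorithms, k = k, repeats = repeats,
                 stratified = stratified, scaler_scope = scaler_scope,
                 seed = seed, out_dir = out_dir),
            class = "vf_config")
}

#' Run the full simulate-extract-classify-evaluate pipeline
#'
#' End-to-end orchestration: generate a labeled cohort from the configured
#' preset, extract the feature table, run every configured (feature set,
#' algorithm) cross-validation experiment, compare the feature groups, and
#' (when `out_dir` is set) write the artifact bundle: feature table CSV
#' (display feature names), per-fold metrics CSV, summary JSON, pooled ROC
#' points CSV and a manifest recording seed, configuration and package
#' version. Identical configurations and seeds give identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `vf_run`: `features`, `group_tests`,
#'   `experiments` (named list of `vf_cv`), `summary` tibble, `manifest`.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(n_vf = 5, n_control = 5, repeats = 2))
#' run$summary
#' }
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "vf_config"))
  pp <- preset_params(config$preset)
  inform(sprintf("Generating %d VF + %d control records (preset %s, seed %d)",
                 config$n_vf, config$n_control, config$preset, config$seed))
  cohort <- generate_cohort(config$n_vf, config$n_control,
                            vf_params = pp$vf, control_params = pp$control,
                            seed = config$seed, fs = config$fs)
  features <- extract_features(cohort)
  group_tests <- compare_feature_groups(features)

  experiments <- list()
  for (fsname in config$feature_sets) {
    for (alg in config$algorithms) {
      key <- paste(alg, fsname, sep = "_")
      inform(sprintf("Cross-validating %s on the %s feature set", alg, fsname))
      experiments[[key]] <- run_experiment(
        features, feature_set = fsname, algorithm = alg, k = config$k,
        repeats = config$repeats, seed = config$seed,
        stratified = config$stratified, scaler_scope = config$scaler_scope)
    }
  }
  summary_tbl <- dplyr::bind_rows(lapply(experiments, glance))

  manifest <- list(
    seed = config$seed, config = unclass(config),
    package_version = as.character(utils::packageVersion("vfforecast")),
    excluded_records = attr(features, "excluded"),
    created = "run"
  )
  run <- structure(list(features = features, group_tests = group_tests,
                        experiments = experiments, summary = summary_tbl,
                        manifest = manifest),
                   class = "vf_run")
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- run$features
  disp <- feature_display_names()
  names(feats) <- ifelse(names(feats) %in% names(disp),
                         disp[names(feats)], names(feats))
  write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  folds <- dplyr::bind_rows(lapply(run$experiments, function(e) e$folds))
  write.csv(folds, file.path(out_dir, "cv_folds.csv"), row.names = FALSE)
  write.csv(run$summary, file.path(out_dir, "cv_summary.csv"),
            row.names = FALSE)
  roc_pts <- dplyr::bind_rows(lapply(names(run$experiments), function(nm) {
    e <- run$experiments[[nm]]
    sc <- e$scores[e$scores$repeat_id == 1, ]
    pts <- roc_auc(sc$score, sc$label)$points
    dplyr::bind_cols(tibble(experiment = nm), pts)
  }))
  write.csv(roc_pts, file.path(out_dir, "roc_points.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(run$summary, file.path(out_dir, "cv_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.vf_run <- function(x, ...) {
  cat("<vf_run>\n")
  print(x$summary)
  invisible(x)
}
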