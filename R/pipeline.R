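#' @title End-to-end pipeline orchestration
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Serializable key-value structure covering every stage: simulation, band-pass
#' corners, channel subset, epoch duration, feature methods, labeling schemes,
#' SMOTE settings, classifier grid and the master seed.
#'
#' @param ... overrides for any top-level key.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(list(
    simulation = list(n_subjects = 8, trials_per_subject = 6,
                      trial_seconds = 10, effect_size = 1, noise_sd = 2,
                      anxious_fraction = 0.5),
    band = c(4, 45),
    channels = ANXIETY_CHANNELS,
    epoch_seconds = 1,
    feature_methods = c("dwt", "psd"),
    labeling_schemes = c("sam", "hama"),
    fz_surrogate = "mean_f3_f4",
    smote_k = 5,
    train_fraction = 0.8,
    seed = 1L,
    out_dir = NULL), list(...))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  required <- c("simulation", "band", "channels", "epoch_seconds",
                "feature_methods", "labeling_schemes", "smote_k",
                "train_fraction", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing) || any(vapply(cfg[required], is.null, TRUE)))
    stop(sprintf("pipeline config missing key(s): %s",
                 paste(union(missing, required[vapply(cfg[required], is.null, TRUE)]),
                       collapse = ", ")), call. = FALSE)
  invisible(cfg)
}

#' Run the full detection pipeline
#'
#' simulate -> band-pass -> channel selection -> epoch -> label -> extract
#' features -> (SMOTE) -> train and evaluate the classifier grid. When
#' `config$out_dir` is set, feature tables (CSV), the metrics grid (CSV), the
#' evaluation reports (JSON) and a run manifest (JSON: config and seeds) are
#' written there.
#'
#' @param config a [pipeline_config()].
#' @return list with `grid`, `reports`, `features`, `labels`, `annotations`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  validate_pipeline_config(config)
  sim <- do.call(sim_config, c(config$simulation, list(seed = config$seed)))
  cohort <- simulate_cohort(sim)
  epochs <- preprocess(cohort$recordings, low = config$band[1],
                       high = config$band[2], keep = config$channels,
                       duration = config$epoch_seconds)
  labels <- lapply(stats::setNames(nm = config$labeling_schemes), function(sch)
    label_dataset(epochs, cohort$annotations, sch))
  tables <- lapply(stats::setNames(nm = config$feature_methods), function(m)
    feature_table(epochs, m, fz_surrogate = config$fz_surrogate))
  prov_cols <- c("subject_id", "trial_id", "epoch_index")
  mats <- lapply(tables, function(tb)
    as.matrix(tb[, setdiff(colnames(tb), prov_cols), drop = FALSE]))
  cmp <- run_comparison(mats, labels, train_fraction = config$train_fraction,
                        seed = config$seed, smote_k = config$smote_k)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(tables))
      utils::write.csv(tables[[m]],
                       file.path(config$out_dir, sprintf("features_%s.csv", m)),
                       row.names = FALSE)
    utils::write.csv(cmp$grid, file.path(config$out_dir, "metrics_grid.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(cmp$reports, function(r)
        list(classifier = r$classifier$name,
             hyperparameters = r$classifier$hyperparameters,
             accuracy = r$accuracy, recall_micro = r$recall_micro,
             precision_weighted = r$precision_weighted,
             confusion = as.vector(r$confusion), auc = r$auc,
             kappa = r$kappa, split_seed = r$split_seed)),
      file.path(config$out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
    manifest <- list(config = unclass(config),
                     r_version = as.character(getRversion()),
                     n_epochs = length(epochs),
                     timestamp_free = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(grid = cmp$grid, reports = cmp$reports, features = tables,
       labels = labels, annotations = cohort$annotations)
}
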