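#' Full-study pipeline configuration
#'
#' One object that fully determines every artifact of a study run:
#' synthesize -> preprocess -> extract features -> rank/select -> classify
#' (KNN and SOM) -> report. The single global `seed` fans out to the
#' per-stage seeds by fixed offsets (+0 cohort, +1 hold-out split, +2 SOM
#' init), so stages can be re-run in isolation.
#'
#' @param cohort A [cohort_spec()] (its seed is overridden by `seed`).
#' @param filter A [filter_spec()].
#' @param features A [feature_config()].
#' @param k_features Number of top-ranked features kept (default 24).
#' @param holdout_fraction KNN hold-out fraction (default 0.30).
#' @param knn_k Number of neighbours (default 10).
#' @param som_neurons,som_epochs SOM size and training length.
#' @param seed Global integer seed.
#' @return A `pd_pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(), filter = filter_spec(),
                            features = feature_config(), k_features = 24,
                            holdout_fraction = 0.30, knn_k = 10,
                            som_neurons = 3, som_epochs = 200, seed = 1) {
  structure(list(cohort = cohort, filter = filter, features = features,
                 k_features = k_features,
                 holdout_fraction = holdout_fraction, knn_k = knn_k,
                 som_neurons = som_neurons, som_epochs = som_epochs,
                 seed = as.integer(seed)),
            class = "pd_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a plain-text YAML file whose top-level keys mirror the
#' [pipeline_config()] arguments (`cohort`, `filter`, `features`,
#' `k_features`, `holdout_fraction`, `knn_k`, `som_neurons`, `som_epochs`,
#' `seed`); omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pd_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  co <- do.call(cohort_spec, y$cohort %||% list())
  fi <- do.call(filter_spec, y$filter %||% list())
  fe <- do.call(feature_config, y$features %||% list())
  pipeline_config(cohort = co, filter = fi, features = fe,
                  k_features = y$k_features %||% 24,
                  holdout_fraction = y$holdout_fraction %||% 0.30,
                  knn_k = y$knn_k %||% 10,
                  som_neurons = y$som_neurons %||% 3,
                  som_epochs = y$som_epochs %||% 200,
                  seed = y$seed %||% 1)
}

#' Run the full study pipeline
#'
#' Executes every stage on a fresh synthetic cohort and (optionally)
#' writes the artifacts to a run directory: the feature table, the ANOVA
#' ranking, the reduced table, the KNN and SOM evaluation reports with
#' confusion matrices, SOM sample-hit counts, a machine-readable
#' `summary.json` and a `run.log` recording every default in effect.
#' Recording CSVs and diagnostic figures are written only on request (they
#' are presentation, not computation, and dominate disk use). The run is a
#' pure function of the configuration: identical configs give identical
#' summaries.
#'
#' A cohort with an empty class is run as a 2-class problem with a logged
#' notice.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip all file output.
#' @param write_recordings Also write the raw and filtered recording CSVs.
#' @param write_plots Also write diagnostic figures (PNG).
#' @return Invisibly, a list with every stage result: `cohort`, `table`,
#'   `ranking`, `reduced`, `knn`, `knn_report`, `som_model`, `som`,
#'   `som_report`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         write_recordings = FALSE, write_plots = FALSE) {
  if (!inherits(config, "pd_pipeline_config"))
    abort_invalid("`config` must be a `pd_pipeline_config`.")
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  spec <- config$cohort
  spec$seed <- config$seed
  say("seed: %d (fan-out: cohort +0, split +1, SOM +2)", config$seed)
  say("cohort: %d healthy / %d tremor / %d bradykinesia; tasks %s; %g Hz, %g s",
      spec$n_healthy, spec$n_tremor, spec$n_bradykinesia,
      paste(spec$tasks, collapse = ","), spec$sampling_rate_hz,
      spec$duration_s)
  n_classes <- sum(c(spec$n_healthy, spec$n_tremor, spec$n_bradykinesia) > 0)
  if (n_classes < 3)
    say("notice: only %d non-empty classes; running a %d-class problem",
        n_classes, n_classes)

  cohort <- generate_cohort(spec)
  say("filter: Butterworth band-pass order %d, %g-%g Hz, zero_phase=%s; Hampel window 11, 3 Mads",
      config$filter$order, config$filter$low_cut_hz, config$filter$high_cut_hz,
      config$filter$zero_phase)
  filtered <- preprocess_cohort(cohort, config$filter)
  say("features: ApEn m=%d r=%g*SD; corr-dim emb=%d; Welch %d samples, %g overlap; bands %s",
      config$features$apen_m, config$features$apen_r_factor,
      config$features$cd_emb_dim, config$features$welch_segment,
      config$features$welch_overlap,
      paste(names(config$features$bands), collapse = ","))
  table <- build_feature_table(filtered, config$features)
  ranking <- anova_rank(table)
  say("selection: one-way ANOVA ranking, top k=%d features kept",
      config$k_features)
  reduced <- select_features(ranking, table, k = config$k_features)

  split <- stratified_holdout_split(reduced,
                                    holdout_fraction = config$holdout_fraction,
                                    seed = config$seed + 1L)
  say("KNN: k=%d, stratified hold-out %g (train %d / test %d), z-scored Euclidean",
      config$knn_k, config$holdout_fraction, nrow(split$train),
      nrow(split$test))
  knn <- knn_fit_predict(split$train, split$test, k = config$knn_k)
  knn_report <- evaluate(knn$true, knn$predicted,
                         scores = knn[grep("^score_", names(knn))])

  say("SOM: %d neurons, batch algorithm, %d epochs, Gaussian radius 1->0, k-means++ init",
      config$som_neurons, config$som_epochs)
  som_model <- som_fit(reduced, n_neurons = config$som_neurons,
                       epochs = config$som_epochs, seed = config$seed + 2L)
  som <- som_predict(som_model, reduced)
  som_report <- evaluate(som$true, som$predicted)

  sens <- setNames(as.list(knn_report$metrics$sensitivity),
                   paste0("knn_sensitivity_", knn_report$metrics$class))
  spc <- setNames(as.list(knn_report$metrics$specificity),
                  paste0("knn_specificity_", knn_report$metrics$class))
  summary <- c(list(
    seed = config$seed,
    n_subjects = length(unique(cohort$subject_id)),
    n_features = length(feature_names(table)),
    k_features = config$k_features,
    knn_accuracy = knn_report$accuracy,
    som_correct_count = sum(som$true == som$predicted),
    som_mse = som_model$mse), sens, spc)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(table, file.path(out_dir, "feature_table.csv"))
    readr::write_csv(tibble::as_tibble(ranking),
                     file.path(out_dir, "ranking.csv"))
    write_feature_table(reduced, file.path(out_dir, "reduced_table.csv"))
    write_eval_report(knn_report, file.path(out_dir, "knn_report.json"))
    write_eval_report(som_report, file.path(out_dir, "som_report.json"))
    readr::write_csv(as.data.frame.table(knn_report$confusion,
                                         responseName = "count"),
                     file.path(out_dir, "knn_confusion.csv"))
    readr::write_csv(as.data.frame.table(som_report$confusion,
                                         responseName = "count"),
                     file.path(out_dir, "som_confusion.csv"))
    readr::write_csv(tidy(som_model), file.path(out_dir, "som_sample_hits.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (write_recordings) {
      write_cohort(cohort, file.path(out_dir, "cohort"))
      write_cohort(filtered, file.path(out_dir, "filtered"))
    }
    if (write_plots) write_pipeline_plots(out_dir, cohort, filtered, table,
                                          ranking, knn_report, som_model)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  invisible(list(cohort = cohort, filtered = filtered, table = table,
                 ranking = ranking, reduced = reduced, split = split,
                 knn = knn, knn_report = knn_report, som_model = som_model,
                 som = som, som_report = som_report, summary = summary,
                 log = log))
}

#' Serialize an evaluation report as JSON
#'
#' @param report A [evaluate()] report.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    accuracy = report$accuracy,
    confusion = as.data.frame.table(report$confusion, responseName = "count"),
    metrics = report$metrics,
    roc = report$roc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_pipeline_plots <- function(out_dir, cohort, filtered, table, ranking,
                                 knn_report, som_model) {
  save_plot <- function(p, name) {
    grDevices::png(file.path(out_dir, name), width = 900, height = 600)
    print(p)
    grDevices::dev.off()
  }
  save_plot(autoplot(cohort$data[[1]]), "raw_first_recording.png")
  save_plot(autoplot(filtered$data[[1]]), "filtered_first_recording.png")
  save_plot(autoplot(ranking), "anova_ranking.png")
  save_plot(plot_feature_histograms(table, head(ranking$feature, 4)),
            "feature_histograms.png")
  save_plot(autoplot(knn_report), "knn_roc.png")
  save_plot(autoplot(som_model), "som_sample_hits.png")
  invisible(out_dir)
}
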