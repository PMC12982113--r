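#' Run the full treatment-response prediction stage
#'
#' Chains responder labelling, class balancing, multi-stage feature
#' selection, model-zoo evaluation and Shapley attribution of the best
#' model, writing tidy JSON/CSV outputs and a run manifest. `paper_mode`
#' moves the bootstrap oversampling before the train/test split (the
#' balance-then-split order); its scores are reported as optimistic.
#'
#' @param features feature tibble (subjects x named features) with either a
#'   `responder` column or `PSQI_pre`/`PSQI_post` columns to derive it.
#' @param config list overriding any of: `seed` (42), `k` (15), `B` (100),
#'   `freq_threshold` (0.75), `vif_threshold` (10), `corr_threshold` (0.8),
#'   `n_splits` (100), `train_fraction` (0.75), `paper_mode` (FALSE),
#'   `models`, `out_dir`.
#' @return invisibly, list with `selection` (`ms_selection_report`),
#'   `evaluation` (`ms_eval_report`), `shap` (`ms_shap` or NULL), `out_dir`.
#' @export
run_prediction_stage <- function(features, config = list()) {
  cfg <- utils::modifyList(list(
    seed = 42L, k = 15, B = 100, freq_threshold = 0.75,
    vif_threshold = 10, corr_threshold = 0.8,
    n_splits = 100, train_fraction = 0.75, paper_mode = FALSE,
    models = c("catboost", "xgb", "lr", "svm", "rf", "knn", "nb", "adaboost"),
    out_dir = tempfile("ms_predict_")
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!"responder" %in% names(features)) {
    features <- label_responders(features)
  }
  selection <- select_features(
    features, k = min(cfg$k, ncol(feature_matrix(features))),
    B = cfg$B, freq_threshold = cfg$freq_threshold,
    vif_threshold = cfg$vif_threshold, corr_threshold = cfg$corr_threshold,
    seed = cfg$seed)
  final <- selection$final_features
  if (length(final) < 2) {
    warning("fewer than 2 features survived selection; using the top ",
            "consensus candidates instead.", call. = FALSE)
    final <- utils::head(unique(unlist(selection$per_method_topk)), 2)
  }
  zoo <- model_zoo(cfg$models, seed = cfg$seed)
  evaluation <- evaluate_models(
    features, features = final, models = zoo,
    n_splits = cfg$n_splits, train_fraction = cfg$train_fraction,
    oversample = if (cfg$paper_mode) "pre" else "fold",
    seed = cfg$seed)
  shap <- NULL
  balanced <- bootstrap_oversample(features, seed = cfg$seed)
  best_fit <- fit_model_zoo(balanced, features = final,
                            models = zoo[evaluation$best_model],
                            seed = cfg$seed)[[1]]
  if (length(final) <= 14) {
    shap <- shap_summary(best_fit, features, seed = cfg$seed)
    readr::write_csv(tidy(shap), file.path(cfg$out_dir, "shap_values.csv"))
  } else {
    warning("Shapley attribution skipped: too many final features for ",
            "exact enumeration.", call. = FALSE)
  }
  readr::write_csv(evaluation$summary, file.path(cfg$out_dir, "metrics.csv"))
  jsonlite::write_json(
    list(final_features = final,
         pruned = selection$pruned,
         stability = lapply(selection$stability_freq, as.list),
         best_model = evaluation$best_model,
         oversample = evaluation$oversample,
         absent_models = evaluation$absent,
         config = cfg[setdiff(names(cfg), "models")]),
    file.path(cfg$out_dir, "selection_report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(selection = selection, evaluation = evaluation,
                 shap = shap, out_dir = cfg$out_dir))
}
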