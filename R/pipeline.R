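#' Full microstate segmentation pipeline over a set of recordings
#'
#' Chains the two-level clustering workflow: per subject, GFP peaks are
#' extracted and clustered with the polarity-invariant K-means; all subject
#' maps are pooled and re-clustered into group-level templates; the group
#' templates are canonically labelled A-D against a reference set and
#' back-fitted to every subject's GFP peaks; temporal and transition metrics
#' are computed per subject.
#'
#' @param recordings named list of average-referenced, microstate-band
#'   [ms_recording] objects (apply [microstate_prefilter()] first if needed;
#'   `prefilter = TRUE` does it here).
#' @param k number of classes (default 4).
#' @param restarts K-means restarts at both levels (default 100).
#' @param seed integer seed.
#' @param reference reference [ms_templates] for canonical A-D labelling.
#' @param min_distance_ms GFP peak separation (ms).
#' @param min_abs_corr optional back-fit correlation threshold (default 0).
#' @param prefilter apply [microstate_prefilter()] to each recording first.
#' @return list: `group_templates` ([ms_templates]), `subject_templates`
#'   (list), `sequences` (list of [ms_peak_sequence]), `metrics` (tidy
#'   tibble: subject, metric, class, value), `gev` (per-subject back-fit
#'   GEV).
#' @export
microstate_pipeline <- function(recordings, k = 4, restarts = 100, seed = 1L,
                                reference = make_template_set(),
                                min_distance_ms = 10, min_abs_corr = 0,
                                prefilter = FALSE) {
  if (is.null(names(recordings))) {
    names(recordings) <- sprintf("S%03d", seq_along(recordings))
  }
  if (prefilter) recordings <- lapply(recordings, microstate_prefilter)
  subject_templates <- vector("list", length(recordings))
  names(subject_templates) <- names(recordings)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    gfp <- compute_gfp(rec)
    peaks <- find_gfp_peaks(gfp, rec$rate, min_distance_ms)
    maps <- t(rec$data[, peaks, drop = FALSE])
    fit <- modified_kmeans(maps, k = k, restarts = restarts,
                           seed = child_seed(seed, i), gfp = gfp[peaks])
    subject_templates[[i]] <- fit$templates
  }
  group <- two_level_templates(subject_templates, k = k, restarts = restarts,
                               seed = child_seed(seed, 0L))
  group <- assign_canonical_labels(group, reference)
  sequences <- lapply(recordings, backfit_peaks, templates = group,
                      min_distance_ms = min_distance_ms,
                      min_abs_corr = min_abs_corr)
  gev <- vapply(seq_along(recordings), function(i) {
    compute_gev(sequences[[i]], compute_gfp(recordings[[i]]))
  }, numeric(1))
  names(gev) <- names(recordings)
  metrics <- purrr::map2_dfr(sequences, names(sequences), function(s, id) {
    tidy(compute_metrics(s)) |> dplyr::mutate(subject = id, .before = 1)
  })
  list(group_templates = group, subject_templates = subject_templates,
       sequences = sequences, metrics = metrics, gev = gev)
}

#' Pivot tidy per-subject metrics to a wide feature table
#'
#' Turns the long metric tibble emitted by [microstate_pipeline()] into one
#' row per subject with the standard feature names (`Duration_X`,
#' `Occurrence_X`, `Coverage_X`, `OrgTM_X->Y`), ready for the
#' response-prediction stage.
#'
#' @param metrics tidy tibble with columns `subject`, `metric`, `class`,
#'   `value`.
#' @return wide tibble, one row per subject.
#' @export
metrics_to_features <- function(metrics) {
  metrics |>
    dplyr::mutate(feature = dplyr::case_when(
      .data$metric == "coverage" ~ paste0("Coverage_", .data$class),
      .data$metric == "duration_ms" ~ paste0("Duration_", .data$class),
      .data$metric == "occurrence" ~ paste0("Occurrence_", .data$class),
      .data$metric == "orgtm" ~ paste0("OrgTM_", .data$class)
    )) |>
    dplyr::select("subject", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
}

#' Run the microstate stage of the pipeline from a config list
#'
#' Thin orchestration wrapper: simulates (or loads) a cohort, preprocesses,
#' runs [microstate_pipeline()] per condition and writes tidy CSV outputs
#' plus a JSON run manifest. Deterministic given the seeds in `config`.
#'
#' @param config list with elements `seed`, `n_hc`, `n_ci`, `duration_s`,
#'   `rate`, `restarts`, `out_dir` (see the defaults in the function).
#' @return invisibly, a list with the pipeline results per condition and the
#'   manifest path.
#' @export
run_microstate_stage <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 42L, n_hc = 6L, n_ci = 6L, n_responders = 2L,
    duration_s = 20, rate = 256, restarts = 20, k = 4,
    min_distance_ms = 10, out_dir = tempfile("ms_run_")
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, started = format(Sys.time()), warnings = list())
  spec <- cohort_spec(n_hc = cfg$n_hc, n_ci = cfg$n_ci,
                      n_responders = cfg$n_responders, seed = cfg$seed)
  sim <- simulate_cohort(spec, duration_s = cfg$duration_s, rate = cfg$rate)
  conds <- list(hc = grepl("\\.hc$", names(sim$recordings)),
                pre = grepl("\\.pre$", names(sim$recordings)),
                post = grepl("\\.post$", names(sim$recordings)))
  results <- list()
  for (cond in names(conds)) {
    recs <- sim$recordings[conds[[cond]]]
    if (length(recs) < 2) next
    results[[cond]] <- microstate_pipeline(
      recs, k = cfg$k, restarts = cfg$restarts,
      seed = child_seed(cfg$seed, match(cond, names(conds))),
      min_distance_ms = cfg$min_distance_ms)
    readr::write_csv(results[[cond]]$metrics,
                     file.path(cfg$out_dir, paste0("metrics_", cond, ".csv")))
  }
  readr::write_csv(sim$cohort, file.path(cfg$out_dir, "cohort.csv"))
  manifest$finished <- format(Sys.time())
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(results = results, cohort = sim$cohort,
                 manifest = manifest_path, out_dir = cfg$out_dir))
}
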