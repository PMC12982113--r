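#' Label treatment responders from pre/post PSQI scores
#'
#' A responder is a patient whose PSQI dropped by at least (default) the
#' threshold fraction of the baseline score: `(pre - post)/pre >=
#' threshold_fraction`. Clinical usage varies between an inclusive and a
#' strict comparator at the boundary; both are supported via `strict`.
#'
#' @param data tibble holding the score columns (piped first, tidyverse
#'   style).
#' @param psqi_pre,psqi_post column names (tidy-select) or numeric vectors
#'   when `data` is omitted.
#' @param threshold_fraction default 0.5 (a 50% reduction).
#' @param strict if `TRUE` use `>` instead of `>=` at the boundary.
#' @return `data` with a `responder` column (0/1) and an attribute `summary`
#'   (counts and percentages); or, for vector input, the labelled tibble.
#' @export
label_responders <- function(data = NULL, psqi_pre = "PSQI_pre",
                             psqi_post = "PSQI_post",
                             threshold_fraction = 0.5, strict = FALSE) {
  if (is.null(data)) {
    data <- tibble::tibble(PSQI_pre = psqi_pre, PSQI_post = psqi_post)
    psqi_pre <- "PSQI_pre"; psqi_post <- "PSQI_post"
  }
  pre <- data[[psqi_pre]]; post <- data[[psqi_post]]
  if (length(pre) != length(post)) {
    stop("pre and post score vectors differ in length.", call. = FALSE)
  }
  bad <- which(pre <= 0)
  if (length(bad)) {
    stop("non-positive baseline PSQI for subject row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reduction <- (pre - post) / pre
  lab <- if (strict) reduction > threshold_fraction
         else reduction >= threshold_fraction
  out <- dplyr::mutate(data, responder = as.integer(lab))
  n <- sum(is.finite(reduction))
  n_resp <- sum(lab, na.rm = TRUE)
  attr(out, "summary") <- tibble::tibble(
    n = n, responders = n_resp, non_responders = n - n_resp,
    responder_pct = round(100 * n_resp / n, 1),
    non_responder_pct = round(100 * (n - n_resp) / n, 1)
  )
  out
}

#' Balance classes by bootstrap oversampling of the minority class
#'
#' Resamples minority-class rows with replacement until both classes have
#' the majority count. Majority rows are untouched; a `.resampled` column
#' marks the duplicated rows. Already balanced input is returned unchanged
#' (with `.resampled = FALSE`).
#'
#' @param table tibble with a binary `responder` column.
#' @param seed integer seed.
#' @param label_col name of the label column.
#' @return balanced tibble.
#' @export
bootstrap_oversample <- function(table, seed = 42L, label_col = "responder") {
  lab <- table[[label_col]]
  tab <- table(lab)
  if (length(tab) < 2) stop("both classes must be present.", call. = FALSE)
  if (tab[1] == tab[2]) {
    return(dplyr::mutate(table, .resampled = FALSE))
  }
  minority <- names(tab)[which.min(tab)]
  deficit <- max(tab) - min(tab)
  minority_rows <- which(lab == minority)
  extra <- with_seed(seed, sample(minority_rows, deficit, replace = TRUE))
  dplyr::bind_rows(
    dplyr::mutate(table, .resampled = FALSE),
    dplyr::mutate(table[extra, ], .resampled = TRUE)
  )
}
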