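#' Back-fitted GFP peak sequence
#'
#' An `ms_peak_sequence` stores, for each retained GFP peak, its sample
#' index, the winning microstate label and the absolute spatial correlation
#' with the winning template, together with the sampling rate and total
#' sample count of the analyzed recording (needed to expand peak labels back
#' to continuous time).
#'
#' @param peak_samples strictly increasing integer sample indices.
#' @param labels character state label per peak.
#' @param abs_corr numeric in \[0, 1\] per peak.
#' @param rate sampling rate (Hz).
#' @param total_samples sample count of the analyzed recording.
#' @param state_labels the full label alphabet (classes may be absent from a
#'   particular sequence).
#' @return an object of class `ms_peak_sequence`.
#' @export
ms_peak_sequence <- function(peak_samples, labels, abs_corr, rate,
                             total_samples, state_labels = sort(unique(labels))) {
  if (is.unsorted(peak_samples, strictly = TRUE)) {
    stop("peak samples must be strictly increasing.", call. = FALSE)
  }
  if (length(labels) != length(peak_samples) ||
      length(abs_corr) != length(peak_samples)) {
    stop("labels/abs_corr must match the number of peaks.", call. = FALSE)
  }
  if (any(abs_corr < 0 | abs_corr > 1 + 1e-12)) {
    stop("abs_corr must lie in [0, 1].", call. = FALSE)
  }
  structure(list(peak_samples = as.integer(peak_samples),
                 labels = as.character(labels),
                 abs_corr = pmin(abs_corr, 1),
                 rate = rate, total_samples = as.integer(total_samples),
                 state_labels = state_labels),
            class = "ms_peak_sequence")
}

#' @export
print.ms_peak_sequence <- function(x, ...) {
  cat(sprintf("<ms_peak_sequence> %d peaks over %.1f s (%.1f peaks/s)\n",
              length(x$peak_samples), x$total_samples / x$rate,
              length(x$peak_samples) / (x$total_samples / x$rate)))
  invisible(x)
}

#' @method tidy ms_peak_sequence
#' @export
tidy.ms_peak_sequence <- function(x, ...) {
  tibble::tibble(sample = x$peak_samples,
                 time_s = (x$peak_samples - 1) / x$rate,
                 label = x$labels, abs_corr = x$abs_corr)
}

#' Back-fit templates to the GFP peaks of a recording
#'
#' Each GFP-peak map is assigned to the template with the maximum absolute
#' spatial correlation — polarity is ignored, so negating the recording
#' changes nothing. No temporal smoothing or correlation threshold is
#' applied by default; an optional `min_abs_corr` drops poorly fitting peaks
#' (leaving unassigned time).
#'
#' @param rec an [ms_recording], average referenced (2-20 Hz microstate band
#'   expected).
#' @param templates an [ms_templates].
#' @param min_distance_ms minimum GFP peak separation (ms), default 10.
#' @param min_abs_corr optional threshold in \[0,1\); peaks below it are
#'   dropped (default 0 = keep all).
#' @return an [ms_peak_sequence].
#' @export
backfit_peaks <- function(rec, templates, min_distance_ms = 10,
                          min_abs_corr = 0) {
  stopifnot(inherits(rec, "ms_recording"), inherits(templates, "ms_templates"))
  gfp <- compute_gfp(rec)
  peaks <- find_gfp_peaks(gfp, rec$rate, min_distance_ms)
  maps <- t(rec$data[, peaks, drop = FALSE])
  # drop zero-variance peak maps (spatial correlation undefined)
  keep <- apply(maps, 1, stats::sd) > 0
  if (!all(keep)) {
    message(sprintf("dropped %d zero-variance peak map(s).", sum(!keep)))
    peaks <- peaks[keep]; maps <- maps[keep, , drop = FALSE]
  }
  cc <- abs(spatial_correlation(maps, templates$maps))
  win <- max.col(cc, ties.method = "first")
  ac <- cc[cbind(seq_along(win), win)]
  if (min_abs_corr > 0) {
    keep <- ac >= min_abs_corr
    peaks <- peaks[keep]; win <- win[keep]; ac <- ac[keep]
  }
  ms_peak_sequence(peaks, templates$labels[win], ac, rec$rate,
                   ncol(rec$data), state_labels = templates$labels)
}

# Core episode bookkeeping shared by the analyzer and the ground-truth
# oracle: given consecutive episode states and durations (ms), produce the
# tidy metric table.
episode_metrics <- function(states, dur_ms, total_ms, labels) {
  # merge any consecutive duplicates defensively
  if (length(states) > 1) {
    same <- c(FALSE, states[-1] == states[-length(states)])
    if (any(same)) {
      grp <- cumsum(!same)
      dur_ms <- as.numeric(tapply(dur_ms, grp, sum))
      states <- states[!same]
    }
  }
  k <- length(labels)
  cover <- dur <- occ <- stats::setNames(numeric(k), labels)
  for (j in seq_len(k)) {
    idx <- which(states == j)
    cover[j] <- sum(dur_ms[idx]) / total_ms * 100
    dur[j] <- if (length(idx)) mean(dur_ms[idx]) else 0
    occ[j] <- length(idx) / (total_ms / 1000)
  }
  trans <- matrix(0, k, k, dimnames = list(labels, labels))
  if (length(states) > 1) {
    from <- states[-length(states)]; to <- states[-1]
    for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
  }
  n_trans <- sum(trans)
  orgtm <- if (n_trans > 0) trans / n_trans * 100 else trans
  per_class <- tibble::tibble(
    class = labels,
    coverage = as.numeric(cover),
    duration_ms = as.numeric(dur),
    occurrence = as.numeric(occ)
  )
  pairs <- expand.grid(from = labels, to = labels, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  orgtm_tbl <- tibble::tibble(
    from = pairs$from, to = pairs$to,
    orgtm = orgtm[cbind(pairs$from, pairs$to)]
  ) |> dplyr::arrange(.data$from, .data$to)
  structure(list(per_class = per_class, orgtm = orgtm_tbl,
                 n_transitions = n_trans, analyzed_s = total_ms / 1000),
            class = "ms_metrics")
}

#' Temporal and transition metrics of a back-fitted sequence
#'
#' Peak labels are expanded to continuous time by nearest-peak assignment:
#' boundaries fall at the midpoints between consecutive peaks, and the record
#' edges (before the first and after the last peak) belong to the first/last
#' peak. Maximal same-label runs define episodes, from which per-class
#' coverage (% of analyzed time), mean duration (ms), occurrence (episodes
#' per second) and the organizational transition matrix (each ordered
#' off-diagonal pair as % of all observed transitions) are computed.
#'
#' @param seq an [ms_peak_sequence] with >= 2 peaks.
#' @return an `ms_metrics` object: `per_class` tibble (class, coverage,
#'   duration_ms, occurrence), `orgtm` tibble (from, to, orgtm),
#'   `n_transitions`, `analyzed_s`. Use [tidy()] for one long tibble.
#' @export
compute_metrics <- function(seq) {
  stopifnot(inherits(seq, "ms_peak_sequence"))
  if (length(seq$peak_samples) < 2) {
    stop("need at least 2 peaks to compute metrics.", call. = FALSE)
  }
  p <- seq$peak_samples
  # continuous-time boundaries in ms; sample i occupies [i-1, i) / rate
  bounds <- c(0, (p[-length(p)] + p[-1] - 2) / 2, seq$total_samples - 1) /
    seq$rate * 1000
  seg_ms <- diff(bounds)
  idx <- match(seq$labels, seq$state_labels)
  m <- episode_metrics(idx, seg_ms,
                       total_ms = (seq$total_samples - 1) / seq$rate * 1000,
                       labels = seq$state_labels)
  if (m$n_transitions == 0) {
    message("single-label sequence: transition matrix is all zero.")
  }
  m
}

#' @export
print.ms_metrics <- function(x, ...) {
  cat(sprintf("<ms_metrics> %.1f s analyzed, %d transitions\n",
              x$analyzed_s, x$n_transitions))
  print(x$per_class)
  invisible(x)
}

#' Tidy microstate metrics into one long tibble
#'
#' @param x an `ms_metrics` object.
#' @param ... unused.
#' @return tibble with columns `metric`, `class` (or `from`/`to` pair encoded
#'   as `X->Y`), `value`.
#' @method tidy ms_metrics
#' @export
tidy.ms_metrics <- function(x, ...) {
  dplyr::bind_rows(
    x$per_class |>
      tidyr::pivot_longer(-"class", names_to = "metric", values_to = "value") |>
      dplyr::transmute(metric = .data$metric, class = .data$class,
                       value = .data$value),
    x$orgtm |>
      dplyr::transmute(metric = "orgtm",
                       class = paste0(.data$from, "->", .data$to),
                       value = .data$orgtm)
  )
}
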