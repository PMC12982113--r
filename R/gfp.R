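#' Global field power
#'
#' GFP(t) is the population standard deviation across channels of the
#' average-referenced voltages at sample t: the instantaneous strength of the
#' scalp field. Its local maxima are the moments of highest topographic
#' signal-to-noise and are where microstate clustering and back-fitting
#' operate.
#'
#' @param rec an [ms_recording]; should be average referenced (a warning or
#'   error is raised otherwise, per `strict`).
#' @param strict if `TRUE`, a non-average-referenced input is an error;
#'   otherwise a warning.
#' @return numeric vector of length `ncol(rec$data)`.
#' @export
compute_gfp <- function(rec, strict = FALSE) {
  stopifnot(inherits(rec, "ms_recording"))
  if (rec$reference != "average") {
    msg <- "recording is not average referenced; GFP assumes it is."
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  x <- rec$data
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

#' Local maxima of a GFP series
#'
#' Strict local maxima (greater than both neighbours), endpoints excluded,
#' thinned so consecutive peaks are at least `min_distance_ms` apart (the
#' larger peak wins, greedily from the largest down).
#'
#' @param gfp numeric series (length >= 3).
#' @param rate sampling rate in Hz.
#' @param min_distance_ms minimum separation between retained peaks (ms).
#' @return integer vector of peak sample indices (possibly empty).
#' @export
find_gfp_peaks <- function(gfp, rate, min_distance_ms = 10) {
  n <- length(gfp)
  if (n < 3) stop("series too short for peak picking.", call. = FALSE)
  core <- 2:(n - 1)
  is_peak <- gfp[core] > gfp[core - 1] & gfp[core] > gfp[core + 1]
  peaks <- core[is_peak]
  if (length(peaks) == 0 || min_distance_ms <= 0) return(peaks)
  min_gap <- min_distance_ms / 1000 * rate
  keep <- logical(length(peaks))
  alive <- rep(TRUE, length(peaks))
  ord <- order(gfp[peaks], decreasing = TRUE)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    too_close <- abs(peaks - peaks[i]) < min_gap
    too_close[i] <- FALSE
    alive[too_close] <- FALSE
  }
  peaks[keep]
}
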