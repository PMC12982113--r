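#' Standard resting-state preprocessing chain
#'
#' Applies, in order: polyphase resampling to `target_rate` (default 256 Hz),
#' zero-phase band-pass filtering (default 1-45 Hz, 4th-order Butterworth
#' applied forward-backward), a zero-phase band-stop notch (default 48-52 Hz)
#' for power-line interference, and optionally a peak-to-peak amplitude
#' screen on non-overlapping 2-s epochs with re-concatenation of the
#' survivors (a stand-in for manual artifact rejection; disabled by
#' default). Every step is appended to the recording history with its
#' parameters.
#'
#' @param rec an [ms_recording].
#' @param target_rate output sampling rate in Hz.
#' @param band numeric length-2 pass band (Hz); `NULL` skips.
#' @param notch numeric length-2 stop band (Hz); `NULL` skips (it is skipped
#'   automatically when it lies above the Nyquist frequency of
#'   `target_rate`... it never is at the defaults).
#' @param epoch_s epoch length for the amplitude screen (s).
#' @param reject_peak_to_peak amplitude threshold (µV); `NULL` disables the
#'   screen.
#' @param artifact_stage optional function `Recording -> Recording` run after
#'   filtering; hook for decomposition-based artifact removal on real data
#'   (identity by default).
#' @return preprocessed [ms_recording].
#' @export
standard_preprocess <- function(rec, target_rate = 256, band = c(1, 45),
                                notch = c(48, 52), epoch_s = 2,
                                reject_peak_to_peak = NULL,
                                artifact_stage = NULL) {
  stopifnot(inherits(rec, "ms_recording"))
  if (!is.null(band) && rec$rate < 2 * band[2]) {
    stop("configuration error: sampling rate below twice the band upper edge.",
         call. = FALSE)
  }
  if (rec$rate != target_rate) {
    rec <- resample_recording(rec, target_rate)
  }
  if (!is.null(band)) {
    if (target_rate < 2 * band[2]) {
      stop("configuration error: requested band infeasible at target rate.",
           call. = FALSE)
    }
    rec <- filter_recording(rec, band, type = "pass")
  }
  if (!is.null(notch)) {
    if (notch[2] < target_rate / 2) {
      rec <- filter_recording(rec, notch, type = "stop")
    }
  }
  if (!is.null(artifact_stage)) {
    rec <- artifact_stage(rec)
    rec <- ms_append_history(rec, "artifact_stage (user hook)")
  }
  if (!is.null(reject_peak_to_peak)) {
    rec <- screen_epochs(rec, epoch_s, reject_peak_to_peak)
  }
  rec
}

#' Secondary microstate-band filter and average reference
#'
#' Restricts the signal to the microstate analysis band (default 2-20 Hz,
#' zero-phase Butterworth) and re-references to the common average, after
#' which the per-sample channel mean is zero by construction.
#'
#' @param rec a preprocessed [ms_recording] with >= 2 channels.
#' @param band numeric length-2 microstate band (Hz).
#' @return band-limited, average-referenced [ms_recording].
#' @export
microstate_prefilter <- function(rec, band = c(2, 20)) {
  stopifnot(inherits(rec, "ms_recording"))
  if (nrow(rec$data) < 2) {
    stop("average reference undefined for a single channel.", call. = FALSE)
  }
  rec <- filter_recording(rec, band, type = "pass")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "average"
  ms_append_history(rec, "average reference")
}

# Zero-phase 4th-order Butterworth band-pass or band-stop across channels.
filter_recording <- function(rec, band, type = c("pass", "stop"), order = 4) {
  type <- match.arg(type)
  wn <- band / (rec$rate / 2)
  if (any(wn <= 0) || any(wn >= 1)) {
    stop("configuration error: band edges must lie inside (0, Nyquist).",
         call. = FALSE)
  }
  bf <- signal::butter(order, wn, type = if (type == "pass") "pass" else "stop")
  out <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  rec$data <- out
  rownames(rec$data) <- rec$channel_names
  ms_append_history(rec, sprintf("butterworth band-%s %g-%g Hz (order %d, zero phase)",
                                 type, band[1], band[2], order))
}

# Polyphase anti-aliased resampling (signal::resample) to a new rate.
resample_recording <- function(rec, target_rate) {
  frac <- target_rate / rec$rate
  # express as a small integer ratio
  den <- 1000
  r <- round(frac * den)
  g <- gcd(r, den)
  p <- r / g; q <- den / g
  out <- t(apply(rec$data, 1, function(ch) signal::resample(ch, p, q)))
  rec$data <- out
  rownames(rec$data) <- rec$channel_names
  rec$rate <- target_rate
  ms_append_history(rec, sprintf("resampled to %g Hz (polyphase %d/%d)",
                                 target_rate, p, q))
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

# Drop epochs whose worst-channel peak-to-peak amplitude exceeds the
# threshold; survivors are concatenated back into a continuous record.
screen_epochs <- function(rec, epoch_s, threshold) {
  len <- round(epoch_s * rec$rate)
  n_ep <- floor(ncol(rec$data) / len)
  keep <- logical(n_ep)
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1) * len + 1):(i * len)
    ptp <- max(apply(rec$data[, idx, drop = FALSE], 1,
                     function(ch) diff(range(ch))))
    keep[i] <- ptp <= threshold
  }
  cols <- unlist(lapply(which(keep), function(i) ((i - 1) * len + 1):(i * len)))
  if (length(cols) == 0) {
    stop("data error: every epoch exceeded the amplitude threshold.",
         call. = FALSE)
  }
  rec$data <- rec$data[, cols, drop = FALSE]
  ms_append_history(rec, sprintf(
    "epoch screen: kept %d/%d epochs of %g s (peak-to-peak <= %g)",
    sum(keep), n_ep, epoch_s, threshold))
}
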