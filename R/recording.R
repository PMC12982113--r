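#' EEG recording container
#'
#' An `ms_recording` bundles a channels-by-samples voltage matrix (microvolts)
#' with its sampling rate, ordered channel names, the current reference
#' (`"recorded"` or `"average"`) and an append-only processing history. It is
#' the object every preprocessing and microstate stage passes around.
#'
#' @param data numeric matrix, channels in rows, samples in columns (µV).
#' @param rate sampling rate in Hz (positive scalar).
#' @param channel_names character vector of unique 10-20 labels, one per row.
#' @param reference `"recorded"` or `"average"`.
#' @param history character vector of processing steps already applied.
#'
#' @return An object of class `ms_recording`.
#' @export
ms_recording <- function(data, rate, channel_names,
                         reference = c("recorded", "average"),
                         history = character()) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number (Hz).", call. = FALSE)
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    stop(sprintf(
      "format error: %d channel names supplied for %d data rows.",
      length(channel_names), nrow(data)
    ), call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("format error: duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("recording contains non-finite values.", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, rate = rate, channel_names = channel_names,
         reference = reference, history = as.character(history)),
    class = "ms_recording"
  )
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf(
    "<ms_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate, x$reference
  ))
  if (length(x$history)) {
    cat("history:\n")
    for (h in x$history) cat("  - ", h, "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.ms_recording <- function(x) dim(x$data)

ms_append_history <- function(rec, step) {
  rec$history <- c(rec$history, step)
  rec
}

#' Duration of a recording in seconds
#' @param rec an `ms_recording`.
#' @return scalar seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "ms_recording"))
  ncol(rec$data) / rec$rate
}

#' Tidy a recording into a long tibble
#'
#' @param x an `ms_recording`.
#' @param ... unused.
#' @return tibble with columns `channel`, `time_s`, `value_uv`.
#' @method tidy ms_recording
#' @export
tidy.ms_recording <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channel_names, times = ncol(x$data)),
    time_s = rep((seq_len(ncol(x$data)) - 1) / x$rate, each = nrow(x$data)),
    value_uv = as.vector(x$data)
  )
}

#' Write / read a recording in the matrix + sidecar dialect
#'
#' The portable plain-text dialect: voltages as a TSV matrix (channels in
#' rows, no header) beside a `<stem>_channels.tsv` sidecar holding the
#' channel table (`name`, `unit`, `x`, `y`) and a `<stem>_meta.json` with the
#' sampling rate and reference.
#'
#' @param rec an `ms_recording`.
#' @param path path of the data TSV to write (its stem names the sidecars).
#' @param montage optional montage tibble (`name`, `x`, `y`) stored in the
#'   sidecar for downstream topographic use.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `ms_recording`.
#' @export
write_recording <- function(rec, path, montage = NULL) {
  stopifnot(inherits(rec, "ms_recording"))
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- tibble::tibble(name = rec$channel_names, unit = "uV")
  if (!is.null(montage)) {
    pos <- montage[match(rec$channel_names, montage$name), c("x", "y")]
    side$x <- pos$x
    side$y <- pos$y
  }
  readr::write_tsv(side, sidecar_path(path, "channels.tsv"))
  jsonlite::write_json(
    list(rate = rec$rate, reference = rec$reference, history = rec$history),
    sidecar_path(path, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path, suffix) {
  stem <- sub("\\.[^.]*$", "", path)
  paste0(stem, "_", suffix)
}

#' @rdname write_recording
#' @param path path to the data TSV written by [write_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: recording file not found: ", path, call. = FALSE)
  }
  chan_path <- sidecar_path(path, "channels.tsv")
  meta_path <- sidecar_path(path, "meta.json")
  if (!file.exists(chan_path)) {
    stop("I/O error: channel sidecar not found: ", chan_path, call. = FALSE)
  }
  dat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(dat) <- NULL
  chans <- readr::read_tsv(chan_path, show_col_types = FALSE)
  if (!"name" %in% names(chans)) {
    stop("format error: channel sidecar lacks a `name` column.", call. = FALSE)
  }
  if (nrow(chans) != nrow(dat)) {
    stop(sprintf(
      "format error: %d channel names supplied for %d data rows.",
      nrow(chans), nrow(dat)
    ), call. = FALSE)
  }
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(rate = 256, reference = "recorded", history = character())
  }
  ms_recording(dat, rate = meta$rate, channel_names = chans$name,
               reference = meta$reference,
               history = as.character(meta$history))
}
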