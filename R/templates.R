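#' Microstate template set
#'
#' A `ms_templates` object holds K topographic maps (rows), each average
#' referenced (zero channel mean) and unit L2 norm, with class labels.
#' Template polarity is meaningless: a map and its negation describe the same
#' microstate, and every operation in the package treats them identically.
#'
#' @param maps K x channels numeric matrix.
#' @param labels character vector of K class labels (default `"A".."D"` style).
#' @param channel_names channel names, length = ncol(maps).
#' @param level `"subject"` or `"group"`.
#' @return an `ms_templates` object.
#' @export
ms_templates <- function(maps, labels = NULL, channel_names = NULL,
                         level = c("subject", "group")) {
  level <- match.arg(level)
  maps <- as.matrix(maps)
  storage.mode(maps) <- "double"
  if (is.null(labels)) labels <- LETTERS[seq_len(nrow(maps))]
  if (length(labels) != nrow(maps)) {
    stop("`labels` must have one entry per map.", call. = FALSE)
  }
  if (is.null(channel_names)) channel_names <- colnames(maps)
  maps <- normalize_maps(maps)
  dimnames(maps) <- list(labels, channel_names)
  structure(list(maps = maps, labels = as.character(labels),
                 channel_names = channel_names, level = level),
            class = "ms_templates")
}

# Remove the channel mean from each map and scale to unit L2 norm.
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) {
    stop("degenerate (all-zero) template map.", call. = FALSE)
  }
  maps / nrm
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf("<ms_templates> %d maps x %d channels (%s level): %s\n",
              nrow(x$maps), ncol(x$maps), x$level,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' @method tidy ms_templates
#' @export
tidy.ms_templates <- function(x, ...) {
  tibble::tibble(
    label = rep(x$labels, times = ncol(x$maps)),
    channel = rep(x$channel_names %||% as.character(seq_len(ncol(x$maps))),
                  each = nrow(x$maps)),
    value = as.vector(x$maps)
  )
}

#' Spatial correlation between topographic maps
#'
#' Pearson correlation across channels of average-referenced maps. For
#' zero-mean maps this is the cosine of the angle between them; microstate
#' assignment uses its absolute value (polarity-free).
#'
#' @param a,b numeric vectors (maps) or matrices with maps in rows.
#' @return correlation matrix (rows of `a` x rows of `b`), or scalar if both
#'   are vectors.
#' @export
spatial_correlation <- function(a, b) {
  va <- is.null(dim(a)); vb <- is.null(dim(b))
  a <- rbind(a); b <- rbind(b)
  a <- a - rowMeans(a); b <- b - rowMeans(b)
  a <- a / sqrt(rowSums(a^2)); b <- b / sqrt(rowSums(b^2))
  out <- tcrossprod(a, b)
  if (va && vb) out[1, 1] else out
}

#' Canonical A-D microstate archetypes on a montage
#'
#' Builds the four canonical resting-state microstate topographies as smooth
#' spatial gradients over electrode positions: A, a left-posterior to
#' right-anterior gradient; B, its left-right mirror (right-posterior to
#' left-anterior); C, a symmetric fronto-occipital gradient; D, a
#' fronto-central maximum. Maps are average referenced and unit normalized.
#' A small seeded spatial perturbation can be added (`jitter_sd > 0`) to
#' emulate between-cohort template variability; the default is the exact
#' analytic archetypes.
#'
#' @param n_channels number of channels (must match the montage).
#' @param montage tibble with `name`, `x`, `y` positions (see
#'   [montage_1020()]).
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @param jitter_sd standard deviation of the additive spatial perturbation,
#'   relative to the unit-norm map (default 0).
#' @return an `ms_templates` with labels A-D.
#' @export
make_template_set <- function(n_channels = 26, montage = montage_1020(),
                              seed = 1L, jitter_sd = 0) {
  required <- c("name", "x", "y")
  if (!all(required %in% names(montage))) {
    stop("configuration error: montage must provide name, x, y columns.",
         call. = FALSE)
  }
  if (nrow(montage) != n_channels) {
    stop(sprintf("configuration error: montage has %d channels, expected %d.",
                 nrow(montage), n_channels), call. = FALSE)
  }
  if (n_channels < 4) {
    stop("configuration error: need at least 4 channels.", call. = FALSE)
  }
  bad <- montage$name[!is.finite(montage$x) | !is.finite(montage$y)]
  if (length(bad)) {
    stop("configuration error: montage missing positions for channel(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- montage$x; y <- montage$y
  maps <- rbind(
    A = x + y,                                     # left-occipital -> right-frontal
    B = -x + y,                                    # right-occipital -> left-frontal
    C = y,                                         # symmetric fronto-occipital
    D = exp(-((x^2 + (y - 0.25)^2) / (2 * 0.35^2))) # fronto-central maximum
  )
  if (jitter_sd > 0) {
    maps <- normalize_maps(maps)
    set.seed(as.integer(seed))
    maps <- maps + matrix(stats::rnorm(length(maps), sd = jitter_sd),
                          nrow = nrow(maps))
  }
  ms_templates(maps, labels = c("A", "B", "C", "D"),
               channel_names = montage$name, level = "group")
}
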