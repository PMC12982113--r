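#' Built-in 26-channel 10-20 montage
#'
#' Planar electrode coordinates for the 26-channel layout used throughout the
#' package: the classic 10-20 positions plus fronto-central and
#' centro-parietal rows. Coordinates are a standard top-view projection with
#' the nose up: `x` runs left (negative) to right (positive), `y` posterior
#' (negative) to anterior (positive), head rim at radius 1.
#'
#' @param n_channels currently only 26 is built in.
#' @return tibble with columns `name`, `x`, `y`.
#' @export
#' @examples
#' montage_1020()
montage_1020 <- function(n_channels = 26) {
  if (n_channels != 26) {
    stop("configuration error: only the 26-channel 10-20 montage is built in.",
         call. = FALSE)
  }
  tibble::tribble(
    ~name,  ~x,     ~y,
    "Fp1",  -0.31,  0.95,
    "Fp2",   0.31,  0.95,
    "F7",   -0.81,  0.59,
    "F3",   -0.55,  0.48,
    "Fz",    0.00,  0.50,
    "F4",    0.55,  0.48,
    "F8",    0.81,  0.59,
    "FC5",  -0.78,  0.26,
    "FC1",  -0.28,  0.26,
    "FC2",   0.28,  0.26,
    "FC6",   0.78,  0.26,
    "T7",   -1.00,  0.00,
    "C3",   -0.50,  0.00,
    "C4",    0.50,  0.00,
    "T8",    1.00,  0.00,
    "CP5",  -0.78, -0.26,
    "CP1",  -0.28, -0.26,
    "CP2",   0.28, -0.26,
    "CP6",   0.78, -0.26,
    "P7",   -0.81, -0.59,
    "P3",   -0.55, -0.48,
    "Pz",    0.00, -0.50,
    "P4",    0.55, -0.48,
    "P8",    0.81, -0.59,
    "O1",   -0.31, -0.95,
    "O2",    0.31, -0.95
  )
  # Cz is the recording reference at the vertex and carries no signal of its
  # own, so it is not part of the 26 data channels.
}

#' Left-right mirror of a montage's channel labels
#'
#' Maps each electrode to its homologue across the midline (odd/even 10-20
#' suffix swap); midline channels map to themselves.
#'
#' @param montage montage tibble from [montage_1020()].
#' @return character vector: for each channel, the name of its mirror.
#' @export
mirror_channels <- function(montage) {
  nm <- montage$name
  swap_one <- function(s) {
    m <- regmatches(s, regexec("^([A-Za-z]+)([0-9]+)$", s))[[1]]
    if (length(m) == 0) return(s)           # midline (Fz, Cz, Pz, ...)
    num <- as.integer(m[3])
    paste0(m[2], if (num %% 2 == 1) num + 1 else num - 1)
  }
  out <- vapply(nm, swap_one, character(1))
  missing <- setdiff(out, nm)
  if (length(missing)) {
    stop("configuration error: montage lacks mirror channels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unname(out)
}
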