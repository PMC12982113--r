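#' Ground truth for synthetic microstate EEG
#'
#' Bundles everything the simulator needs: the K true topographies, the
#' conditional next-state transition matrix (row stochastic, zero diagonal),
#' per-state mean dwell times, the signal-to-noise ratio (RMS of the
#' microstate signal over RMS of the spatially white sensor noise) and the
#' carrier frequency of the underlying oscillation (10 Hz by default,
#' matching eyes-closed alpha dominance).
#'
#' @param templates an [ms_templates] (defaults to the canonical archetypes).
#' @param transition_matrix K x K row-stochastic matrix with zero diagonal;
#'   default uniform over the other states.
#' @param mean_dwell_ms positive per-state mean dwell times (ms); recycled.
#' @param snr positive amplitude ratio signal RMS / noise RMS.
#' @param carrier_hz oscillation frequency of the activation waveform.
#' @param seed integer seed governing all simulator randomness.
#' @return an object of class `ms_ground_truth`.
#' @export
ground_truth <- function(templates = make_template_set(),
                         transition_matrix = NULL,
                         mean_dwell_ms = 70, snr = 2, carrier_hz = 10,
                         seed = 1L) {
  k <- nrow(templates$maps)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k)
    diag(transition_matrix) <- 0
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (any(diag(transition_matrix) != 0)) {
    stop("transition matrix must have an exactly zero diagonal.", call. = FALSE)
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    stop("transition matrix rows must each sum to 1.", call. = FALSE)
  }
  if (any(transition_matrix < 0)) {
    stop("transition probabilities must be nonnegative.", call. = FALSE)
  }
  mean_dwell_ms <- rep_len(mean_dwell_ms, k)
  if (any(mean_dwell_ms <= 0)) stop("mean_dwell_ms must be > 0.", call. = FALSE)
  if (snr <= 0) stop("snr must be > 0.", call. = FALSE)
  cc <- abs(spatial_correlation(templates$maps, templates$maps))
  diag(cc) <- 0
  if (max(cc) >= 0.9) {
    stop("templates are not mutually distinct (max |spatial correlation| >= 0.9).",
         call. = FALSE)
  }
  dimnames(transition_matrix) <- list(templates$labels, templates$labels)
  structure(
    list(templates = templates, transition_matrix = transition_matrix,
         mean_dwell_ms = stats::setNames(mean_dwell_ms, templates$labels),
         snr = snr, carrier_hz = carrier_hz, seed = as.integer(seed)),
    class = "ms_ground_truth"
  )
}

#' @export
print.ms_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ms_ground_truth> %d states (%s); dwell %s ms; snr %g; carrier %g Hz\n",
    nrow(x$templates$maps), paste(x$templates$labels, collapse = ","),
    paste(signif(x$mean_dwell_ms, 3), collapse = "/"), x$snr, x$carrier_hz
  ))
  invisible(x)
}

#' Simulate a Markov microstate label sequence
#'
#' Draws a piecewise-constant state sequence: segment lengths come from a
#' gamma distribution with shape 2 and the per-state mean dwell (scale =
#' mean/2), successors from the conditional transition matrix, so no two
#' consecutive segments share a label.
#'
#' @param truth an `ms_ground_truth`.
#' @param duration_s length of the sequence in seconds (>= 1).
#' @param rate sampling rate in Hz (>= 100).
#' @param seed integer seed (defaults to the truth's own seed).
#' @return integer vector of state indices, one per sample, with the state
#'   labels as a `labels` attribute.
#' @export
simulate_state_sequence <- function(truth, duration_s, rate,
                                    seed = truth$seed) {
  stopifnot(inherits(truth, "ms_ground_truth"))
  if (duration_s < 1) stop("duration_s must be >= 1 s.", call. = FALSE)
  if (rate < 100) stop("rate must be >= 100 Hz.", call. = FALSE)
  P <- truth$transition_matrix
  if (any(rowSums(P) == 0)) {
    stop("configuration error: degenerate transition row (all zero).",
         call. = FALSE)
  }
  k <- nrow(P)
  n <- round(duration_s * rate)
  with_seed(seed, {
    # draw segments until the requested duration is covered
    states <- integer(0); lens <- numeric(0)
    s <- sample.int(k, 1)
    total <- 0
    while (total < duration_s * 1000) {
      len <- stats::rgamma(1, shape = 2, scale = truth$mean_dwell_ms[s] / 2)
      states <- c(states, s); lens <- c(lens, len)
      total <- total + len
      s <- sample.int(k, 1, prob = P[s, ])
    }
    edges <- round(cumsum(lens) / 1000 * rate)
    labels <- integer(n)
    start <- 1L
    for (i in seq_along(states)) {
      stop_i <- min(n, edges[i])
      if (stop_i >= start) labels[start:stop_i] <- states[i]
      start <- stop_i + 1L
      if (start > n) break
    }
    if (start <= n) labels[start:n] <- states[length(states)]
    # rounding can occasionally produce zero-length segments; labels remain
    # piecewise constant by construction
    attr(labels, "labels") <- truth$templates$labels
    labels
  })
}

#' Synthesize a multichannel recording from a state sequence
#'
#' The active template is modulated by a sinusoidal carrier (random phase and
#' log-normal amplitude per segment), producing global field power peaks
#' around twice per carrier cycle; spatially white Gaussian sensor noise is
#' added and scaled so that RMS(signal)/RMS(noise) equals the ground truth
#' `snr` (on the average-referenced signal). `snr = Inf` gives a noiseless
#' recording.
#'
#' @param truth an `ms_ground_truth`.
#' @param state_seq integer state index per sample (from
#'   [simulate_state_sequence()]).
#' @param rate sampling rate in Hz.
#' @param seed integer seed (defaults to the truth's seed offset by one so a
#'   sequence/recording pair drawn from the same truth is jointly seeded).
#' @return an [ms_recording], average referenced.
#' @export
synthesize_recording <- function(truth, state_seq, rate,
                                 seed = child_seed(truth$seed, 1L)) {
  stopifnot(inherits(truth, "ms_ground_truth"))
  n <- length(state_seq)
  if (n == 0) stop("state_seq must be nonempty.", call. = FALSE)
  maps <- truth$templates$maps
  nch <- ncol(maps)
  t_s <- (seq_len(n) - 1) / rate
  with_seed(seed, {
    # segment boundaries of the label sequence
    runs <- rle(as.integer(state_seq))
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    phase <- stats::runif(length(runs$values), 0, 2 * pi)
    amp <- stats::rlnorm(length(runs$values), meanlog = 0, sdlog = 0.3)
    activation <- numeric(n)
    for (i in seq_along(runs$values)) {
      idx <- starts[i]:ends[i]
      activation[idx] <- amp[i] *
        sin(2 * pi * truth$carrier_hz * t_s[idx] + phase[i])
    }
    sig <- maps[as.integer(state_seq), , drop = FALSE] * activation
    sig <- t(sig)                       # channels x samples
    if (is.finite(truth$snr)) {
      noise <- matrix(stats::rnorm(nch * n), nch, n)
      noise <- noise - rep(colMeans(noise), each = nch)  # average reference
      scale <- sqrt(mean(sig^2)) / (truth$snr * sqrt(mean(noise^2)))
      sig <- sig + scale * noise
    }
    ms_recording(sig, rate = rate,
                 channel_names = truth$templates$channel_names,
                 reference = "average",
                 history = sprintf("synthesized (carrier %g Hz, snr %g)",
                                   truth$carrier_hz, truth$snr))
  })
}

#' Microstate metrics of a known label sequence
#'
#' Computes coverage, duration, occurrence and the organizational transition
#' matrix directly from a per-sample ground-truth label sequence; used as the
#' oracle against which the analyzer's recovered metrics are compared.
#'
#' @param state_seq integer per-sample state sequence with a `labels`
#'   attribute (from [simulate_state_sequence()]).
#' @param rate sampling rate in Hz.
#' @param labels state labels (defaults to the sequence's attribute).
#' @return tidy tibble as from [compute_metrics()].
#' @export
true_sequence_metrics <- function(state_seq, rate,
                                  labels = attr(state_seq, "labels")) {
  runs <- rle(as.integer(state_seq))
  episode_metrics(runs$values, runs$lengths / rate * 1000,
                  total_ms = length(state_seq) / rate * 1000,
                  labels = labels)
}
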