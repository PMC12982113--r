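#' Specification of a synthetic clinical cohort
#'
#' Defines the study design the simulator emulates: a healthy-control (HC)
#' group and a chronic-insomnia (CI) group assessed before and after
#' treatment, with planted group effects on microstate dynamics, a planted
#' pre-to-post PSQI improvement, and planted baseline-feature differences
#' between treatment responders and non-responders.
#'
#' Group effects act on dwell means and transition probabilities (rows are
#' re-normalized), never on the topographies themselves: group template maps
#' are indistinguishable by design, only their temporal dynamics differ.
#'
#' @param n_hc,n_ci subject counts (>= 2 each).
#' @param n_responders number of CI subjects planted as treatment responders.
#' @param group_effects list with `dwell_mult` (named per-state multipliers
#'   applied to CI dwell means) and `transition_mult` (named `"X->Y"`
#'   multipliers applied to CI transition probabilities before row
#'   re-normalization).
#' @param responder_dwell_mult named per-state multipliers applied on top of
#'   the CI effects for planted responders at baseline (the planted
#'   feature-response association).
#' @param reversal_responder,reversal_nonresponder fraction of the CI group
#'   effect undone after treatment for responders / non-responders.
#' @param psqi_range inclusion range for the CI baseline PSQI.
#' @param truth base [ground_truth()] shared by all subjects.
#' @param seed integer master seed.
#' @return an object of class `ms_cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 19, n_ci = 41, n_responders = 14,
                        group_effects = list(
                          dwell_mult = c(A = 1.06, B = 0.89, C = 1.04, D = 0.88),
                          transition_mult = c("A->C" = 1.45, "B->D" = 0.68)
                        ),
                        responder_dwell_mult = c(A = 1.12, B = 0.92),
                        reversal_responder = 0.8,
                        reversal_nonresponder = 0.2,
                        psqi_range = c(5, 16),
                        truth = ground_truth(),
                        seed = 1L) {
  if (n_hc < 2 || n_ci < 2) stop("need at least 2 subjects per group.",
                                 call. = FALSE)
  if (n_responders < 0 || n_responders > n_ci) {
    stop("n_responders must lie in [0, n_ci].", call. = FALSE)
  }
  if (!is.null(group_effects$dwell_mult) && any(group_effects$dwell_mult <= 0)) {
    stop("configuration error: dwell multipliers must be positive.",
         call. = FALSE)
  }
  if (!is.null(group_effects$transition_mult) &&
      any(group_effects$transition_mult < 0)) {
    stop("configuration error: transition multipliers must be nonnegative.",
         call. = FALSE)
  }
  structure(list(n_hc = n_hc, n_ci = n_ci, n_responders = n_responders,
                 group_effects = group_effects,
                 responder_dwell_mult = responder_dwell_mult,
                 reversal_responder = reversal_responder,
                 reversal_nonresponder = reversal_nonresponder,
                 psqi_range = psqi_range, truth = truth,
                 seed = as.integer(seed)),
            class = "ms_cohort_spec")
}

# Apply dwell/transition effects to a base ground truth, scaled by `strength`
# in [0, 1] (1 = full effect). Returns a new ground truth.
apply_group_effects <- function(truth, effects, strength = 1,
                                extra_dwell_mult = NULL) {
  dwell <- truth$mean_dwell_ms
  if (!is.null(effects$dwell_mult)) {
    m <- effects$dwell_mult[names(dwell)]
    m[is.na(m)] <- 1
    dwell <- dwell * m^strength
  }
  if (!is.null(extra_dwell_mult)) {
    m <- extra_dwell_mult[names(dwell)]
    m[is.na(m)] <- 1
    dwell <- dwell * m
  }
  P <- truth$transition_matrix
  if (!is.null(effects$transition_mult) && length(effects$transition_mult)) {
    for (nm in names(effects$transition_mult)) {
      ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
      P[ft[1], ft[2]] <- P[ft[1], ft[2]] * effects$transition_mult[[nm]]^strength
    }
    P <- P / rowSums(P)
  }
  ground_truth(templates = truth$templates, transition_matrix = P,
               mean_dwell_ms = dwell, snr = truth$snr,
               carrier_hz = truth$carrier_hz, seed = truth$seed)
}

#' Simulate a synthetic clinical cohort
#'
#' Emits a clinical table (one row per subject with demographics, pre/post
#' scale scores and the planted responder flag), a per-subject/condition
#' ground-truth list, and — when `duration_s > 0` — the synthetic recordings
#' themselves. HC recordings are drawn from the base ground truth, CI
#' baseline recordings from the truth perturbed by the group effects (plus
#' the planted responder effects), and CI post-treatment recordings with the
#' group effects partially reversed (more so for responders). The emitted
#' PSQI columns are consistent with the planted responder labels under the
#' fractional-reduction responder rule, under both the `>=` and the strict
#' `>` comparator.
#'
#' @param spec an [cohort_spec()].
#' @param duration_s recording length in seconds (0 skips signal synthesis).
#' @param rate sampling rate in Hz.
#' @return list with `cohort` (tibble), `truths` (named list of
#'   `ms_ground_truth` keyed `subject_id.condition`), and `recordings`
#'   (named list of [ms_recording], possibly empty).
#' @export
simulate_cohort <- function(spec, duration_s = 150, rate = 256) {
  stopifnot(inherits(spec, "ms_cohort_spec"))
  n <- spec$n_hc + spec$n_ci
  ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c("HC", "CI"), c(spec$n_hc, spec$n_ci))
  cohort <- with_seed(spec$seed, {
    responder <- rep(NA, n)
    ci_idx <- which(group == "CI")
    responder[ci_idx] <- 0
    responder[sample(ci_idx, spec$n_responders)] <- 1
    age <- round(ifelse(group == "HC", stats::rnorm(n, 34.9, 8.3),
                        stats::rnorm(n, 34.6, 11.7)))
    age <- pmax(age, 18)
    sex <- ifelse(stats::runif(n) < 0.43, "M", "F")
    edu <- round(ifelse(group == "HC", stats::rnorm(n, 16.8, 2.4),
                        stats::rnorm(n, 16.4, 2.3)))
    psqi_pre <- ifelse(
      group == "HC",
      pmax(0, pmin(8, round(stats::rnorm(n, 4, 1.5)))),
      pmax(spec$psqi_range[1],
           pmin(spec$psqi_range[2], round(stats::rnorm(n, 13, 1.5))))
    )
    psqi_post <- rep(NA_real_, n)
    for (i in ci_idx) {
      if (responder[i] == 1) {
        frac <- stats::runif(1, 0.55, 0.8)
        post <- round(psqi_pre[i] * (1 - frac))
        # keep strictly above the 50% reduction boundary
        while (psqi_pre[i] - post <= psqi_pre[i] / 2) post <- post - 1
        psqi_post[i] <- max(post, 0)
      } else {
        frac <- stats::runif(1, 0.08, 0.42)
        post <- round(psqi_pre[i] * (1 - frac))
        # keep strictly below the boundary
        while (psqi_pre[i] - post >= psqi_pre[i] / 2) post <- post + 1
        psqi_post[i] <- post
      }
    }
    scale_change <- function(pre_mean, pre_sd, drop_mean, drop_sd) {
      pre <- stats::rnorm(n, pre_mean, pre_sd)
      drop <- pmax(0, stats::rnorm(n, drop_mean, drop_sd))
      list(pre = round(ifelse(group == "CI", pre, NA), 1),
           post = round(ifelse(group == "CI", pre - drop, NA), 1))
    }
    isi <- scale_change(16.9, 4.7, 5.9, 2.0)
    has <- scale_change(40.7, 9.0, 4.4, 1.8)
    fss <- scale_change(47.1, 9.6, 6.9, 2.5)
    hamd <- scale_change(10.2, 3.0, 3.3, 1.4)
    hama <- scale_change(9.7, 2.5, 2.8, 1.3)
    tibble::tibble(
      subject_id = ids, group = group, age = age, sex = sex,
      education_years = edu,
      PSQI_pre = psqi_pre, PSQI_post = psqi_post,
      ISI_pre = isi$pre, ISI_post = isi$post,
      HAS_pre = has$pre, HAS_post = has$post,
      FSS_pre = fss$pre, FSS_post = fss$post,
      HAMD_pre = hamd$pre, HAMD_post = hamd$post,
      HAMA_pre = hama$pre, HAMA_post = hama$post,
      responder = responder
    )
  })
  truths <- list()
  recordings <- list()
  for (i in seq_len(n)) {
    id <- cohort$subject_id[i]
    if (cohort$group[i] == "HC") {
      conds <- "hc"
      tr <- list(hc = spec$truth)
    } else {
      extra <- if (cohort$responder[i] == 1) spec$responder_dwell_mult else NULL
      rev_frac <- if (cohort$responder[i] == 1) spec$reversal_responder
                  else spec$reversal_nonresponder
      tr <- list(
        pre  = apply_group_effects(spec$truth, spec$group_effects, 1, extra),
        post = apply_group_effects(spec$truth, spec$group_effects,
                                   1 - rev_frac, extra)
      )
      conds <- c("pre", "post")
    }
    for (cond in conds) {
      key <- paste(id, cond, sep = ".")
      truths[[key]] <- tr[[cond]]
      if (duration_s > 0) {
        sseed <- child_seed(spec$seed, 7L * i + match(cond, c("hc", "pre", "post")))
        seq_i <- simulate_state_sequence(tr[[cond]], duration_s, rate,
                                         seed = sseed)
        recordings[[key]] <- synthesize_recording(tr[[cond]], seq_i, rate,
                                                  seed = child_seed(sseed, 1L))
      }
    }
  }
  list(cohort = cohort, truths = truths, recordings = recordings)
}

#' Synthesize a labelled feature table with planted effects
#'
#' Builds the ML test bed: `n_pos` responders and `n_neg` non-responders
#' with a handful of informative features (Gaussian with the stated
#' standardized class-mean separation) among independent Normal(0,1) noise
#' features. Column names reuse the microstate metric vocabulary
#' (`Duration_X`, `Occurrence_X`, `Coverage_X`, `OrgTM_X->Y`).
#'
#' @param n_pos,n_neg class sizes (>= 2).
#' @param effect_sizes named numeric vector: per informative feature, the
#'   standardized mean difference (positive class minus negative class).
#'   Unnamed vectors are given metric-vocabulary names automatically.
#' @param n_noise_features number of additional pure-noise features.
#' @param seed integer seed.
#' @return tibble with `subject_id`, `responder` (0/1) and one column per
#'   feature.
#' @export
synthesize_feature_table <- function(n_pos, n_neg, effect_sizes = numeric(0),
                                     n_noise_features = 10, seed = 1L) {
  if (n_pos < 2 || n_neg < 2) stop("need >= 2 subjects per class.",
                                   call. = FALSE)
  if (any(!is.finite(effect_sizes))) stop("effect sizes must be finite.",
                                          call. = FALSE)
  vocab <- feature_vocabulary()
  n_inf <- length(effect_sizes)
  if (n_inf > 0 && is.null(names(effect_sizes))) {
    names(effect_sizes) <- vocab[seq_len(n_inf)]
  }
  noise_names <- setdiff(vocab, names(effect_sizes))
  if (n_noise_features > length(noise_names)) {
    noise_names <- c(noise_names,
                     sprintf("Noise_%d", seq_len(n_noise_features - length(noise_names))))
  }
  noise_names <- noise_names[seq_len(n_noise_features)]
  n <- n_pos + n_neg
  label <- rep(c(1, 0), c(n_pos, n_neg))
  with_seed(seed, {
    inf <- matrix(stats::rnorm(n * n_inf), n, n_inf)
    if (n_inf > 0) {
      inf <- inf + outer(label, unname(effect_sizes))
    }
    noise <- matrix(stats::rnorm(n * n_noise_features), n, n_noise_features)
    out <- cbind(inf, noise)
    colnames(out) <- c(names(effect_sizes), noise_names)
    tibble::as_tibble(out) |>
      dplyr::mutate(subject_id = sprintf("P%03d", seq_len(n)),
                    responder = label, .before = 1)
  })
}

# Canonical feature name vocabulary: 4 classes x 3 temporal metrics plus the
# 12 ordered transition pairs.
feature_vocabulary <- function(classes = c("A", "B", "C", "D")) {
  pairs <- expand.grid(from = classes, to = classes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[order(pairs$from, pairs$to), ]
  c(paste0("Duration_", classes), paste0("Occurrence_", classes),
    paste0("Coverage_", classes),
    paste0("OrgTM_", pairs$from, "->", pairs$to))
}
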