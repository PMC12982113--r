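#' Assemble a tidy statistical result row
#'
#' All group-level tests in the package return rows of this shape so results
#' bind into one tidy table mirroring a clinical results section.
#'
#' @noRd
stat_row <- function(test_name, effect_name, statistic, df, p_raw,
                     family_size = 1, adjustment = c("bonferroni", "none"),
                     group_summaries = NA_character_) {
  adjustment <- match.arg(adjustment)
  p_adj <- if (adjustment == "bonferroni") pmin(1, p_raw * family_size) else p_raw
  tibble::tibble(
    test = test_name, effect = effect_name,
    statistic = statistic, df = df,
    p_raw = p_raw, p_adjusted = p_adj,
    adjustment = adjustment, family_size = family_size,
    group_summaries = group_summaries
  )
}

# mean ± SD or median (IQR) string, gated on Shapiro-Wilk normality.
describe_sample <- function(x, normal = NULL) {
  if (is.null(normal)) normal <- shapiro_ok(x)
  if (normal) {
    sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  } else {
    sprintf("%.2f (%.2f)", stats::median(x), stats::IQR(x))
  }
}

shapiro_ok <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(unique(x)) < 3) return(TRUE)
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  stats::shapiro.test(x)$p.value >= alpha
}

#' Topographic analysis of variance (TANOVA) by permutation
#'
#' Nonparametric test for differences between group-level microstate
#' topographies. Per class, each group is summarized by the polarity-free
#' principal orientation of its subject maps; the observed statistic is the
#' mean over group pairs of the global map dissimilarity `1 - |Pearson
#' correlation|` between these normalized group maps. The null is built by permuting group
#' membership `n_perm` times; `p = (1 + #(null >= observed)) / (1 + n_perm)`,
#' Bonferroni-adjusted over classes.
#'
#' @param group_maps named list (one element per group) of lists/matrices of
#'   per-subject maps for one class, or — more conveniently — a list of
#'   per-group matrices `subjects x channels` when testing a single class.
#'   Use [tanova_by_class()] to run all classes of a template list.
#' @param n_perm number of permutations (warning below 100).
#' @param seed integer seed.
#' @param class_label label recorded in the result row.
#' @param family_size Bonferroni family (default 1; `tanova_by_class` uses
#'   the class count).
#' @return one-row tidy result tibble (see [stat_row] fields).
#' @export
tanova_permutation <- function(group_maps, n_perm = 999, seed = 1L,
                               class_label = "map", family_size = 1) {
  if (length(group_maps) < 2) stop("need >= 2 groups.", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value.")
  sizes <- vapply(group_maps, nrow, integer(1))
  if (any(sizes < 2)) stop("every group needs >= 2 subjects.", call. = FALSE)
  all_maps <- normalize_maps(do.call(rbind, group_maps))
  grp <- rep(seq_along(group_maps), sizes)
  obs <- tanova_statistic(all_maps, grp)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      tanova_statistic(all_maps, sample(grp))
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  stat_row("TANOVA (permutation)", class_label, obs, NA_real_, p,
           family_size = family_size)
}

# Mean pairwise dissimilarity between group representative maps. Each
# group's representative is the dominant eigenvector of its maps' outer
# products (the polarity-free principal orientation), so the statistic is
# invariant to subject order and per-subject map sign.
tanova_statistic <- function(maps, grp) {
  groups <- sort(unique(grp))
  means <- lapply(groups, function(g) {
    m <- maps[grp == g, , drop = FALSE]
    ev <- eigen(crossprod(m), symmetric = TRUE)
    ev$vectors[, 1]
  })
  pairs <- utils::combn(length(groups), 2)
  mean(apply(pairs, 2, function(pr) {
    1 - abs(sum(means[[pr[1]]] * means[[pr[2]]]))
  }))
}

#' TANOVA over all classes of per-subject template sets
#'
#' @param template_sets_by_group named list: per group, a list of subject
#'   [ms_templates] (canonically labelled so class rows align).
#' @param n_perm,seed as in [tanova_permutation()].
#' @return tidy tibble, one row per class, Bonferroni family = class count.
#' @export
tanova_by_class <- function(template_sets_by_group, n_perm = 999, seed = 1L) {
  labels <- template_sets_by_group[[1]][[1]]$labels
  purrr::map_dfr(seq_along(labels), function(j) {
    gm <- lapply(template_sets_by_group, function(subjects) {
      do.call(rbind, lapply(subjects, function(s) s$maps[j, ]))
    })
    tanova_permutation(gm, n_perm = n_perm, seed = child_seed(seed, j),
                       class_label = labels[j], family_size = length(labels))
  })
}

#' Mixed two-way (group x class) ANOVA on a microstate metric
#'
#' Mixed-design ANOVA with group as the between-subject factor and
#' microstate class as the within-subject factor, run separately per metric:
#' the classical expected-mean-squares F tests (between error = subjects
#' within groups; within error = class x subject interaction). No sphericity
#' correction is applied by default.
#'
#' @param data tibble with columns `subject`, `group`, `class`, `value`
#'   (complete: every subject measured in every class).
#' @param sphericity_correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return tidy tibble with rows for the group main effect, class main
#'   effect and interaction.
#' @export
metric_anova <- function(data, sphericity_correction = c("none", "greenhouse-geisser")) {
  sphericity_correction <- match.arg(sphericity_correction)
  data <- dplyr::mutate(data,
                        subject = factor(.data$subject),
                        group = factor(.data$group),
                        class = factor(.data$class))
  counts <- dplyr::count(data, .data$subject, .data$class)
  full <- table(data$subject, data$class)
  if (any(full != 1)) {
    bad <- rownames(full)[rowSums(full != 1) > 0]
    stop("missing or duplicated cells for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (stats::var(data$value) == 0) {
    return(tibble::tibble(
      test = "mixed ANOVA", effect = c("group", "class", "group:class"),
      statistic = 0, df = NA_real_, p_raw = 1, p_adjusted = 1,
      adjustment = "none", family_size = 1,
      group_summaries = "zero-variance input: no effect"
    ))
  }
  fit <- stats::aov(value ~ group * class + Error(subject / class),
                    data = data)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: subject:class"]][[1]])
  get_row <- function(tbl, name) {
    i <- which(trimws(rownames(tbl)) == name)
    tbl[i, , drop = FALSE]
  }
  rows <- list(
    group = get_row(between, "group"),
    class = get_row(within, "class"),
    `group:class` = get_row(within, "group:class")
  )
  eps <- 1
  if (sphericity_correction == "greenhouse-geisser") {
    eps <- gg_epsilon(data)
  }
  purrr::map_dfr(names(rows), function(nm) {
    r <- rows[[nm]]
    err <- if (nm == "group") get_row(between, "Residuals")
           else get_row(within, "Residuals")
    Fv <- r[["F value"]]
    df1 <- r[["Df"]]; df2 <- err[["Df"]]
    adj <- if (nm == "group") 1 else eps
    p <- stats::pf(Fv, df1 * adj, df2 * adj, lower.tail = FALSE)
    stat_row("mixed ANOVA", nm, Fv, df1, p, adjustment = "none")
  })
}

# Greenhouse-Geisser epsilon: eigenvalue form on the double-centered
# within-subject covariance matrix.
gg_epsilon <- function(data) {
  wide <- tidyr::pivot_wider(data, id_cols = c("subject", "group"),
                             names_from = "class", values_from = "value")
  Y <- as.matrix(wide[, -(1:2)])
  S <- stats::cov(Y)
  k <- ncol(S)
  Sc <- sweep(S, 1, rowMeans(S))
  Sc <- sweep(Sc, 2, colMeans(S))
  Sc <- Sc + mean(S)
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Pairwise post-hoc comparisons with a normality gate
#'
#' For each requested contrast, runs a paired or unpaired two-sample test:
#' Student's t when Shapiro-Wilk accepts normality (of the paired
#' differences, or of both groups), otherwise the Wilcoxon signed-rank /
#' Mann-Whitney test. Bonferroni adjustment over `family_size`. A rank-based
#' Dunn-style backend (`backend = "dunn"`: rank-sum z tests on the pooled
#' ranks) is available as an alternative.
#'
#' @param data tibble with columns `value` and `group` (two levels per
#'   contrast), plus `subject` for paired contrasts.
#' @param contrasts list of 2-vectors of group levels to compare.
#' @param paired logical (single value or per contrast).
#' @param family_size Bonferroni family size (default: number of contrasts).
#' @param backend `"gated"` (default) or `"dunn"`.
#' @param effect_prefix prefix for the effect name.
#' @return tidy tibble, one row per contrast.
#' @export
posthoc_pairwise <- function(data, contrasts, paired = FALSE,
                             family_size = length(contrasts),
                             backend = c("gated", "dunn"),
                             effect_prefix = "") {
  backend <- match.arg(backend)
  paired <- rep_len(paired, length(contrasts))
  purrr::map_dfr(seq_along(contrasts), function(i) {
    pr <- contrasts[[i]]
    a <- data$value[data$group == pr[1]]
    b <- data$value[data$group == pr[2]]
    if (paired[i]) {
      sa <- data$subject[data$group == pr[1]]
      sb <- data$subject[data$group == pr[2]]
      b <- b[match(sa, sb)]
    }
    if (length(a) < 3 || length(b) < 3) {
      stop("need n >= 3 per group for contrast ",
           paste(pr, collapse = " vs "), call. = FALSE)
    }
    eff <- paste0(effect_prefix, pr[1], " vs ", pr[2])
    summ <- paste(describe_sample(a), "|", describe_sample(b))
    if (backend == "dunn") {
      z <- dunn_z(a, b)
      return(stat_row("Dunn (rank)", eff, z, NA_real_,
                      2 * stats::pnorm(-abs(z)), family_size,
                      group_summaries = summ))
    }
    if (paired[i]) {
      d <- a - b
      if (all(d == 0)) {
        return(stat_row("paired t", eff, 0, length(d) - 1, 1, family_size,
                        group_summaries = summ))
      }
      if (shapiro_ok(d)) {
        tt <- stats::t.test(a, b, paired = TRUE)
        stat_row("paired t", eff, unname(tt$statistic),
                 unname(tt$parameter), tt$p.value, family_size,
                 group_summaries = summ)
      } else {
        wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
        stat_row("Wilcoxon signed-rank", eff, unname(wt$statistic),
                 NA_real_, wt$p.value, family_size, group_summaries = summ)
      }
    } else {
      if (shapiro_ok(a) && shapiro_ok(b)) {
        tt <- stats::t.test(a, b)
        stat_row("Welch t", eff, unname(tt$statistic), unname(tt$parameter),
                 tt$p.value, family_size, group_summaries = summ)
      } else {
        wt <- stats::wilcox.test(a, b, exact = FALSE)
        stat_row("Mann-Whitney", eff, unname(wt$statistic), NA_real_,
                 wt$p.value, family_size, group_summaries = summ)
      }
    }
  })
}

# Dunn-style z statistic on pooled ranks (two-group case).
dunn_z <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  n <- length(x); na <- length(a); nb <- length(b)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
  (mean(r[seq_len(na)]) - mean(r[na + seq_len(nb)])) / se
}

#' Paired tests on the 12 transition probabilities
#'
#' One paired (or unpaired, for between-group designs) test per ordered
#' off-diagonal class pair of the organizational transition matrix,
#' Bonferroni family fixed at the 12 pairs.
#'
#' @param orgtm_a,orgtm_b tibbles with columns `subject`, `from`, `to`,
#'   `orgtm`; for paired designs rows match by subject.
#' @param paired logical.
#' @return tidy tibble with 12 rows.
#' @export
transition_tests <- function(orgtm_a, orgtm_b, paired = TRUE) {
  pairs <- dplyr::distinct(orgtm_a, .data$from, .data$to) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::arrange(.data$from, .data$to)
  family <- nrow(pairs)
  purrr::map_dfr(seq_len(family), function(i) {
    fr <- pairs$from[i]; to <- pairs$to[i]
    a <- orgtm_a |> dplyr::filter(.data$from == fr, .data$to == to)
    b <- orgtm_b |> dplyr::filter(.data$from == fr, .data$to == to)
    dat <- tibble::tibble(
      value = c(a$orgtm, b$orgtm),
      group = rep(c("a", "b"), c(nrow(a), nrow(b))),
      subject = c(a$subject, b$subject)
    )
    res <- posthoc_pairwise(dat, list(c("a", "b")), paired = paired,
                            family_size = family,
                            effect_prefix = paste0("OrgTM_", fr, "->", to, ": "))
    res
  })
}

#' Clinical scale and demographic comparisons for a cohort table
#'
#' Per clinical scale with pre/post columns: Shapiro-Wilk gate, then paired
#' t-test or Wilcoxon signed-rank on the treated group. Demographics between
#' groups: chi-square for sex, two-sample t (or Mann-Whitney under
#' non-normality) for age and education. Summaries follow the gate: mean
#' ± SD when normal, median (IQR) otherwise.
#'
#' @param cohort tibble as from [simulate_cohort()] (`group`, `sex`, `age`,
#'   `education_years`, `<scale>_pre`/`<scale>_post` columns).
#' @param scales character vector of scale stems to test.
#' @param treated_group level of `group` with pre/post data.
#' @return tidy tibble, one row per test.
#' @export
clinical_change_tests <- function(cohort,
                                  scales = c("PSQI", "ISI", "HAS", "FSS",
                                             "HAMD", "HAMA"),
                                  treated_group = "CI") {
  ci <- dplyr::filter(cohort, .data$group == treated_group)
  scale_rows <- purrr::map_dfr(scales, function(sc) {
    pre_col <- paste0(sc, "_pre"); post_col <- paste0(sc, "_post")
    if (!pre_col %in% names(cohort) || !post_col %in% names(cohort)) {
      stop("missing scale column: ", pre_col, " / ", post_col, call. = FALSE)
    }
    pre <- ci[[pre_col]]; post <- ci[[post_col]]
    ok <- is.finite(pre) & is.finite(post)
    pre <- pre[ok]; post <- post[ok]
    d <- pre - post
    summ <- paste(describe_sample(pre), "->", describe_sample(post))
    if (all(d == 0)) {
      return(stat_row("paired t", sc, 0, length(d) - 1, 1,
                      adjustment = "none", group_summaries = summ))
    }
    if (shapiro_ok(d)) {
      tt <- stats::t.test(pre, post, paired = TRUE)
      stat_row("paired t", sc, unname(tt$statistic), unname(tt$parameter),
               tt$p.value, adjustment = "none", group_summaries = summ)
    } else {
      wt <- stats::wilcox.test(pre, post, paired = TRUE, exact = FALSE)
      stat_row("Wilcoxon signed-rank", sc, unname(wt$statistic), NA_real_,
               wt$p.value, adjustment = "none", group_summaries = summ)
    }
  })
  demo_rows <- NULL
  if (length(unique(cohort$group)) == 2) {
    tab <- table(cohort$group, cohort$sex)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    demo_rows <- dplyr::bind_rows(
      stat_row("chi-square", "sex", unname(chi$statistic),
               unname(chi$parameter), chi$p.value, adjustment = "none"),
      purrr::map_dfr(c("age", "education_years"), function(v) {
        g <- split(cohort[[v]], cohort$group)
        tt <- stats::t.test(g[[1]], g[[2]])
        stat_row("Welch t", v, unname(tt$statistic), unname(tt$parameter),
                 tt$p.value, adjustment = "none",
                 group_summaries = paste(describe_sample(g[[1]]), "|",
                                         describe_sample(g[[2]])))
      })
    )
  }
  dplyr::bind_rows(scale_rows, demo_rows)
}
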