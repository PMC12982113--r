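make_metric_data <- function(n_per_group, classes = c("A", "B"),
                             group_means = list(g1 = c(0, 0), g2 = c(0, 0)),
                             sd = 1, seed = 1) {
  set.seed(seed)
  out <- list()
  for (g in seq_along(group_means)) {
    for (j in seq_along(classes)) {
      out[[length(out) + 1]] <- tibble::tibble(
        subject = sprintf("g%d_s%02d", g, seq_len(n_per_group)),
        group = names(group_means)[g],
        class = classes[j],
        value = rnorm(n_per_group, group_means[[g]][j], sd)
      )
    }
  }
  dplyr::bind_rows(out)
}

test_that("mixed ANOVA interaction reduces to squared t on difference scores", {
  dat <- make_metric_data(12, group_means = list(g1 = c(0, 1), g2 = c(0.5, 0)),
                          seed = 2)
  res <- metric_anova(dat)
  # oracle: two-sample (pooled) t on per-subject class-difference scores
  wide <- tidyr::pivot_wider(dat, names_from = class, values_from = value)
  d <- wide$A - wide$B
  tt <- t.test(d[wide$group == "g1"], d[wide$group == "g2"], var.equal = TRUE)
  f_int <- res$statistic[res$effect == "group:class"]
  expect_equal(f_int, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p_raw[res$effect == "group:class"], tt$p.value,
               tolerance = 1e-9)
})

test_that("mixed ANOVA matches brute-force cell-mean sums of squares", {
  dat <- make_metric_data(6, group_means = list(g1 = c(1, 3), g2 = c(2, 2)),
                          seed = 3)
  res <- metric_anova(dat)
  # brute-force decomposition on the 2x2 design
  wide <- tidyr::pivot_wider(dat, names_from = class, values_from = value)
  Y <- as.matrix(wide[, c("A", "B")])
  g <- wide$group
  n <- nrow(Y); a <- 2; k <- 2
  grand <- mean(Y)
  subj_mean <- rowMeans(Y)
  grp_mean <- tapply(subj_mean, g, mean)
  ss_group <- k * sum(table(g) * (grp_mean - grand)^2)
  ss_subj <- k * sum((subj_mean - grp_mean[g])^2)
  cls_mean <- colMeans(Y)
  ss_class <- n * sum((cls_mean - grand)^2)
  cell_mean <- rbind(colMeans(Y[g == "g1", ]), colMeans(Y[g == "g2", ]))
  ng <- as.numeric(table(g))
  ss_int <- sum(ng * (sweep(sweep(cell_mean, 1, tapply(subj_mean, g, mean)),
                            2, cls_mean) + grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err_within <- ss_tot - ss_group - ss_subj - ss_class - ss_int
  f_group <- (ss_group / (a - 1)) / (ss_subj / (n - a))
  f_class <- (ss_class / (k - 1)) / (ss_err_within / ((n - a) * (k - 1)))
  f_int <- (ss_int / ((a - 1) * (k - 1))) / (ss_err_within / ((n - a) * (k - 1)))
  expect_equal(res$statistic[res$effect == "group"], f_group, tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "class"], f_class, tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "group:class"], f_int,
               tolerance = 1e-9)
})

test_that("mixed ANOVA handles degenerate and incomplete inputs", {
  dat <- make_metric_data(4, sd = 0, seed = 1)
  dat$value <- 1
  res <- metric_anova(dat)
  expect_equal(res$p_raw, rep(1, 3))
  dat2 <- make_metric_data(4, seed = 1)
  expect_error(metric_anova(dat2[-1, ]), "missing or duplicated")
})

test_that("group main effect p-values are calibrated under the null", {
  reps <- 40
  p <- vapply(seq_len(reps), function(r) {
    dat <- make_metric_data(8, seed = 100 + r)
    res <- metric_anova(dat)
    res$p_raw[res$effect == "group"]
  }, numeric(1))
  expect_lt(mean(p < 0.05), 0.2) # not wildly anticonservative
  expect_gt(mean(p), 0.3)        # and roughly uniform on average
})

test_that("post-hoc pairwise tests honour pairing, gating and Bonferroni", {
  set.seed(9)
  x <- rnorm(20, 0, 1)
  dat <- tibble::tibble(value = c(x, x),
                        group = rep(c("pre", "post"), each = 20),
                        subject = rep(sprintf("s%d", 1:20), 2))
  res <- posthoc_pairwise(dat, list(c("pre", "post")), paired = TRUE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_adjusted, 1)
  # Bonferroni definition
  dat2 <- tibble::tibble(value = c(rnorm(10), rnorm(10, 2)),
                         group = rep(c("a", "b"), each = 10),
                         subject = NA)
  r12 <- posthoc_pairwise(dat2, list(c("a", "b")), family_size = 12)
  expect_equal(r12$p_adjusted, min(1, 12 * r12$p_raw))
  expect_error(posthoc_pairwise(dat2[c(1, 2, 11, 12), ], list(c("a", "b"))),
               "n >= 3")
  # planted 1 SD shift, n = 41/group: detected
  set.seed(10)
  hits <- vapply(1:10, function(r) {
    d3 <- tibble::tibble(value = c(rnorm(41), rnorm(41, 1)),
                         group = rep(c("a", "b"), each = 41), subject = NA)
    posthoc_pairwise(d3, list(c("a", "b")), family_size = 4)$p_adjusted < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # rank-based backend agrees in direction
  rd <- posthoc_pairwise(dat2, list(c("a", "b")), backend = "dunn")
  expect_lt(rd$p_raw, 0.05)
})

test_that("transition tests cover exactly the 12 ordered pairs", {
  cl <- make_closure_cohort(3, 12, seed = 41)
  mets <- lapply(seq_along(cl$sequences), function(i) {
    true_sequence_metrics(cl$sequences[[i]], 256)$orgtm |>
      dplyr::mutate(subject = sprintf("s%d", i))
  })
  org <- dplyr::bind_rows(mets)
  res <- transition_tests(org, org, paired = TRUE)
  expect_equal(nrow(res), 12)
  expect_equal(res$p_adjusted, rep(1, 12))
  expect_equal(unique(res$family_size), 12)
})

test_that("clinical change tests gate on normality and flag planted change", {
  spec <- cohort_spec(n_hc = 10, n_ci = 41, n_responders = 14, seed = 5)
  sim <- simulate_cohort(spec, duration_s = 0)
  res <- clinical_change_tests(sim$cohort)
  psqi <- res[res$effect == "PSQI", ]
  expect_lt(psqi$p_raw, 0.001)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(all(c("sex", "age", "education_years") %in% res$effect))
  # no change -> p = 1
  coh <- sim$cohort
  coh$PSQI_post <- coh$PSQI_pre
  res0 <- clinical_change_tests(coh, scales = "PSQI")
  expect_equal(res0$p_raw[res0$effect == "PSQI"], 1)
  expect_error(clinical_change_tests(sim$cohort, scales = "NOPE"),
               "NOPE")
})

test_that("TANOVA permutation test separates different maps, not identical ones", {
  ts <- make_template_set()
  set.seed(12)
  noisy <- function(map, n, sd) {
    m <- outer(rep(1, n), map) + matrix(rnorm(n * 26, sd = sd), n)
    m * sample(c(-1, 1), n, replace = TRUE)  # random polarity per subject
  }
  # same underlying map -> p well above significance (typically)
  g_same <- list(a = noisy(ts$maps["A", ], 12, 0.3),
                 b = noisy(ts$maps["A", ], 12, 0.3))
  p_same <- tanova_permutation(g_same, n_perm = 199, seed = 1)$p_raw
  expect_gt(p_same, 0.05)
  # different maps -> significant
  g_diff <- list(a = noisy(ts$maps["A", ], 15, 0.3),
                 b = noisy(ts$maps["D", ], 15, 0.3))
  p_diff <- tanova_permutation(g_diff, n_perm = 199, seed = 1)$p_raw
  expect_lte(p_diff, 0.01)
  # permuting subjects within groups leaves the observed statistic unchanged
  s1 <- tanova_permutation(g_same, n_perm = 100, seed = 2)$statistic
  g_perm <- list(a = g_same$a[sample(12), ], b = g_same$b[sample(12), ])
  s2 <- tanova_permutation(g_perm, n_perm = 100, seed = 3)$statistic
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_error(tanova_permutation(list(a = g_same$a)), ">= 2 groups")
})
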