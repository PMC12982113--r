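test_that("responder labelling handles the 50% boundary under both comparators", {
  tab <- tibble::tibble(PSQI_pre = c(14, 13), PSQI_post = c(7, 7))
  inclusive <- label_responders(tab)
  strict <- label_responders(tab, strict = TRUE)
  expect_equal(inclusive$responder, c(1L, 0L))  # exactly 50% counts
  expect_equal(strict$responder, c(0L, 0L))     # strict > excludes it
  expect_error(label_responders(tibble::tibble(PSQI_pre = c(0, 10),
                                               PSQI_post = c(0, 3))),
               "non-positive")
  s <- attr(inclusive, "summary")
  expect_equal(s$responders, 1)
  expect_equal(s$responder_pct, 50)
})

test_that("bootstrap oversampling balances classes from minority resamples only", {
  tab <- synthesize_feature_table(14, 27, n_noise_features = 4, seed = 1)
  bal <- bootstrap_oversample(tab, seed = 42)
  expect_equal(as.integer(table(bal$responder)), c(27L, 27L))
  # duplicates are marked and are copies of original minority rows
  dup <- dplyr::filter(bal, .resampled)
  expect_equal(unique(dup$responder), 1)
  expect_true(all(dup$subject_id %in% tab$subject_id[tab$responder == 1]))
  # already balanced input returned unchanged
  tab2 <- synthesize_feature_table(5, 5, n_noise_features = 3, seed = 2)
  expect_equal(nrow(bootstrap_oversample(tab2, seed = 1)), 10)
  expect_error(bootstrap_oversample(dplyr::filter(tab, responder == 1)),
               "both classes")
})

test_that("all three selectors surface a dominant planted feature", {
  tab <- synthesize_feature_table(27, 27, effect_sizes = c(Duration_B = 5),
                                  n_noise_features = 19, seed = 3)
  for (m in c("rf", "rfe", "xgb")) {
    top <- rank_features_topk(tab, method = m, k = 15, seed = 7)
    expect_length(top, 15)
    expect_true("Duration_B" %in% top[1:3])
  }
  # k = all features -> a permutation of the vocabulary
  all_k <- rank_features_topk(tab, method = "rf", k = 20, seed = 7)
  expect_setequal(all_k, setdiff(names(tab), c("subject_id", "responder")))
  expect_error(rank_features_topk(tab, method = "rf", k = 50), "exceeds")
})

test_that("stability selection retains the planted feature and reproduces", {
  tab <- synthesize_feature_table(20, 20, effect_sizes = c(Duration_B = 5),
                                  n_noise_features = 19, seed = 4)
  st <- stability_select(tab, method = "rfe", B = 20, k = 5, seed = 5)
  expect_true("Duration_B" %in% st$stable)
  expect_equal(unname(st$frequencies["Duration_B"]), 1)
  # a pure-noise feature is selected at roughly the combinatorial base rate
  expect_lt(max(st$frequencies[setdiff(names(st$frequencies), "Duration_B")]),
            0.75 + 1e-9)
  st2 <- stability_select(tab, method = "rfe", B = 20, k = 5, seed = 5)
  expect_identical(st$frequencies, st2$frequencies)
})

test_that("consensus intersection follows the >= 2 methods rule", {
  sets <- list(rf = c("a", "b", "c"), rfe = c("b", "c", "d"), xgb = c("c", "e"))
  expect_setequal(consensus_features(sets), c("b", "c"))
  expect_length(consensus_features(list(a = "x", b = "y", c = "z")), 0)
  same <- list(a = c("u", "v"), b = c("u", "v"), c = c("u", "v"))
  expect_setequal(consensus_features(same), c("u", "v"))
})

test_that("VIF matches the closed-form regression oracle and prunes duplicates", {
  set.seed(6)
  n <- 100
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- x1 + x2 + rnorm(n, sd = 0.3)
  X <- cbind(f1 = x1, f2 = x2, f3 = x3)
  v <- vif_values(X)
  # independent oracle: 1/(1 - R^2) via lm
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
  # independent features: nothing pruned
  tab_ind <- tibble::as_tibble(matrix(rnorm(300), 100,
                                      dimnames = list(NULL, c("a", "b", "c")))) |>
    dplyr::mutate(responder = rep(0:1, 50))
  pr <- collinearity_prune(tab_ind)
  expect_equal(nrow(pr$pruned), 0)
  expect_true(all(pr$vif < 1.5))
  # exact duplicate: one copy dropped with infinite VIF
  tab_dup <- tab_ind |> dplyr::mutate(a_copy = a)
  pr2 <- collinearity_prune(tab_dup)
  expect_equal(nrow(pr2$pruned), 1)
  expect_true(pr2$pruned$feature %in% c("a", "a_copy"))
  expect_equal(pr2$pruned$value, Inf)
  # moderately correlated pair beyond the threshold is caught by |r|
  tab_cor <- tab_ind |> dplyr::mutate(near_a = a + rnorm(100, sd = 0.3))
  pr3 <- collinearity_prune(tab_cor, vif_threshold = 1e6, corr_threshold = 0.8)
  expect_equal(pr3$pruned$reason, "correlation")
})

test_that("the model zoo fits, predicts and reports absent backends", {
  tab <- synthesize_feature_table(15, 15, effect_sizes = c(Duration_A = 12),
                                  n_noise_features = 2, seed = 8)
  expect_warning(zoo <- model_zoo(seed = 42), "catboost")
  fits <- fit_model_zoo(tab, models = zoo, seed = 42)
  expect_setequal(names(fits), c("xgb", "lr", "svm", "rf", "knn", "nb",
                                 "adaboost"))
  for (m in names(fits)) {
    p <- predict_prob(fits[[m]], tab)
    expect_true(all(p >= 0 & p <= 1), info = m)
    # near-separable data: training accuracy 1 for every model
    expect_equal(mean((p >= 0.5) == (tab$responder == 1)), 1, info = m)
  }
  # seeded determinism for the stochastic tree models
  fits2 <- fit_model_zoo(tab, models = model_zoo(c("rf", "xgb", "adaboost"),
                                                 seed = 42), seed = 42)
  for (m in c("rf", "xgb", "adaboost")) {
    expect_equal(predict_prob(fits[[m]], tab), predict_prob(fits2[[m]], tab),
                 tolerance = 1e-12, info = m)
  }
  expect_error(suppressWarnings(
    fit_model_zoo(dplyr::mutate(tab, responder = 1))), "single-class")
})

test_that("stratified evaluation preserves class ratios and ranks planted signal", {
  tab <- synthesize_feature_table(14, 27, effect_sizes = c(Duration_A = 5),
                                  n_noise_features = 3, seed = 9)
  rep_ev <- evaluate_models(tab, models = model_zoo(c("rf", "lr"), seed = 42),
                            n_splits = 10, seed = 42)
  # each test fold keeps the 14/27 ratio within one subject
  per_split_n <- 41 - (round(14 * 0.75) + round(27 * 0.75))
  expect_equal(length(rep_ev$labels), 10 * per_split_n)
  expect_lt(abs(mean(rep_ev$labels) - 14 / 41), 0.04)
  auc <- rep_ev$summary |> dplyr::filter(metric == "auc")
  expect_true(all(auc$mean >= 0.9))
  expect_true(rep_ev$best_model %in% c("rf", "lr"))
  # determinism of the full report
  rep_ev2 <- evaluate_models(tab, models = model_zoo(c("rf", "lr"), seed = 42),
                             n_splits = 10, seed = 42)
  expect_equal(rep_ev$summary, rep_ev2$summary, tolerance = 1e-12)
})

test_that("DeLong test matches brute-force AUC and a bootstrap variance oracle", {
  # toy set: exhaustive pair counting gives AUC 1
  labels <- c(1, 1, 0, 0)
  dl <- delong_auc_test(c(0.9, 0.8, 0.1, 0.2), c(0.9, 0.8, 0.1, 0.2), labels)
  expect_equal(dl$auc_a, 1)
  expect_equal(dl$p, 1)
  expect_true(dl$degenerate)
  # brute-force AUC on a random instance
  set.seed(13)
  y <- rep(c(1, 0), c(30, 40))
  sa <- rnorm(70) + y
  sb <- rnorm(70) + 0.5 * y
  pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
  auc_brute <- mean((sa[pairs$p] > sa[pairs$n]) + 0.5 * (sa[pairs$p] == sa[pairs$n]))
  dl2 <- delong_auc_test(sa, sb, y)
  expect_equal(dl2$auc_a, auc_brute, tolerance = 1e-12)
  expect_false(dl2$degenerate)
  expect_gte(dl2$p, 0)
  # variance oracle: bootstrap of the AUC difference on a larger case
  set.seed(14)
  y2 <- rep(c(1, 0), each = 100)
  s1 <- rnorm(200) + y2
  s2 <- 0.7 * s1 + 0.3 * rnorm(200)
  dl3 <- delong_auc_test(s1, s2, y2)
  boot <- replicate(2000, {
    idx <- c(sample(which(y2 == 1), 100, TRUE), sample(which(y2 == 0), 100, TRUE))
    auc_mw <- function(sc) {
      r <- rank(c(sc[idx[1:100]], sc[idx[101:200]]))
      (sum(r[1:100]) - 100 * 101 / 2) / (100 * 100)
    }
    auc_mw(s1) - auc_mw(s2)
  })
  expect_equal(dl3$var_delta, var(boot), tolerance = 0.25)
})

test_that("DeLong agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rep(c(1, 0), c(25, 35))
  sa <- rnorm(60) + 0.8 * y
  sb <- rnorm(60) + 0.4 * y
  dl <- delong_auc_test(sa, sb, y)
  ref <- pROC::roc.test(
    pROC::roc(y, sa, quiet = TRUE, direction = "<", levels = c(0, 1)),
    pROC::roc(y, sb, quiet = TRUE, direction = "<", levels = c(0, 1)),
    method = "delong")
  expect_equal(dl$p, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(dl$z), abs(unname(ref$statistic)), tolerance = 1e-9)
})

test_that("exact Shapley attributions are additive and locate planted signal", {
  tab <- synthesize_feature_table(15, 15, effect_sizes = c(Duration_A = 3),
                                  n_noise_features = 2, seed = 16)
  fits <- fit_model_zoo(tab, models = model_zoo("rf", seed = 42), seed = 42)
  sh <- shap_summary(fits$rf, tab, seed = 1)
  # additivity: per-subject attributions sum to prediction - base value
  preds <- predict_prob(fits$rf, tab)
  expect_equal(rowSums(sh$values) + sh$base_value, preds, tolerance = 1e-9)
  # planted feature dominates and pushes responders upward
  expect_equal(sh$ranking$feature[1], "Duration_A")
  resp_mean <- mean(sh$values[tab$responder == 1, "Duration_A"])
  expect_gt(resp_mean, 0)
  # single-feature model: that feature carries all attribution
  fits1 <- fit_model_zoo(tab, features = "Duration_A",
                         models = model_zoo("lr", seed = 42), seed = 42)
  sh1 <- shap_summary(fits1$lr, tab, seed = 1)
  expect_equal(ncol(sh1$values), 1)
  expect_gt(mean(abs(sh1$values)), 0)
})
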