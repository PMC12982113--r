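#' The eight-algorithm classifier zoo
#'
#' Returns the model specifications used throughout the prediction stage:
#' CatBoost, XGBoost, logistic regression, SVM (RBF, with built-in
#' probability calibration), random forest, k-nearest neighbours, naive
#' Bayes and AdaBoost. Stated hyperparameters: 100 trees for the random
#' forest and XGBoost, 100 boosting iterations for CatBoost, 5 neighbours
#' for KNN; everything else at library defaults. The model list is
#' config-driven: a backend with no available implementation (CatBoost has
#' none here) is skipped with a warning and marked absent in reports.
#'
#' @param models character vector of model names to include.
#' @param seed integer seed baked into every stochastic learner.
#' @return named list of model specs (`fit(X, y)` / `predict_prob(fit, X)`),
#'   with an `absent` attribute naming skipped backends.
#' @export
model_zoo <- function(models = c("catboost", "xgb", "lr", "svm", "rf",
                                 "knn", "nb", "adaboost"),
                      seed = 42L) {
  available <- list(
    lr = list(
      fit = function(X, y) {
        suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                        family = stats::binomial()))
      },
      predict_prob = function(fit, X) {
        eta <- cbind(1, X) %*% ifelse(is.na(fit$coefficients), 0,
                                      fit$coefficients)
        as.numeric(1 / (1 + exp(-eta)))
      }
    ),
    svm = list(
      fit = function(X, y) {
        e1071::svm(X, factor(y, levels = c(0, 1)), probability = TRUE)
      },
      predict_prob = function(fit, X) {
        pr <- attr(stats::predict(fit, X, probability = TRUE),
                   "probabilities")
        as.numeric(pr[, "1"])
      }
    ),
    rf = list(
      fit = function(X, y) {
        ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                       num.trees = 100, probability = TRUE,
                       seed = as.integer(seed))
      },
      predict_prob = function(fit, X) {
        stats::predict(fit, as.data.frame(X))$predictions[, "1"]
      }
    ),
    xgb = list(
      fit = function(X, y) {
        with_seed(seed, xgboost::xgb.train(
          params = list(objective = "binary:logistic", nthread = 1,
                        seed = as.integer(seed)),
          data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
          nrounds = 100, verbose = 0))
      },
      predict_prob = function(fit, X) {
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
      }
    ),
    knn = list(
      fit = function(X, y) list(X = X, y = y),
      predict_prob = function(fit, X) {
        pr <- class::knn(fit$X, X, factor(fit$y, levels = c(0, 1)), k = 5,
                         prob = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == "1", p_win, 1 - p_win)
      }
    ),
    nb = list(
      fit = function(X, y) {
        e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0, 1)))
      },
      predict_prob = function(fit, X) {
        stats::predict(fit, as.data.frame(X), type = "raw")[, "1"]
      }
    ),
    adaboost = list(
      fit = function(X, y) adaboost_fit(X, y, n_rounds = 50, seed = seed),
      predict_prob = function(fit, X) adaboost_prob(fit, X)
    )
  )
  absent <- setdiff(models, names(available))
  if (length(absent)) {
    warning("no available backend for: ", paste(absent, collapse = ", "),
            "; skipped.", call. = FALSE)
  }
  structure(available[intersect(models, names(available))], absent = absent)
}

# AdaBoost (discrete SAMME) over depth-1 rpart stumps.
adaboost_fit <- function(X, y, n_rounds = 50, seed = 42L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- as.data.frame(X)
  yy <- factor(y, levels = c(0, 1))
  stumps <- list(); alphas <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(yy ~ ., data = cbind(yy = yy, df), weights = w,
                          method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = 0, xval = 0,
                                                         minsplit = 2))
      pred <- stats::predict(fit, df, type = "class")
      err <- sum(w * (pred != yy))
      if (err >= 0.5) break
      if (err <= 1e-12) {
        stumps[[length(stumps) + 1]] <- fit
        alphas <- c(alphas, 10)  # capped weight for a perfect stump
        break
      }
      alpha <- 0.5 * log((1 - err) / err)
      stumps[[length(stumps) + 1]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * ifelse(pred != yy, 1, -1))
      w <- w / sum(w)
    }
  })
  if (length(stumps) == 0) {
    # no usable weak learner: fall back to the empirical base rate
    return(list(stumps = list(), alphas = numeric(0),
                base = mean(y == 1)))
  }
  list(stumps = stumps, alphas = alphas, base = mean(y == 1))
}

adaboost_prob <- function(fit, X) {
  if (length(fit$stumps) == 0) return(rep(fit$base, nrow(X)))
  df <- as.data.frame(X)
  score <- rep(0, nrow(X))
  for (m in seq_along(fit$stumps)) {
    pred <- stats::predict(fit$stumps[[m]], df, type = "class")
    score <- score + fit$alphas[m] * ifelse(pred == "1", 1, -1)
  }
  1 / (1 + exp(-2 * score))  # logistic link on the boosted margin
}

#' Fit every model of the zoo on a feature table
#'
#' @param table balanced feature tibble with a `responder` column and the
#'   final feature columns.
#' @param features character vector of feature columns to use (default all).
#' @param models a [model_zoo()] spec list.
#' @param seed integer seed (passed to [model_zoo()] when `models` is
#'   omitted).
#' @return named list of fitted models (class `ms_model_set`), each element
#'   a list `fit`, `spec`, `features`.
#' @export
fit_model_zoo <- function(table, features = NULL, models = NULL, seed = 42L) {
  if (is.null(models)) models <- model_zoo(seed = seed)
  X <- feature_matrix(table)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- table$responder
  if (length(unique(y)) < 2) stop("labels are single-class.", call. = FALSE)
  fits <- lapply(models, function(spec) {
    list(fit = spec$fit(X, y), spec = spec, features = colnames(X))
  })
  structure(fits, class = "ms_model_set", absent = attr(models, "absent"))
}

#' Predict class-1 probabilities from a fitted zoo member
#'
#' @param object one element of a [fit_model_zoo()] result.
#' @param table feature tibble to score.
#' @return numeric probabilities.
#' @export
predict_prob <- function(object, table) {
  X <- feature_matrix(table)[, object$features, drop = FALSE]
  object$spec$predict_prob(object$fit, X)
}

# -- classification metrics on probability scores ---------------------------

score_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(auc = auc_mann_whitney(scores, labels),
    accuracy = mean(pred == labels),
    precision = precision, recall = recall, f1 = f1,
    pr_auc = average_precision(scores, labels))
}

# AUC as the normalized Mann-Whitney statistic (ties count 1/2).
auc_mann_whitney <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Average precision (step-interpolated area under the PR curve).
average_precision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab == 1)
  precision <- tp / seq_along(lab)
  recall <- tp / sum(lab == 1)
  sum(precision * (lab == 1)) / sum(lab == 1)
}

#' Repeated stratified shuffle-split evaluation of the model zoo
#'
#' `n_splits` repetitions of a stratified 75/25 train/test split, preserving
#' the class ratio in both folds; each repetition fits every model on the
#' training fold and scores the held-out fold on AUC, accuracy, precision,
#' recall, F1 and PR-AUC. Class balancing by bootstrap oversampling can run
#' inside the training fold only (`oversample = "fold"`, the leakage-safe
#' default), before splitting on the whole table (`"pre"`, reproducing the
#' balance-then-split order whose scores are optimistic because duplicated
#' subjects cross folds — reports label it so), or not at all (`"none"`).
#'
#' @param table feature tibble with `responder` labels.
#' @param features feature columns to use (default all).
#' @param models a [model_zoo()] list (default: full zoo).
#' @param n_splits repetitions (default 100).
#' @param train_fraction default 0.75.
#' @param oversample `"fold"`, `"pre"` or `"none"`.
#' @param seed integer seed.
#' @return an `ms_eval_report`: `summary` tibble (model, metric, mean, sd),
#'   `per_split` tibble, `scores` (pooled out-of-fold scores per model),
#'   `labels`, `best_model`, `delong` (pairwise p-value tibble),
#'   `oversample` mode, `absent` backends.
#' @export
evaluate_models <- function(table, features = NULL, models = NULL,
                            n_splits = 100, train_fraction = 0.75,
                            oversample = c("fold", "pre", "none"),
                            seed = 42L) {
  oversample <- match.arg(oversample)
  if (is.null(models)) models <- model_zoo(seed = seed)
  if (oversample == "pre") {
    table <- bootstrap_oversample(table, seed = child_seed(seed, 999L))
  }
  y <- table$responder
  if (min(table(y)) < 2) stop("both classes need >= 2 subjects.", call. = FALSE)
  idx_pos <- which(y == 1); idx_neg <- which(y == 0)
  n_tr_pos <- round(length(idx_pos) * train_fraction)
  n_tr_pos <- min(max(n_tr_pos, 1), length(idx_pos) - 1)
  n_tr_neg <- round(length(idx_neg) * train_fraction)
  n_tr_neg <- min(max(n_tr_neg, 1), length(idx_neg) - 1)
  per_split <- list()
  pooled <- lapply(models, function(m) numeric(0))
  pooled_labels <- numeric(0)
  for (s in seq_len(n_splits)) {
    tr <- with_seed(child_seed(seed, s), {
      c(sample(idx_pos, n_tr_pos), sample(idx_neg, n_tr_neg))
    })
    train <- table[tr, ]; test <- table[-tr, ]
    if (oversample == "fold") {
      if (min(table(train$responder)) != max(table(train$responder))) {
        train <- bootstrap_oversample(train, seed = child_seed(seed, 5000L + s))
      }
    }
    fits <- fit_model_zoo(train, features = features, models = models,
                          seed = seed)
    for (m in names(fits)) {
      sc <- predict_prob(fits[[m]], test)
      met <- score_metrics(sc, test$responder)
      per_split[[length(per_split) + 1]] <- tibble::tibble(
        model = m, split = s, metric = names(met), value = unname(met))
      pooled[[m]] <- c(pooled[[m]], sc)
    }
    pooled_labels <- c(pooled_labels, test$responder)
  }
  per_split <- dplyr::bind_rows(per_split)
  summary <- per_split |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  mean_auc <- summary |> dplyr::filter(.data$metric == "auc")
  best <- mean_auc$model[which.max(mean_auc$mean)]
  mods <- names(models)
  delong <- NULL
  if (length(mods) > 1) {
    combos <- utils::combn(mods, 2)
    delong <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
      a <- combos[1, j]; b <- combos[2, j]
      dl <- delong_auc_test(pooled[[a]], pooled[[b]], pooled_labels)
      tibble::tibble(model_a = a, model_b = b, delta_auc = dl$delta_auc,
                     z = dl$z, p = dl$p)
    })
  }
  structure(
    list(summary = summary, per_split = per_split, scores = pooled,
         labels = pooled_labels, best_model = best, delong = delong,
         oversample = oversample, n_splits = n_splits,
         absent = attr(models, "absent")),
    class = "ms_eval_report"
  )
}

#' @export
print.ms_eval_report <- function(x, ...) {
  cat(sprintf("<ms_eval_report> %d splits, oversampling: %s%s\n",
              x$n_splits, x$oversample,
              if (x$oversample == "pre")
                " (balance-before-split: scores are optimistic)" else ""))
  auc <- x$summary |> dplyr::filter(.data$metric == "auc") |>
    dplyr::arrange(dplyr::desc(.data$mean))
  for (i in seq_len(nrow(auc))) {
    cat(sprintf("  %-9s AUC %.3f ± %.3f%s\n", auc$model[i], auc$mean[i],
                auc$sd[i], if (auc$model[i] == x$best_model) "  <- best" else ""))
  }
  if (length(x$absent)) {
    cat("  absent backends:", paste(x$absent, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method glance ms_eval_report
#' @export
glance.ms_eval_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd")) |>
    dplyr::mutate(best = .data$model == x$best_model,
                  n_splits = x$n_splits, oversample = x$oversample)
}

#' DeLong test for two correlated ROC AUCs
#'
#' AUCs are computed as normalized Mann-Whitney statistics; their variances
#' and covariance come from the DeLong structural components (placement
#' values of each positive against the negatives and vice versa), giving
#' `z = (AUC_a - AUC_b) / sqrt(var)` and a two-sided normal p-value. Both
#' score vectors must refer to the same labels. A zero-variance difference
#' (identical score orderings) returns p = 1 with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b probability/score vectors on the same cases.
#' @param labels binary labels (0/1), both classes present.
#' @return list: `auc_a`, `auc_b`, `delta_auc`, `var_delta`, `z`, `p`,
#'   `degenerate`.
#' @export
delong_auc_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stop("scores and labels must have equal length.", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present.", call. = FALSE)
  }
  pos <- labels == 1; neg <- labels == 0
  comp <- function(sc) {
    X <- sc[pos]; Y <- sc[neg]
    m <- length(X); n <- length(Y)
    psi <- outer(X, Y, function(x, y) (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi),
         m = m, n = n)
  }
  a <- comp(scores_a); b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  S <- s10 / a$m + s01 / a$n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- a$auc - b$auc
  if (var_delta <= 0 || !is.finite(var_delta)) {
    return(list(auc_a = a$auc, auc_b = b$auc, delta_auc = delta,
                var_delta = max(var_delta, 0), z = 0, p = 1,
                degenerate = TRUE))
  }
  z <- delta / sqrt(var_delta)
  list(auc_a = a$auc, auc_b = b$auc, delta_auc = delta,
       var_delta = var_delta, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Exact Shapley attribution for a fitted zoo member
#'
#' Interventional Shapley values computed exactly by enumerating all `2^p`
#' feature coalitions (p <= `max_features`), with the conditional
#' expectation estimated over a background sample of rows. By construction
#' the attributions of each subject sum exactly to the model output minus
#' the background mean prediction (the additivity property).
#'
#' @param model one fitted element of [fit_model_zoo()].
#' @param table feature tibble whose rows are explained.
#' @param background background rows (default: `table` itself, subsampled to
#'   `max_background`).
#' @param max_background background rows cap (default 25).
#' @param max_features refuse enumeration beyond this many features
#'   (default 14).
#' @param seed integer seed for the background subsample.
#' @return an `ms_shap`: `values` (subjects x features matrix),
#'   `base_value`, `ranking` tibble (feature, mean_abs, mean_signed,
#'   dominant_sign).
#' @export
shap_summary <- function(model, table, background = NULL,
                         max_background = 25, max_features = 14,
                         seed = 1L) {
  feats <- model$features
  p <- length(feats)
  if (p > max_features) {
    stop(sprintf("exact enumeration over %d features exceeds the cap (%d).",
                 p, max_features), call. = FALSE)
  }
  X <- feature_matrix(table)[, feats, drop = FALSE]
  if (is.null(background)) background <- X
  B <- background[, feats, drop = FALSE]
  if (nrow(B) > max_background) {
    B <- B[with_seed(seed, sample(nrow(B), max_background)), , drop = FALSE]
  }
  n <- nrow(X); nb <- nrow(B)
  n_coal <- 2^p
  # v[i, c]: mean model output for subject i with coalition c's features
  # from x_i and the rest from each background row
  v <- matrix(0, n, n_coal)
  coal_members <- vector("list", n_coal)
  for (ci in seq_len(n_coal)) {
    members <- which(bitwAnd(ci - 1L, bitwShiftL(1L, 0:(p - 1))) != 0)
    coal_members[[ci]] <- members
    big <- B[rep(seq_len(nb), times = n), , drop = FALSE]
    if (length(members)) {
      xrep <- X[rep(seq_len(n), each = nb), members, drop = FALSE]
      big[, members] <- xrep
    }
    preds <- model$spec$predict_prob(model$fit, big)
    v[, ci] <- colMeans(matrix(preds, nb, n))
  }
  sizes <- lengths(coal_members)
  fact <- factorial(0:p)
  phi <- matrix(0, n, p, dimnames = list(NULL, feats))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_coal - 1), bit) == 0)
    for (ci in without) {
      s <- sizes[ci]
      w <- fact[s + 1] * fact[p - s] / fact[p + 1]
      phi[, j] <- phi[, j] + w * (v[, ci + bit] - v[, ci])
    }
  }
  base <- mean(v[, 1])
  ranking <- tibble::tibble(
    feature = feats,
    mean_abs = colMeans(abs(phi)),
    mean_signed = colMeans(phi)
  ) |>
    dplyr::mutate(dominant_sign = ifelse(.data$mean_signed >= 0, "+", "-")) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs))
  structure(list(values = phi, base_value = base, per_subject_output = v[, n_coal],
                 ranking = ranking),
            class = "ms_shap")
}

#' @export
print.ms_shap <- function(x, ...) {
  cat(sprintf("<ms_shap> %d subjects x %d features, base value %.3f\n",
              nrow(x$values), ncol(x$values), x$base_value))
  print(x$ranking)
  invisible(x)
}

#' @method tidy ms_shap
#' @export
tidy.ms_shap <- function(x, ...) {
  tibble::as_tibble(x$values) |>
    dplyr::mutate(subject = dplyr::row_number()) |>
    tidyr::pivot_longer(-"subject", names_to = "feature",
                        values_to = "shap_value")
}
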