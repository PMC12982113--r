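#' Rank features by one of three importance criteria
#'
#' The three selectors of the multi-stage screen: `rf` — random-forest Gini
#' (impurity) importance; `rfe` — recursive feature elimination with a
#' logistic model on standardized features, iteratively dropping the
#' smallest-|coefficient| feature until `k` remain; `xgb` — gradient-boosted
#' tree gain importance. All are seeded.
#'
#' @param table tibble with a binary `responder` column and numeric feature
#'   columns (non-feature columns `subject_id`, `subject`, `.resampled` are
#'   ignored).
#' @param method `"rf"`, `"rfe"` or `"xgb"`.
#' @param k how many features to return (default 15).
#' @param seed integer seed.
#' @return character vector of `k` feature names, most important first.
#' @export
rank_features_topk <- function(table, method = c("rf", "rfe", "xgb"),
                               k = 15, seed = 42L) {
  method <- match.arg(method)
  X <- feature_matrix(table)
  y <- table$responder
  if (k > ncol(X)) {
    stop(sprintf("k = %d exceeds the %d available features.", k, ncol(X)),
         call. = FALSE)
  }
  ranked <- switch(
    method,
    rf = with_seed(seed, {
      fit <- ranger::ranger(x = as.data.frame(X), y = factor(y),
                            num.trees = 100, importance = "impurity",
                            seed = as.integer(seed))
      names(sort(fit$variable.importance, decreasing = TRUE))
    }),
    xgb = with_seed(seed, {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      nthread = 1, seed = as.integer(seed)),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = 100, verbose = 0)
      imp <- xgboost::xgb.importance(model = fit)
      # features never used by a split get zero gain and rank last
      c(imp$Feature, setdiff(colnames(X), imp$Feature))
    }),
    rfe = rfe_logistic(X, y, k)
  )
  ranked[seq_len(k)]
}

# Extract the numeric feature matrix from a feature tibble.
feature_matrix <- function(table, drop = c("subject_id", "subject",
                                           "responder", ".resampled",
                                           "group")) {
  X <- as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature table contains missing values.", call. = FALSE)
  X
}

# Recursive feature elimination with standardized logistic regression:
# repeatedly drop the feature with the smallest absolute coefficient.
rfe_logistic <- function(X, y, k) {
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  keep <- colnames(X)
  dropped <- character(0)
  while (length(keep) > k) {
    df <- as.data.frame(Xs[, keep, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                       family = stats::binomial()))
    co <- abs(stats::coef(fit)[-1])
    co[is.na(co)] <- 0
    worst <- keep[which.min(co)]
    dropped <- c(worst, dropped)
    keep <- setdiff(keep, worst)
  }
  # order survivors by final |coefficient|
  df <- as.data.frame(Xs[, keep, drop = FALSE])
  fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                     family = stats::binomial()))
  co <- abs(stats::coef(fit)[-1])
  co[is.na(co)] <- 0
  c(keep[order(co, decreasing = TRUE)], dropped)
}

#' Bootstrap stability selection around a ranking method
#'
#' Draws `B` bootstrap resamples of subjects, reruns [rank_features_topk()]
#' on each, and retains the features appearing in the top-`k` in more than
#' `freq_threshold` of resamples.
#'
#' @param table feature tibble (see [rank_features_topk()]).
#' @param method selector passed through.
#' @param B bootstrap iterations (>= 10; default 100).
#' @param freq_threshold retention threshold on the selection fraction
#'   (default 0.75, strict `>`).
#' @param k top-k size per resample.
#' @param seed integer seed.
#' @return list: `stable` (character vector), `frequencies` (named numeric,
#'   all features).
#' @export
stability_select <- function(table, method = "rf", B = 100,
                             freq_threshold = 0.75, k = 15, seed = 42L) {
  if (B < 10) stop("B must be >= 10.", call. = FALSE)
  feats <- colnames(feature_matrix(table))
  counts <- stats::setNames(numeric(length(feats)), feats)
  n <- nrow(table)
  for (b in seq_len(B)) {
    idx <- with_seed(child_seed(seed, b), {
      # resample within class so both classes stay represented
      unlist(lapply(split(seq_len(n), table$responder), function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }))
    })
    top <- rank_features_topk(table[idx, ], method = method, k = k,
                              seed = child_seed(seed, 10000L + b))
    counts[top] <- counts[top] + 1
  }
  freq <- counts / B
  list(stable = names(freq)[freq > freq_threshold], frequencies = freq)
}

#' Consensus features across selection methods
#'
#' Features retained by at least `min_methods` of the per-method stable
#' sets, with the Venn-region counts attached for reporting.
#'
#' @param stable_sets named list of character vectors (e.g. rf/rfe/xgb).
#' @param min_methods minimum number of methods (default 2).
#' @return character vector of consensus features with a `venn` attribute
#'   (named counts of every method combination).
#' @export
consensus_features <- function(stable_sets, min_methods = 2) {
  all_feats <- unique(unlist(stable_sets))
  member <- sapply(stable_sets, function(s) all_feats %in% s)
  if (length(all_feats) == 1) member <- matrix(member, nrow = 1)
  hits <- rowSums(member)
  consensus <- all_feats[hits >= min_methods]
  combos <- apply(member, 1, function(r) {
    paste(names(stable_sets)[r], collapse = "&")
  })
  venn <- table(combos)
  structure(consensus, venn = venn)
}

#' Variance-inflation and correlation pruning of candidate features
#'
#' Multicollinearity screen: iteratively computes each candidate's VIF
#' (`1/(1 - R^2)` from regressing it on the remaining candidates) and drops
#' the largest-VIF feature while any VIF exceeds `vif_threshold`; then, for
#' any remaining pair with `|Pearson r| > corr_threshold`, drops the member
#' with the larger mean absolute correlation to all others. Perfectly
#' collinear features are dropped with VIF reported as `Inf`. Every removal
#' is logged with its offending value.
#'
#' @param table feature tibble restricted to >= 2 candidate columns (plus
#'   the usual id/label columns, ignored).
#' @param candidates character vector of candidate feature names (default:
#'   all feature columns).
#' @param vif_threshold default 10.
#' @param corr_threshold default 0.8.
#' @return list: `kept` (character), `pruned` (tibble: feature, reason,
#'   value), `vif` (named numeric of the final set).
#' @export
collinearity_prune <- function(table, candidates = NULL, vif_threshold = 10,
                               corr_threshold = 0.8) {
  X <- feature_matrix(table)
  if (is.null(candidates)) candidates <- colnames(X)
  X <- X[, candidates, drop = FALSE]
  if (ncol(X) < 2) stop("need >= 2 candidate features.", call. = FALSE)
  pruned <- tibble::tibble(feature = character(), reason = character(),
                           value = numeric())
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    v <- vif_values(X[, keep, drop = FALSE])
    if (max(v) <= vif_threshold) break
    worst <- names(v)[which.max(v)]
    pruned <- dplyr::add_row(pruned, feature = worst, reason = "vif",
                             value = max(v))
    keep <- setdiff(keep, worst)
  }
  repeat {
    if (length(keep) < 2) break
    r <- stats::cor(X[, keep, drop = FALSE])
    diag(r) <- 0
    if (max(abs(r)) <= corr_threshold) break
    idx <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    mean_abs <- rowMeans(abs(r))[idx]
    worst <- pair[which.max(mean_abs)]
    pruned <- dplyr::add_row(pruned, feature = worst, reason = "correlation",
                             value = max(abs(r)))
    keep <- setdiff(keep, worst)
  }
  final_vif <- if (length(keep) >= 2) vif_values(X[, keep, drop = FALSE])
               else stats::setNames(rep(1, length(keep)), keep)
  list(kept = keep, pruned = pruned, vif = final_vif)
}

#' Variance inflation factors of a feature matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of column j on the remaining columns; `Inf` under perfect
#' collinearity.
#'
#' @param X numeric matrix with >= 2 columns.
#' @return named numeric vector.
#' @export
vif_values <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    if (ssr <= sst * 1e-12) Inf else 1 / (ssr / sst)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Run the full multi-stage feature-selection chain
#'
#' Default stage order: per-method top-k ranking wrapped in bootstrap
#' stability selection, consensus across methods (>= 2 of 3), then
#' VIF/correlation pruning. The alternative order `"consensus_first"`
#' intersects the plain top-k lists first and applies stability to the
#' consensus set afterwards.
#'
#' @param table feature tibble with `responder` labels.
#' @param methods selectors to combine.
#' @param k,B,freq_threshold,vif_threshold,corr_threshold stage parameters.
#' @param order `"stability_first"` (default) or `"consensus_first"`.
#' @param seed integer seed.
#' @return a `ms_selection_report`: list with `per_method_topk`,
#'   `stability_freq`, `consensus`, `venn`, `pruned`, `final_features`.
#' @export
select_features <- function(table, methods = c("rf", "rfe", "xgb"), k = 15,
                            B = 100, freq_threshold = 0.75,
                            vif_threshold = 10, corr_threshold = 0.8,
                            order = c("stability_first", "consensus_first"),
                            seed = 42L) {
  order <- match.arg(order)
  topk <- lapply(stats::setNames(methods, methods), function(m) {
    rank_features_topk(table, method = m, k = k, seed = child_seed(seed, 1L))
  })
  stab <- lapply(stats::setNames(methods, methods), function(m) {
    stability_select(table, method = m, B = B,
                     freq_threshold = freq_threshold, k = k,
                     seed = child_seed(seed, match(m, methods)))
  })
  if (order == "stability_first") {
    consensus <- consensus_features(lapply(stab, `[[`, "stable"))
  } else {
    consensus <- consensus_features(topk)
    stable_all <- unique(unlist(lapply(stab, `[[`, "stable")))
    consensus <- structure(intersect(consensus, stable_all),
                           venn = attr(consensus, "venn"))
  }
  if (length(consensus) >= 2) {
    prune <- collinearity_prune(table, candidates = as.character(consensus),
                                vif_threshold = vif_threshold,
                                corr_threshold = corr_threshold)
    final <- prune$kept
    pruned <- prune$pruned
    vif <- prune$vif
  } else {
    final <- as.character(consensus)
    pruned <- tibble::tibble(feature = character(), reason = character(),
                             value = numeric())
    vif <- stats::setNames(rep(1, length(final)), final)
  }
  structure(
    list(per_method_topk = topk,
         stability_freq = lapply(stab, `[[`, "frequencies"),
         consensus = as.character(consensus),
         venn = attr(consensus, "venn"),
         pruned = pruned, final_features = final, vif = vif),
    class = "ms_selection_report"
  )
}

#' @export
print.ms_selection_report <- function(x, ...) {
  cat("<ms_selection_report>\n")
  cat("  consensus (", length(x$consensus), "): ",
      paste(x$consensus, collapse = ", "), "\n", sep = "")
  if (nrow(x$pruned)) {
    cat("  pruned:\n")
    for (i in seq_len(nrow(x$pruned))) {
      cat(sprintf("    - %s (%s = %.3g)\n", x$pruned$feature[i],
                  x$pruned$reason[i], x$pruned$value[i]))
    }
  }
  cat("  final (", length(x$final_features), "): ",
      paste(x$final_features, collapse = ", "), "\n", sep = "")
  invisible(x)
}
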