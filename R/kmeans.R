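#' Polarity-invariant (modified) K-means clustering of topographic maps
#'
#' The microstate variant of K-means: a map and its negation belong to the
#' same class. Maps are assigned to the template with the largest squared
#' spatial correlation; each template is then updated to the dominant
#' eigenvector of the sum of outer products of its assigned maps (the
#' principal orientation, which is sign-free). The best of `restarts` random
#' initializations by global explained variance (GEV) is returned.
#'
#' Convergence: assignments stable or relative GEV change below `tol`
#' (default 1e-6), capped at `max_iter` iterations. An emptied cluster is
#' re-seeded from the currently worst-fit map.
#'
#' @param maps n x channels matrix of average-referenced maps (n >= k).
#' @param k number of classes (default 4).
#' @param restarts number of random initializations (default 100).
#' @param seed integer seed.
#' @param gfp optional per-map GFP weights for the GEV criterion (default
#'   equal weights).
#' @param max_iter,tol convergence controls.
#' @return list with `templates` (an [ms_templates] labelled `1..k` pending
#'   canonical labelling), `assignment` (integer per map), `gev` (scalar),
#'   `restart_gev` (GEV reached by each restart).
#' @export
modified_kmeans <- function(maps, k = 4, restarts = 100, seed = 1L,
                            gfp = NULL, max_iter = 300, tol = 1e-6) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (k > n) stop(sprintf("k = %d exceeds the %d available maps.", k, n),
                  call. = FALSE)
  ch_names <- colnames(maps)
  V <- normalize_maps(maps)               # unit-norm, zero-mean rows
  if (is.null(gfp)) gfp <- rep(1, n)
  w <- gfp^2 / sum(gfp^2)
  best <- NULL
  restart_gev <- numeric(restarts)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- kmeans_once(V, k, w, max_iter, tol)
      restart_gev[r] <- fit$gev
      if (is.null(best) || fit$gev > best$gev) best <- fit
    }
  })
  templ <- ms_templates(best$templates,
                        labels = as.character(seq_len(k)),
                        channel_names = ch_names, level = "subject")
  list(templates = templ, assignment = best$assignment, gev = best$gev,
       restart_gev = restart_gev)
}

kmeans_once <- function(V, k, w, max_iter, tol) {
  n <- nrow(V)
  centers <- V[sample.int(n, k), , drop = FALSE]
  assignment <- integer(n)
  gev_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    corr <- tcrossprod(V, centers)        # cosine = spatial correlation
    assignment_new <- max.col(corr^2, ties.method = "first")
    # re-seed empty clusters from the worst-fit map
    fit2 <- corr[cbind(seq_len(n), assignment_new)]^2
    for (j in seq_len(k)) {
      if (!any(assignment_new == j)) {
        worst <- which.min(fit2)
        centers[j, ] <- V[worst, ]
        assignment_new[worst] <- j
        fit2[worst] <- 1
      }
    }
    for (j in seq_len(k)) {
      idx <- which(assignment_new == j)
      S <- crossprod(V[idx, , drop = FALSE])
      ev <- eigen(S, symmetric = TRUE)
      centers[j, ] <- ev$vectors[, 1]
    }
    centers <- centers - rowMeans(centers)
    centers <- centers / sqrt(rowSums(centers^2))
    corr <- tcrossprod(V, centers)
    gev <- sum(w * corr[cbind(seq_len(n), assignment_new)]^2)
    converged <- identical(assignment_new, assignment) ||
      abs(gev - gev_prev) < tol * max(gev_prev, .Machine$double.eps)
    assignment <- assignment_new
    gev_prev <- gev
    if (converged) break
  }
  list(templates = centers, assignment = assignment, gev = gev_prev)
}

#' Two-level (subject then group) template estimation
#'
#' Pools every subject's individual template maps and reruns the
#' polarity-invariant K-means across participants, yielding the group-level
#' average microstate templates that are subsequently back-fitted to each
#' subject's GFP peaks.
#'
#' @param subject_template_sets list of [ms_templates] (>= 2 subjects, equal
#'   channel counts).
#' @param k,restarts,seed as in [modified_kmeans()].
#' @return a group-level [ms_templates] (labels `1..k` pending canonical
#'   labelling).
#' @export
two_level_templates <- function(subject_template_sets, k = 4, restarts = 100,
                                seed = 1L) {
  if (length(subject_template_sets) < 2) {
    stop("need at least 2 subjects.", call. = FALSE)
  }
  nch <- vapply(subject_template_sets, function(s) ncol(s$maps), integer(1))
  if (length(unique(nch)) != 1) {
    stop("channel count differs across subjects.", call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(subject_template_sets, function(s) s$maps))
  fit <- modified_kmeans(pooled, k = k, restarts = restarts, seed = seed)
  out <- fit$templates
  out$level <- "group"
  out
}

#' Canonical A-D labelling of a template set
#'
#' Exhaustively evaluates all k! label permutations against a reference
#' template set (default: the canonical archetypes on the built-in montage)
#' and keeps the permutation maximizing the total absolute spatial
#' correlation. Ties within 1e-9 are broken deterministically by
#' lexicographic permutation order.
#'
#' @param templates an [ms_templates] with k maps.
#' @param reference an [ms_templates] on the same channels supplying the
#'   target labels.
#' @return `templates` relabelled (and row-reordered to the reference label
#'   order), with a `match` attribute giving per-class absolute correlations.
#' @export
assign_canonical_labels <- function(templates,
                                    reference = make_template_set()) {
  k <- nrow(templates$maps)
  if (nrow(reference$maps) != k ||
      ncol(reference$maps) != ncol(templates$maps)) {
    stop("reference and templates must share k and channel space.",
         call. = FALSE)
  }
  cc <- abs(spatial_correlation(reference$maps, templates$maps))
  perms <- permutations(k)
  totals <- apply(perms, 1, function(p) sum(cc[cbind(seq_len(k), p)]))
  best <- which(totals > max(totals) - 1e-9)[1]  # lexicographic tie-break
  p <- perms[best, ]
  out <- ms_templates(templates$maps[p, , drop = FALSE],
                      labels = reference$labels,
                      channel_names = templates$channel_names,
                      level = templates$level)
  attr(out, "match") <- stats::setNames(cc[cbind(seq_len(k), p)],
                                        reference$labels)
  out
}

# All permutations of 1..n, in lexicographic row order.
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Global explained variance of a back-fitted peak sequence
#'
#' GEV is the GFP^2-weighted fraction of topographic variance explained by
#' the winning templates: `sum(gfp^2 * corr^2) / sum(gfp^2)` over peaks.
#'
#' @param seq an [ms_peak_sequence].
#' @param gfp the full GFP series the peaks were picked from.
#' @return scalar in \[0, 1\].
#' @export
compute_gev <- function(seq, gfp) {
  g <- gfp[seq$peak_samples]
  sum(g^2 * seq$abs_corr^2) / sum(g^2)
}
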