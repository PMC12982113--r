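test_that("GFP matches the direct population-SD formula", {
  # two channels +1/-1 -> population SD 1; all-zero sample -> 0
  rec <- ms_recording(cbind(c(1, -1), c(0, 0)), 256, c("C1", "C2"),
                      reference = "average")
  expect_equal(compute_gfp(rec), c(1, 0))
  set.seed(7)
  d <- matrix(rnorm(26 * 40), 26)
  d <- sweep(d, 2, colMeans(d))
  rec <- ms_recording(d, 256, montage_1020()$name, reference = "average")
  oracle <- apply(d, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(compute_gfp(rec), oracle, tolerance = 1e-12)
  rec$reference <- "recorded"
  expect_warning(compute_gfp(rec), "average referenced")
  expect_error(compute_gfp(rec, strict = TRUE), "average referenced")
})

test_that("GFP peak picking finds strict local maxima with spacing control", {
  expect_equal(find_gfp_peaks(c(0, 1, 0, 1, 0), 256, 0), c(2, 4))
  expect_equal(length(find_gfp_peaks(rep(1, 100), 256)), 0)
  # 10 Hz rectified carrier: ~20 extrema per second
  t_s <- seq(0, 1 - 1 / 256, by = 1 / 256)
  g <- abs(sin(2 * pi * 10 * t_s))
  expect_equal(length(find_gfp_peaks(g, 256, 10)), 20, tolerance = 0.1)
  # min-distance thinning keeps the larger of two close peaks
  g2 <- c(0, 5, 0, 9, 0, 0, 0, 0, 0, 0)
  expect_equal(find_gfp_peaks(g2, 1000, 3), 4)
})

test_that("modified K-means is polarity invariant and recovers planted maps", {
  ts <- make_template_set()
  set.seed(11)
  # one map repeated with random signs -> k = 1 recovers it exactly
  signs <- sample(c(-1, 1), 40, replace = TRUE)
  maps <- outer(signs, ts$maps["C", ])
  fit <- modified_kmeans(maps, k = 1, restarts = 5, seed = 1)
  expect_equal(abs(spatial_correlation(fit$templates$maps[1, ], ts$maps["C", ])),
               1, tolerance = 1e-9)
  expect_equal(fit$gev, 1, tolerance = 1e-9)
  # maps from 4 distinct templates + mild noise -> each truth recovered
  idx <- rep(1:4, each = 50)
  maps4 <- ts$maps[idx, ] + matrix(rnorm(200 * 26, sd = 0.08), 200)
  fit4 <- modified_kmeans(maps4, k = 4, restarts = 20, seed = 2)
  cc <- abs(spatial_correlation(fit4$templates$maps, ts$maps))
  best <- apply(cc, 2, max)
  expect_true(all(best >= 0.98))
  expect_equal(sort(unname(apply(cc, 2, which.max))), 1:4)  # distinct winners
  # negating every input changes neither assignments nor |correlations|
  fit_neg <- modified_kmeans(-maps4, k = 4, restarts = 20, seed = 2)
  expect_identical(fit_neg$assignment, fit4$assignment)
  expect_equal(fit_neg$gev, fit4$gev, tolerance = 1e-12)
  expect_error(modified_kmeans(maps4[1:3, ], k = 4), "exceeds")
})

test_that("restart search never returns a worse clustering than a single restart", {
  ts <- make_template_set()
  set.seed(3)
  maps <- ts$maps[rep(1:4, each = 15), ] + matrix(rnorm(60 * 26, sd = 0.5), 60)
  fit <- modified_kmeans(maps, k = 4, restarts = 25, seed = 9)
  expect_length(fit$restart_gev, 25)
  expect_gte(fit$gev + 1e-12, max(fit$restart_gev))
})

test_that("two-level clustering pools subject maps and is order invariant", {
  ts <- make_template_set()
  subj <- lapply(1:5, function(i) ts)  # identical subjects
  grp <- two_level_templates(subj, restarts = 10, seed = 1)
  cc <- abs(spatial_correlation(grp$maps, ts$maps))
  expect_true(all(apply(cc, 2, max) > 1 - 1e-9))
  # permuting subjects spans the same template subspace
  set.seed(4)
  subj2 <- lapply(1:5, function(i) {
    ms_templates(ts$maps + matrix(rnorm(4 * 26, sd = 0.05), 4),
                 channel_names = ts$channel_names)
  })
  g1 <- two_level_templates(subj2, restarts = 20, seed = 2)
  g2 <- two_level_templates(rev(subj2), restarts = 20, seed = 2)
  match_cc <- abs(spatial_correlation(g1$maps, g2$maps))
  expect_true(all(apply(match_cc, 1, max) > 0.999))
  expect_error(two_level_templates(subj2[1]), "at least 2")
})

test_that("canonical labelling maximizes total |correlation| over permutations", {
  ref <- make_template_set()
  shuffled <- ms_templates(ref$maps[c(3, 1, 4, 2), ],
                           channel_names = ref$channel_names)
  out <- assign_canonical_labels(shuffled, ref)
  expect_equal(out$labels, c("A", "B", "C", "D"))
  expect_equal(unname(attr(out, "match")), rep(1, 4), tolerance = 1e-9)
  expect_equal(out$maps, ref$maps, tolerance = 1e-9, ignore_attr = TRUE)
  # negated reference labels identically
  out_neg <- assign_canonical_labels(
    ms_templates(-shuffled$maps, channel_names = ref$channel_names), ref)
  expect_equal(abs(out_neg$maps), abs(ref$maps), tolerance = 1e-9,
               ignore_attr = TRUE)
  # brute-force oracle: independent enumeration over all 24 permutations
  set.seed(5)
  rnd <- ms_templates(matrix(rnorm(4 * 26), 4),
                      channel_names = ref$channel_names)
  out_rnd <- assign_canonical_labels(rnd, ref)
  cc <- abs(spatial_correlation(ref$maps, rnd$maps))
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  totals <- apply(perms, 1, function(p) sum(cc[cbind(1:4, p)]))
  expect_equal(sum(attr(out_rnd, "match")), max(totals), tolerance = 1e-12)
})

test_that("back-fitting assigns peaks by maximum absolute correlation", {
  ts <- make_template_set()
  # recording whose samples are exact templates (plus a baseline so peaks exist)
  amp <- c(1, 3, 1, 5, 1, 4, 1)
  states <- c(1, 3, 2, 3, 4, 2, 1)
  data <- t(ts$maps[states, ] * amp)
  rec <- ms_recording(data, 256, ts$channel_names, reference = "average")
  bf <- backfit_peaks(rec, ts, min_distance_ms = 0)
  expect_equal(bf$labels, c("C", "C", "B"))  # strict maxima at samples 2,4,6
  expect_equal(bf$abs_corr, rep(1, 3), tolerance = 1e-9)
  # negated template map still assigned to its own class
  data_neg <- cbind(ts$maps["A", ], -5 * ts$maps["C", ], ts$maps["A", ])
  rec_neg <- ms_recording(data_neg, 256, ts$channel_names,
                          reference = "average")
  bf2 <- backfit_peaks(rec_neg, ts, min_distance_ms = 0)
  expect_equal(bf2$labels[1], "C")
  expect_equal(bf2$abs_corr[1], 1, tolerance = 1e-9)
})

test_that("metric computation matches the hand-worked peak-expansion example", {
  # peaks every 10 ms at 1000 Hz over 60 ms analyzed time
  seq <- ms_peak_sequence(c(6, 16, 26, 36, 46, 56),
                          c("A", "A", "A", "B", "B", "A"),
                          rep(1, 6), rate = 1000, total_samples = 61,
                          state_labels = c("A", "B", "C", "D"))
  m <- compute_metrics(seq)
  pc <- m$per_class
  expect_equal(pc$occurrence[pc$class == "A"], 2 / 0.06, tolerance = 1e-9)
  expect_equal(pc$coverage[pc$class == "A"], 200 / 3, tolerance = 1e-9)
  expect_equal(pc$duration_ms[pc$class == "A"], 20, tolerance = 1e-9)
  expect_equal(pc$duration_ms[pc$class == "B"], 20, tolerance = 1e-9)
  org <- m$orgtm
  expect_equal(org$orgtm[org$from == "A" & org$to == "B"], 50)
  expect_equal(org$orgtm[org$from == "B" & org$to == "A"], 50)
  expect_equal(m$n_transitions, 2)
})

test_that("metric identities hold on arbitrary sequences", {
  set.seed(6)
  for (rep in 1:5) {
    n_pk <- 200
    pk <- sort(sample(2:6000, n_pk))
    labs <- sample(c("A", "B", "C", "D"), n_pk, replace = TRUE)
    seq <- ms_peak_sequence(pk, labs, runif(n_pk), 256, 6002,
                            state_labels = c("A", "B", "C", "D"))
    m <- compute_metrics(seq)
    expect_equal(sum(m$per_class$coverage), 100, tolerance = 0.5)
    expect_equal(sum(m$orgtm$orgtm), 100, tolerance = 1e-6)
    with(m$per_class, {
      ident <- occurrence * duration_ms / 1000 * 100
      expect_equal(coverage, ident, tolerance = 0.01)
    })
  }
  # single-label degenerate case
  seq1 <- ms_peak_sequence(c(10, 20, 30), rep("A", 3), rep(1, 3), 256, 40,
                           state_labels = c("A", "B", "C", "D"))
  m1 <- suppressMessages(compute_metrics(seq1))
  expect_equal(m1$per_class$coverage,  c(100, 0, 0, 0))
  expect_equal(sum(m1$orgtm$orgtm), 0)
  expect_equal(m1$n_transitions, 0)
})

test_that("GEV equals its direct formula and hits the 0/1 endpoints", {
  # all correlations 1 -> GEV 1; orthogonal templates -> 0
  seq <- ms_peak_sequence(c(5, 10, 15), c("A", "B", "A"), rep(1, 3), 256, 20)
  expect_equal(compute_gev(seq, gfp = rep(2, 20)), 1)
  seq0 <- ms_peak_sequence(c(5, 10, 15), c("A", "B", "A"), rep(0, 3), 256, 20)
  expect_equal(compute_gev(seq0, gfp = rep(2, 20)), 0)
  set.seed(8)
  g <- runif(50, 0.5, 2)
  ac <- runif(3)
  seqr <- ms_peak_sequence(c(7, 21, 40), c("A", "A", "B"), ac, 256, 50)
  oracle <- sum(g[c(7, 21, 40)]^2 * ac^2) / sum(g[c(7, 21, 40)]^2)
  expect_equal(compute_gev(seqr, g), oracle, tolerance = 1e-12)
})

test_that("negating a recording leaves every downstream metric unchanged", {
  cl <- make_closure_cohort(2, 10, seed = 31)
  rec <- cl$recordings[[1]]
  neg <- rec
  neg$data <- -neg$data
  bf_a <- backfit_peaks(rec, cl$truth$templates)
  bf_b <- backfit_peaks(neg, cl$truth$templates)
  expect_identical(bf_a$labels, bf_b$labels)
  m_a <- compute_metrics(bf_a); m_b <- compute_metrics(bf_b)
  expect_equal(m_a$per_class, m_b$per_class, tolerance = 1e-12)
  expect_equal(m_a$orgtm, m_b$orgtm, tolerance = 1e-12)
})
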