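
# two tight, far-apart pairs on the line: the canonical worked example
two_pairs <- function() {
  pts <- points_encoding(c(0, 0.1, 10, 10.1))
  run <- kmeans_weighted(pts, 2, n_starts = 20, seed = 1)
  list(pts = pts, run = run)
}

test_that("Calinski-Harabasz matches the hand-computed pair example", {
  tp <- two_pairs()
  # SS_B = 2*(5)^2 * 2 = 100, SS_W = 4 * 0.05^2 = 0.01
  expect_equal(ch_index(tp$pts, tp$run), (100 / 0.01) * (4 - 2) / (2 - 1),
               tolerance = 1e-9)
})

test_that("CH is invariant to cluster relabeling and matches the oracle", {
  encs <- fixture_encodings()
  for (type in c("I", "III")) {
    enc <- encs[[type]]
    for (metric in c("euclidean", "cosine")) {
      lab <- c(1, 2, 2, 3, 1)
      run <- list(partition = wf_partition(enc$workflow_ids, lab),
                  centers = NULL, center_kind = "centroid",
                  metric = metric)
      run$centers <- vapply(unique(lab), function(g)
        rowMeans(enc$matrix[, lab == g, drop = FALSE]),
        numeric(nrow(enc$matrix)))
      class(run) <- "wf_cluster_run"
      expect_equal(ch_index(enc, run), oracle_ch(enc, lab, metric),
                   tolerance = 1e-9)
      # relabeled partition, same structure
      relab <- c(3, 1, 1, 2, 3)
      run2 <- run
      run2$partition <- wf_partition(enc$workflow_ids, relab)
      run2$centers <- vapply(unique(relab), function(g)
        rowMeans(enc$matrix[, relab == g, drop = FALSE]),
        numeric(nrow(enc$matrix)))
      expect_equal(ch_index(enc, run2), ch_index(enc, run),
                   tolerance = 1e-12)
    }
  }
})

test_that("CH rejects out-of-range K and degenerate variance", {
  pts <- points_encoding(c(0, 0, 1, 1))
  all_one <- kmeans_weighted(pts, 1, seed = 1)
  expect_error(ch_index(pts, all_one), "2 <= K")
  split2 <- kmeans_weighted(pts, 2, n_starts = 10, seed = 1)
  expect_error(ch_index(pts, split2), "degenerate")
})

test_that("logSS value and chooser follow the consecutive-difference rule", {
  tp <- two_pairs()
  expect_equal(logss_index(tp$pts, tp$run), log(100 / 0.01),
               tolerance = 1e-9)   # ln(10^4) ~ 9.2103
  expect_equal(logss_choose_k(c("2" = 1.0, "3" = 3.0, "4" = 3.1)), 3L)
  # identical increments tie -> smallest scanned K
  expect_equal(logss_choose_k(c("2" = 1, "3" = 2, "4" = 3)), 2L)
  expect_equal(logss_choose_k(c("2" = 5.0)), 2L)
  expect_equal(logss_choose_k(c("2" = 1.0, "3" = 0.2, "4" = 3.0),
                              absolute = TRUE), 2L)
  expect_error(logss_choose_k(c("2" = 1, "4" = 2)), "consecutive")
})

test_that("silhouette matches hand computation and the brute-force loop", {
  tp <- two_pairs()
  # outer points: a = 0.1, b = 10.05; inner points: a = 0.1, b = 9.95
  s_hand <- ((10.05 - 0.1) / 10.05 + (9.95 - 0.1) / 9.95) / 2
  expect_equal(silhouette_index(tp$pts, tp$run$partition), s_hand,
               tolerance = 1e-9)
  expect_equal(s_hand, 0.99, tolerance = 1e-4)
  # identical points in 2 clusters: a = b = 0 -> s = 0 by convention
  same <- points_encoding(c(1, 1, 1, 1))
  half <- wf_partition(same$workflow_ids, c(1, 1, 2, 2))
  expect_equal(silhouette_index(same, half), 0)
  # oracle agreement (macro and per-point forms, both metrics)
  for (seed in 1:2) {
    enc <- random_encoding(8, 6, seed = seed)
    lab <- c(1, 2, 2, 3, 1, 3)
    part <- wf_partition(enc$workflow_ids, lab)
    for (metric in c("euclidean", "cosine")) for (pp in c(TRUE, FALSE)) {
      expect_equal(silhouette_index(enc, part, metric, per_point = pp),
                   oracle_silhouette(enc, lab, metric, per_point = pp),
                   tolerance = 1e-9)
    }
  }
})

test_that("silhouette values stay within [-1, 1]", {
  for (seed in 1:5) {
    enc <- random_encoding(8, 7, seed = seed, counts = TRUE)
    lab <- sample(rep(1:3, length.out = 7))
    s <- silhouette_index(enc, wf_partition(enc$workflow_ids, lab))
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("select_k chooses K by the index rule and is reproducible", {
  pts <- points_encoding(c(0, 0.1, 10, 10.1))
  fit <- select_k(pts, "kmeans", "euclidean", "CH", 2, 3,
                  n_starts = 20, seed = 5)
  expect_identical(fit$chosen_k, 2L)
  expect_identical(unname(fit$chosen_partition$labels), c(1L, 1L, 2L, 2L))
  fit2 <- select_k(pts, "kmeans", "euclidean", "CH", 2, 3,
                   n_starts = 20, seed = 5)
  expect_equal(fit$per_k, fit2$per_k)
  expect_error(select_k(pts, k_min = 1), "k_min")
})

test_that("within-cluster dispersion decreases with K for k-means", {
  cfg <- sim_config(n_workflows_per_class = 8,
                    tasks_per_workflow = c(3L, 8L))
  ws <- simulate_workflows(cfg, seed = 21)
  enc <- encode_type1(ws)
  fit <- select_k(enc, "kmeans", "euclidean", "CH", 2, 8,
                  n_starts = 15, seed = 3)
  expect_true(all(diff(fit$per_k$ss_w) < 1e-9))
})

test_that("medoid-centered indices use the run's medoids", {
  enc <- fixture_encodings()$I
  run <- kmedoids_weighted(enc, 3, n_starts = 50, seed = 2)
  v <- ch_index(enc, run)
  expect_true(is.finite(v) && v > 0)
  # SS decomposition uses medoid columns: recompute by hand
  med_idx <- match(run$centers, enc$workflow_ids)
  lab <- unname(run$partition$labels)
  D <- unclass(distance_matrix(enc, "euclidean"))
  ssw <- sum(vapply(seq_len(3), function(k)
    sum(D[lab == k, med_idx[k]]^2), 0))
  ss <- wfclust:::.ss_decomposition(enc, run)
  expect_equal(ss$ss_w, ssw, tolerance = 1e-9)
})
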