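test_that("Rand index matches pair enumeration and known cases", {
  ids <- sprintf("w%d", 1:5)
  p1 <- wf_partition(ids, c(1, 1, 2, 2, 3))
  p2 <- wf_partition(ids, c(1, 1, 2, 3, 3))
  expect_equal(rand_index(p1, p2), 0.8)
  expect_equal(rand_index(p1, p1), 1.0)
  singletons <- wf_partition(ids, 1:5)
  together <- wf_partition(ids, rep(1, 5))
  expect_equal(rand_index(singletons, together), 0.0)
  # symmetry and oracle equivalence on random label pairs
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:9, 1)
    l1 <- sample.int(3, n, replace = TRUE)
    l2 <- sample.int(4, n, replace = TRUE)
    q1 <- wf_partition(sprintf("x%d", 1:n), l1)
    q2 <- wf_partition(sprintf("x%d", 1:n), l2)
    expect_equal(rand_index(q1, q2), oracle_rand(l1, l2), tolerance = 1e-12)
    expect_equal(rand_index(q1, q2), rand_index(q2, q1))
  }
  expect_error(rand_index(p1, wf_partition(letters[1:5], 1:5)),
               "mismatched")
})

test_that("rand_index aligns label vectors by name", {
  a <- c(w1 = 1, w2 = 1, w3 = 2)
  b <- c(w3 = 5, w1 = 7, w2 = 7)   # same partition, permuted ids
  expect_equal(rand_index(a, b), 1.0)
})

test_that("the generator respects its configuration and seed", {
  cfg <- sim_config(n_classes = 3, tasks_per_class = 5,
                    n_workflows_per_class = 4,
                    tasks_per_workflow = c(2L, 6L), mixing = 0)
  ws1 <- simulate_workflows(cfg, seed = 99)
  ws2 <- simulate_workflows(cfg, seed = 99)
  expect_equal(ws1, ws2)
  expect_length(ws1$workflows, 12L)
  expect_length(ws1$task_pool, 15L)
  # zero mixing: every task comes from the workflow's own class pool
  for (w in ws1$workflows) {
    own <- vapply(ws1$task_pool[w$instances], `[[`, "", "category")
    expect_true(all(own == w$class_label))
    nt <- length(w$instances)
    expect_gte(nt, 2L); expect_lte(nt, 6L)
    expect_identical(validate_workflow(w, ws1), character(0))
    # chain-with-branching topology: instance t has an inbound edge
    if (nt > 1L)
      expect_setequal(unique(w$edges[, 2]), 2:nt)
  }
  # mixing pulls tasks across class pools
  wsx <- simulate_workflows(sim_config(n_classes = 3, tasks_per_class = 5,
                                       n_workflows_per_class = 10,
                                       tasks_per_workflow = c(4L, 8L),
                                       mixing = 0.5), seed = 7)
  foreign <- vapply(wsx$workflows, function(w)
    sum(vapply(wsx$task_pool[w$instances], `[[`, "", "category") !=
          w$class_label), 0L)
  expect_gt(sum(foreign), 0L)
  expect_error(simulate_workflows(
    sim_config(n_classes = 2, tasks_per_class = 2,
               tasks_per_workflow = c(1L, 20L)), seed = 1),
    "pool size")
})

test_that("separated classes are perfectly recoverable at zero mixing", {
  cfg <- sim_config(n_workflows_per_class = 10,
                    tasks_per_workflow = c(4L, 8L), mixing = 0)
  ws <- simulate_workflows(cfg, seed = 5)
  enc <- encode_type1(ws)
  fit <- select_k(enc, "kmeans", "euclidean", "CH", 2, 6,
                  n_starts = 30, seed = 2)
  expect_equal(rand_index(fit$chosen_partition, reference_partition(ws)),
               1.0)
})

test_that("experiment_grid runs each factor combination reproducibly", {
  cfg <- sim_config(n_workflows_per_class = 5,
                    tasks_per_workflow = c(3L, 6L), mixing = 0.1)
  ws <- simulate_workflows(cfg, seed = 31)
  g1 <- experiment_grid(ws, encodings = c("I", "II"),
                        metrics = c("euclidean", "cosine"),
                        algorithms = "kmeans", indices = "CH",
                        k_min = 2, k_max = 5, n_starts = 10, seed = 8)
  expect_identical(nrow(g1), 4L)
  expect_true(all(g1$chosen_k >= 2 & g1$chosen_k <= 5))
  expect_true(all(g1$rand_index >= 0 & g1$rand_index <= 1))
  g2 <- experiment_grid(ws, encodings = c("I", "II"),
                        metrics = c("euclidean", "cosine"),
                        algorithms = "kmeans", indices = "CH",
                        k_min = 2, k_max = 5, n_starts = 10, seed = 8)
  expect_equal(g1, g2, ignore_attr = TRUE)
  # a 1-combination grid is a single select_k call
  g3 <- experiment_grid(ws, encodings = "I", metrics = "euclidean",
                        algorithms = "kmeans", indices = "CH",
                        k_min = 2, k_max = 5, n_starts = 10, seed = 4)
  set.seed(4)
  fit <- select_k(encode_type1(ws), "kmeans", "euclidean", "CH", 2, 5,
                  n_starts = 10)
  expect_identical(g3$chosen_k, fit$chosen_k)
  expect_equal(g3$rand_index,
               rand_index(fit$chosen_partition, reference_partition(ws)))
})

test_that("rand index can be stratified by workflow size", {
  cfg <- sim_config(n_workflows_per_class = 6,
                    tasks_per_workflow = c(2L, 6L), mixing = 0)
  ws <- simulate_workflows(cfg, seed = 17)
  ref <- reference_partition(ws)
  tab <- ri_by_task_count(ws, ref)
  expect_true(all(tab$n_tasks >= 2 & tab$n_tasks <= 6))
  expect_identical(sum(tab$n_workflows), 24L)
  # the reference against itself is perfect in every stratum
  expect_true(all(tab$rand_index[!is.na(tab$rand_index)] == 1))
})
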