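# Rand-index evaluation against reference labels, the synthetic
# workflow-collection generator, and the factor-grid experiment driver.

#' Rand index between two partitions
#'
#' `(a + d) / C(n, 2)` where `a` counts element pairs co-clustered in both
#' partitions and `d` pairs separated in both. Well defined for partitions
#' with different numbers of clusters; 1 for identical partitions.
#'
#' @param p1,p2 `wf_partition` objects, or label vectors named by id,
#'   over identical id sets.
#' @return Value in `[0, 1]`.
#' @export
rand_index <- function(p1, p2) {
  lab <- function(p) if (inherits(p, "wf_partition")) p$labels else p
  l1 <- lab(p1); l2 <- lab(p2)
  if (!is.null(names(l1)) && !is.null(names(l2))) {
    if (!setequal(names(l1), names(l2))) stop("mismatched id sets")
    l2 <- l2[names(l1)]
  } else if (length(l1) != length(l2)) stop("mismatched id sets")
  n <- length(l1)
  if (n < 2L) stop("need at least two elements")
  tab <- table(l1, l2)
  a <- sum(choose(tab, 2))
  total <- choose(n, 2)
  # d = total - pairs together in p1 - pairs together in p2 + a
  d <- total - sum(choose(rowSums(tab), 2)) - sum(choose(colSums(tab), 2)) + a
  (a + d) / total
}

#' Partition induced by reference class labels
#'
#' @param ws A `workflow_set` whose workflows carry `class_label`s, or a
#'   named label vector.
#' @return A `wf_partition`.
#' @export
reference_partition <- function(ws) {
  labels <- if (inherits(ws, "workflow_set")) {
    vapply(ws$workflows, function(w) w$class_label %||% NA_character_, "")
  } else ws
  if (anyNA(labels)) stop("missing class labels")
  wf_partition(names(labels), match(labels, unique(labels)))
}

#' Configuration for the synthetic workflow generator
#'
#' The defaults emulate a small curated collection of phylogenetic
#' pipelines: four workflow classes with class-specific pools of four
#' tasks each (a pool of 16 tasks overall), workflows of one to eight
#' tasks, log-normal execution times centred near 0.5 time units (matching
#' the spread of the example collection's task times), and one annotation
#' keyword per class.
#'
#' @param n_classes Number of workflow classes.
#' @param tasks_per_class Pool size per class.
#' @param n_workflows_per_class Workflows generated per class.
#' @param tasks_per_workflow Length-2 integer range of task counts.
#' @param mixing Probability in `[0, 1]` that a task is drawn from a
#'   foreign class pool instead of the workflow's own.
#' @param exec_time_meanlog,exec_time_sdlog Log-normal parameters of the
#'   task execution times.
#' @param keyword_classes Character vector of per-class annotation
#'   keywords (recycled/defaulted to `"kw-<class>"`).
#' @return A list of class `"wf_simconfig"`.
#' @export
sim_config <- function(n_classes = 4L, tasks_per_class = 4L,
                       n_workflows_per_class = 10L,
                       tasks_per_workflow = c(1L, 8L),
                       mixing = 0,
                       exec_time_meanlog = log(0.5),
                       exec_time_sdlog = 0.6,
                       keyword_classes = NULL) {
  stopifnot(n_classes >= 1L, tasks_per_class >= 1L,
            n_workflows_per_class >= 1L,
            length(tasks_per_workflow) == 2L,
            tasks_per_workflow[1L] >= 1L,
            tasks_per_workflow[2L] >= tasks_per_workflow[1L],
            mixing >= 0, mixing <= 1)
  if (is.null(keyword_classes))
    keyword_classes <- sprintf("kw-%d", seq_len(n_classes))
  structure(list(n_classes = as.integer(n_classes),
                 tasks_per_class = as.integer(tasks_per_class),
                 n_workflows_per_class = as.integer(n_workflows_per_class),
                 tasks_per_workflow = as.integer(tasks_per_workflow),
                 mixing = mixing,
                 exec_time_meanlog = exec_time_meanlog,
                 exec_time_sdlog = exec_time_sdlog,
                 keyword_classes = rep_len(keyword_classes, n_classes)),
            class = "wf_simconfig")
}

#' Generate a synthetic labelled workflow collection
#'
#' Each workflow's class is assigned round-robin; its task count is uniform
#' in the configured range; every task slot draws from the workflow's own
#' class pool with probability `1 - mixing` and from a uniformly chosen
#' foreign pool otherwise. Within one workflow a pool hands out distinct
#' tasks first and repeats tasks only when more slots request it than it
#' holds, so at zero mixing any workflow with at least `tasks_per_class`
#' tasks covers its whole class pool. The topology is a chain with occasional
#' branching: each non-first task instance receives an edge from a
#' uniformly chosen earlier instance. Execution times are drawn once per
#' pool task from the log-normal; class-pool tasks carry the class keyword
#' as annotation. Deterministic given `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A `workflow_set` whose workflows carry `class_label`s.
#' @export
simulate_workflows <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "wf_simconfig"))
  if (cfg$tasks_per_workflow[2L] > cfg$n_classes * cfg$tasks_per_class)
    stop("tasks_per_workflow max exceeds total pool size")
  if (!is.null(seed)) set.seed(seed)
  pool <- list()
  pool_ids <- vector("list", cfg$n_classes)
  for (cl in seq_len(cfg$n_classes)) {
    ids <- sprintf("c%d_t%d", cl, seq_len(cfg$tasks_per_class))
    pool_ids[[cl]] <- ids
    for (id in ids)
      pool[[id]] <- wf_task(
        id, name = id, category = sprintf("class%d", cl),
        avg_exec_time = stats::rlnorm(1, cfg$exec_time_meanlog,
                                      cfg$exec_time_sdlog),
        annotations = cfg$keyword_classes[[cl]])
  }
  n_wf <- cfg$n_classes * cfg$n_workflows_per_class
  wfs <- vector("list", n_wf)
  for (i in seq_len(n_wf)) {
    cl <- ((i - 1L) %% cfg$n_classes) + 1L
    rng <- cfg$tasks_per_workflow
    nt <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
    # each slot draws its source pool (own class unless mixed away), then
    # pools hand out distinct tasks first, repeating only once exhausted
    src <- vapply(seq_len(nt), function(t) {
      if (cfg$n_classes > 1L && stats::runif(1) < cfg$mixing) {
        others <- setdiff(seq_len(cfg$n_classes), cl)
        others[sample.int(length(others), 1L)]
      } else cl
    }, 0L)
    tasks <- character(nt)
    for (p in unique(src)) {
      slots <- which(src == p)
      pool_p <- pool_ids[[p]]
      np <- length(pool_p)
      k <- length(slots)
      picks <- if (k <= np) pool_p[sample.int(np, k)]
      else c(pool_p[sample.int(np, np)],
             pool_p[sample.int(np, k - np, replace = TRUE)])
      tasks[slots] <- picks
    }
    edges <- if (nt > 1L)
      cbind(vapply(2:nt, function(t)
        if (t == 2L) 1L else sample.int(t - 1L, 1L), 0L), 2:nt)
    else NULL
    wfs[[i]] <- wf_workflow(sprintf("wf%03d", i), tasks, edges,
                            inputs = "Data", outputs = "Results",
                            class_label = sprintf("class%d", cl))
  }
  workflow_set(pool, wfs)
}

.encode_by_name <- function(ws, encoding, rule) {
  switch(encoding,
         I = encode_type1(ws),
         II = encode_type2(ws, rule),
         III = encode_type3(ws),
         IV = encode_type4(ws, rule),
         stop("unknown encoding: ", encoding))
}

#' Run a factor grid of clustering experiments
#'
#' For every combination of encoding, metric, algorithm and validity index
#' a [select_k()] fit is run and, when reference class labels are present,
#' scored with the Rand index. Reproducible given `seed`.
#'
#' @param ws A labelled `workflow_set`.
#' @param encodings Subset of `c("I", "II", "III", "IV")`.
#' @param metrics Subset of `c("euclidean", "cosine")`.
#' @param algorithms Subset of `c("kmeans", "kmedoids")`.
#' @param indices Subset of `c("CH", "SI", "logSS")`.
#' @param rule [keyword_rule()] for encodings II and IV.
#' @param k_min,k_max,n_starts,seed Passed to [select_k()].
#' @return A data.frame with one row per factor combination: the settings,
#'   the chosen K, the index value at the chosen K and the Rand index
#'   against the reference labels (`NA` when unlabelled). The list of
#'   fitted `wf_kselect` objects is attached as attribute `"fits"`.
#' @export
experiment_grid <- function(ws, encodings = c("I", "II", "III", "IV"),
                            metrics = "euclidean", algorithms = "kmeans",
                            indices = "CH",
                            rule = keyword_rule("HGT"),
                            k_min = 2L, k_max = NULL, n_starts = 100L,
                            seed = NULL) {
  stopifnot(length(encodings) >= 1L, length(metrics) >= 1L,
            length(algorithms) >= 1L, length(indices) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  has_labels <- all(!vapply(ws$workflows,
                            function(w) is.null(w$class_label), NA))
  ref <- if (has_labels) reference_partition(ws) else NULL
  grid <- expand.grid(encoding = encodings, metric = metrics,
                      algorithm = algorithms, index = indices,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  out <- grid
  out$chosen_k <- NA_integer_
  out$index_value <- NA_real_
  out$rand_index <- NA_real_
  for (r in seq_len(nrow(grid))) {
    enc <- .encode_by_name(ws, grid$encoding[r], rule)
    fit <- select_k(enc, algorithm = grid$algorithm[r],
                    metric = grid$metric[r], index = grid$index[r],
                    k_min = k_min, k_max = k_max, n_starts = n_starts)
    fits[[r]] <- fit
    out$chosen_k[r] <- fit$chosen_k
    out$index_value[r] <-
      fit$per_k$index[match(fit$chosen_k, fit$per_k$K)]
    if (has_labels)
      out$rand_index[r] <- rand_index(fit$chosen_partition, ref)
  }
  attr(out, "fits") <- fits
  out
}

#' Rand index stratified by workflow size
#'
#' Restricts the comparison of a fitted partition with the reference
#' labels to workflows with a given number of task instances, for each
#' size present in the collection.
#'
#' @param ws The labelled `workflow_set`.
#' @param part A `wf_partition` over the collection.
#' @return A data.frame with columns `n_tasks`, `n_workflows` and
#'   `rand_index` (`NA` for strata with fewer than two workflows).
#' @export
ri_by_task_count <- function(ws, part) {
  ref <- reference_partition(ws)
  sizes <- vapply(ws$workflows, function(w) length(w$instances), 0L)
  out <- lapply(sort(unique(sizes)), function(s) {
    ids <- workflow_ids(ws)[sizes == s]
    ri <- if (length(ids) >= 2L)
      rand_index(part$labels[ids], ref$labels[ids]) else NA_real_
    data.frame(n_tasks = s, n_workflows = length(ids), rand_index = ri)
  })
  do.call(rbind, out)
}
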