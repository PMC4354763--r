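# Pairwise (PS) and global (PSG) clustering-stability indices accumulated
# over Q independent randomized runs. Off-diagonal PS(i,j) is the fraction
# of runs in which i and j are co-clustered; diagonal PS(i) is the fraction
# of runs in which i forms a singleton cluster. PSG aggregates
# max(PS, 1 - PS) over all pairs and singleton supports:
#
#   PSG(W)  = (2 * sum_{i<j} max(PS_ij, 1-PS_ij)
#              + sum_i max(PS_i, 1-PS_i)) / n^2
#   PSG(w_i) = (sum_{j != i} max(PS_ij, 1-PS_ij)
#              + max(PS_i, 1-PS_i)) / n
#
# Both range from 0.5 (maximal instability) to 1 (every pair always
# co-clustered or always separated, every element always or never
# singleton). The n^2 normalization applies the factor 2 to the pairwise
# sum only, which is the unique scaling under which the stated [0.5, 1]
# range holds.

#' Pairwise support matrix from a collection of runs
#'
#' @param runs List of `wf_partition` objects (or `wf_cluster_run`s, whose
#'   partitions are taken), all over the same ordered id list.
#' @return Symmetric n x n matrix with entries in `[0, 1]`: co-clustering
#'   fractions off the diagonal, singleton fractions on it.
#' @export
pairwise_support <- function(runs) {
  stopifnot(length(runs) >= 1L)
  parts <- lapply(runs, function(r)
    if (inherits(r, "wf_cluster_run")) r$partition else r)
  ids <- parts[[1L]]$ids
  for (p in parts)
    if (!identical(p$ids, ids)) stop("inconsistent id lists across runs")
  n <- length(ids)
  ps <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in parts) {
    co <- outer(p$labels, p$labels, "==")
    diag(co) <- p$sizes[p$labels] == 1L   # singleton indicator
    ps <- ps + co
  }
  ps / length(parts)
}

#' Global PSG stability score
#'
#' @param ps Support matrix from [pairwise_support()].
#' @return Value in `[0.5, 1]`; 1 means every co-clustering relation was
#'   identical across all runs.
#' @export
psg_global <- function(ps) {
  n <- nrow(ps)
  off <- ps[upper.tri(ps)]
  dg <- diag(ps)
  (2 * sum(pmax(off, 1 - off)) + sum(pmax(dg, 1 - dg))) / n^2
}

#' Individual PSG stability score(s)
#'
#' @param ps Support matrix from [pairwise_support()].
#' @param i Element index or id; `NULL` (default) returns all elements.
#' @return Value(s) in `[0.5, 1]`, named by element id.
#' @export
psg_individual <- function(ps, i = NULL) {
  n <- nrow(ps)
  one <- function(ii) {
    off <- ps[ii, -ii]
    (sum(pmax(off, 1 - off)) + max(ps[ii, ii], 1 - ps[ii, ii])) / n
  }
  if (!is.null(i)) {
    if (is.character(i)) i <- match(i, rownames(ps))
    return(one(i))
  }
  stats::setNames(vapply(seq_len(n), one, 0), rownames(ps))
}

#' Stability analysis over repeated randomized clustering runs
#'
#' Executes `Q` independent runs. In each run every candidate K in
#' `k_min..k_max` is fitted from a single random starting partition
#' (`n_starts_per_k` starts, default 1 — each run *is* one random start),
#' the run's K is selected by the validity index, and the resulting
#' partition is recorded. The PS matrix and PSG scores are assembled from
#' the `Q` recorded partitions.
#'
#' @param enc A `wf_encoding`.
#' @param algorithm,metric,index,k_min,k_max,max_iter As in [select_k()].
#' @param Q Number of independent runs.
#' @param seed Optional integer seed; identical seeds give identical
#'   results.
#' @param n_starts_per_k Random starts per candidate K within one run.
#' @return An object of class `"wf_stability"`: list with `ids`, `ps`
#'   (support matrix, diagonal = singleton support), `psg_global`,
#'   `psg_individual`, `chosen_k` (per-run selected K), `Q` and settings.
#' @export
stability_run <- function(enc, algorithm = c("kmeans", "kmedoids"),
                          metric = c("euclidean", "cosine"),
                          index = c("CH", "SI", "logSS"),
                          k_min = 2L, k_max = NULL, Q = 100L, seed = NULL,
                          n_starts_per_k = 1L, max_iter = 300L) {
  algorithm <- match.arg(algorithm)
  metric <- match.arg(metric)
  index <- match.arg(index)
  stopifnot(Q >= 1L)
  n <- length(enc$workflow_ids)
  if (is.null(k_max)) k_max <- n - 1L
  if (k_min < 2L || k_max > n - 1L || k_min > k_max)
    stop("need 2 <= k_min <= k_max <= n - 1")
  if (!is.null(seed)) set.seed(seed)
  fit <- if (algorithm == "kmeans") kmeans_weighted else kmedoids_weighted
  ks <- k_min:k_max
  parts <- vector("list", Q)
  chosen <- integer(Q)
  for (q in seq_len(Q)) {
    vals <- numeric(length(ks))
    runs <- vector("list", length(ks))
    for (a in seq_along(ks)) {
      runs[[a]] <- fit(enc, ks[a], metric = metric,
                       n_starts = n_starts_per_k, max_iter = max_iter)
      vals[a] <- .index_of_run(enc, runs[[a]], index)
    }
    kq <- if (index == "logSS")
      logss_choose_k(stats::setNames(vals, ks)) else ks[which.max(vals)]
    chosen[q] <- kq
    parts[[q]] <- runs[[match(kq, ks)]]$partition
  }
  ps <- pairwise_support(parts)
  structure(list(ids = enc$workflow_ids, ps = ps,
                 psg_global = psg_global(ps),
                 psg_individual = psg_individual(ps),
                 chosen_k = chosen, Q = Q,
                 settings = list(algorithm = algorithm, metric = metric,
                                 index = index, k_min = k_min,
                                 k_max = k_max, seed = seed,
                                 n_starts_per_k = n_starts_per_k)),
            class = "wf_stability")
}

#' @export
print.wf_stability <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Clustering stability over Q = %d runs (%s, %s, %s, K in %d..%d)\n",
    x$Q, s$algorithm, s$metric, s$index, s$k_min, s$k_max))
  cat("PS matrix (diagonal = singleton support):\n")
  print(round(x$ps, 3))
  cat(sprintf("global PSG = %.3f\n", x$psg_global))
  cat("individual PSG:\n")
  print(round(x$psg_individual, 3))
  invisible(x)
}

#' @export
plot.wf_stability <- function(x, ...) {
  n <- nrow(x$ps)
  graphics::image(seq_len(n), seq_len(n), t(x$ps[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Pairwise support (PS)", zlim = c(0, 1), ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(x$ps), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(x$ps)), las = 2)
  invisible(x)
}

#' Write a PS support matrix as square CSV
#' @param x A `wf_stability` (or its `ps` matrix).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ps_csv <- function(x, path) {
  ps <- if (inherits(x, "wf_stability")) x$ps else x
  utils::write.csv(as.data.frame(ps), path, row.names = TRUE)
  invisible(path)
}

#' Write a stability report as JSON
#' @param x A `wf_stability`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stability_json <- function(x, path) {
  jsonlite::write_json(
    list(Q = x$Q, psg_global = x$psg_global,
         psg_individual = as.list(x$psg_individual),
         settings = x$settings[!vapply(x$settings, is.null, NA)]),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
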