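# Weighted k-means and k-medoids partitioning under the weighted Euclidean
# or cosine distance, with a best-of-random-starts protocol. Every random
# start is a random initial *partition* (uniform labels repaired to
# non-empty clusters), not a seeding of centers.

#' Create a partition object
#'
#' @param ids Workflow ids.
#' @param labels Integer cluster labels, one per id. Relabelled to
#'   `1..K` in order of first appearance.
#' @return A list of class `"wf_partition"` with fields `ids`, `labels`,
#'   `K` and `sizes`.
#' @export
wf_partition <- function(ids, labels) {
  stopifnot(length(ids) == length(labels), !anyNA(labels))
  labels <- match(labels, unique(labels))
  K <- max(labels)
  structure(list(ids = as.character(ids),
                 labels = stats::setNames(as.integer(labels),
                                          as.character(ids)),
                 K = K, sizes = tabulate(labels, K)),
            class = "wf_partition")
}

#' @export
print.wf_partition <- function(x, ...) {
  cat(sprintf("Partition of %d workflows into %d clusters\n",
              length(x$ids), x$K))
  for (k in seq_len(x$K))
    cat(sprintf("  cluster %d: {%s}\n", k,
                paste(x$ids[x$labels == k], collapse = ", ")))
  invisible(x)
}

#' Write a partition as CSV
#' @param part A `wf_partition`.
#' @param path Output file; columns `workflow_id,cluster`.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(part, path) {
  utils::write.csv(data.frame(workflow_id = part$ids,
                              cluster = unname(part$labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Within-cluster dispersion objective
#'
#' The partitioning objective: the sum over clusters of all ordered-pair
#' squared distances within the cluster, each cluster's sum divided by its
#' size. For the Euclidean metric this equals twice the within-cluster sum
#' of squared distances to the centroid.
#'
#' @param enc A `wf_encoding`, or a precomputed `wf_dist`/matrix.
#' @param part A `wf_partition` over the same workflows.
#' @param metric Distance metric (ignored when `enc` is already a matrix).
#' @return Non-negative objective value.
#' @export
clustering_objective <- function(enc, part,
                                 metric = c("euclidean", "cosine")) {
  D <- if (inherits(enc, "wf_encoding"))
    distance_matrix(enc, match.arg(metric)) else enc
  .objective_from_D(unclass(D), part$labels)
}

.objective_from_D <- function(D, labels) {
  s <- 0
  for (k in unique(labels)) {
    idx <- which(labels == k)
    s <- s + sum(D[idx, idx]^2) / length(idx)
  }
  s
}

# squared weighted distances from all columns of X to center vector c
.sqdist_to_center <- function(X, y, cen, metric) {
  if (metric == "euclidean") return(colSums(y * (X - cen)^2))
  ncen <- sqrt(sum(y * cen^2))
  nrm <- sqrt(colSums(y * X^2))
  d <- if (ncen == 0) as.numeric(nrm > 0) else {
    out <- 1 - colSums(y * X * cen) / (nrm * ncen)
    out[nrm == 0] <- 1
    out
  }
  pmax(d, 0)^2
}

# Move, for each empty cluster, the element farthest from its current
# center (centroid of its cluster) into the empty cluster; ties broken by
# lowest element index. Keeps K fixed.
.repair_empty <- function(labels, K, X, y, metric) {
  repeat {
    sizes <- tabulate(labels, K)
    empty <- which(sizes == 0L)
    if (!length(empty)) return(labels)
    k <- empty[[1L]]
    dist_own <- rep(-Inf, length(labels))
    for (g in which(sizes >= 2L)) {
      idx <- which(labels == g)
      cen <- rowMeans(X[, idx, drop = FALSE])
      dist_own[idx] <- .sqdist_to_center(X[, idx, drop = FALSE], y, cen,
                                         metric)
    }
    mv <- which.max(dist_own)     # ties -> lowest index
    labels[mv] <- k
  }
}

.lloyd_once <- function(X, y, K, metric, max_iter) {
  n <- ncol(X)
  labels <- sample.int(K, n, replace = TRUE)
  labels <- .repair_empty(labels, K, X, y, metric)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    centers <- vapply(seq_len(K), function(k)
      rowMeans(X[, labels == k, drop = FALSE]), numeric(nrow(X)))
    centers <- matrix(centers, nrow = nrow(X))
    d2 <- vapply(seq_len(K), function(k)
      .sqdist_to_center(X, y, centers[, k], metric), numeric(n))
    new_labels <- max.col(-matrix(d2, nrow = n), ties.method = "first")
    new_labels <- .repair_empty(new_labels, K, X, y, metric)
    if (identical(new_labels, labels) || iter >= max_iter) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  list(labels = labels, centers = centers, iter = iter)
}

new_cluster_run <- function(ids, labels, objective, centers, center_kind,
                            iter, algorithm, metric, seed) {
  structure(list(partition = wf_partition(ids, labels),
                 objective = objective,
                 centers = centers, center_kind = center_kind,
                 n_iterations = iter, algorithm = algorithm,
                 metric = metric, seed = seed),
            class = "wf_cluster_run")
}

#' @export
print.wf_cluster_run <- function(x, ...) {
  cat(sprintf("%s (%s) run: K = %d, objective = %.6g, %d iteration(s)\n",
              x$algorithm, x$metric, x$partition$K, x$objective,
              x$n_iterations))
  print(x$partition)
  invisible(x)
}

#' Weighted k-means partitioning
#'
#' Lloyd-style iteration from random starting partitions: cluster centers
#' are per-variable arithmetic means of the member columns, elements are
#' reassigned to the nearest center under the chosen weighted metric, and
#' empty clusters are repaired by moving in the element farthest from its
#' own center. Of `n_starts` independent starts the run with the lowest
#' dispersion objective (see [clustering_objective()]) is returned.
#'
#' @param enc A `wf_encoding`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param n_starts Number of random starting partitions.
#' @param max_iter Iteration cap per start.
#' @param seed Optional integer seed; results are reproducible given it.
#' @return A `wf_cluster_run` with the best partition, its objective,
#'   the centroid matrix and iteration count.
#' @export
kmeans_weighted <- function(enc, k, metric = c("euclidean", "cosine"),
                            n_starts = 1L, max_iter = 300L, seed = NULL) {
  metric <- match.arg(metric)
  e <- .enc_xy(enc)
  n <- ncol(e$X)
  if (k < 1L || k > n) stop("k must be between 1 and the number of workflows")
  stopifnot(n_starts >= 1L)
  if (!is.null(seed)) set.seed(seed)
  D <- .wdist_matrix(e$X, e$y, metric)
  best <- NULL
  for (s in seq_len(n_starts)) {
    r <- .lloyd_once(e$X, e$y, k, metric, max_iter)
    obj <- .objective_from_D(D, r$labels)
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(labels = r$labels, objective = obj, iter = r$iter)
  }
  # centroids in the order of first appearance, matching the relabelled
  # partition returned by wf_partition()
  centers <- vapply(unique(best$labels), function(g)
    rowMeans(e$X[, best$labels == g, drop = FALSE]), numeric(nrow(e$X)))
  centers <- matrix(centers, nrow = nrow(e$X),
                    dimnames = list(rownames(e$X), NULL))
  new_cluster_run(enc$workflow_ids, best$labels, best$objective,
                  centers, "centroid", best$iter, "kmeans", metric,
                  seed)
}

#' Weighted k-medoids partitioning
#'
#' Voronoi-iteration k-medoids: distinct random initial medoids, assignment
#' of every element to its nearest medoid, then medoid update as the
#' cluster member minimizing the within-cluster distance sum (ties broken
#' by lowest index), iterated to a fixed point. Best of `n_starts` by the
#' dispersion objective.
#'
#' @inheritParams kmeans_weighted
#' @return A `wf_cluster_run`; `centers` holds the medoid ids.
#' @export
kmedoids_weighted <- function(enc, k, metric = c("euclidean", "cosine"),
                              n_starts = 1L, max_iter = 300L, seed = NULL) {
  metric <- match.arg(metric)
  e <- .enc_xy(enc)
  n <- ncol(e$X)
  if (k < 1L || k > n) stop("k must be between 1 and the number of workflows")
  stopifnot(n_starts >= 1L)
  if (!is.null(seed)) set.seed(seed)
  D <- .wdist_matrix(e$X, e$y, metric)
  best <- NULL
  for (s in seq_len(n_starts)) {
    med <- sort(sample.int(n, k))
    iter <- 0L
    repeat {
      iter <- iter + 1L
      labels <- max.col(-D[, med, drop = FALSE], ties.method = "first")
      labels[med] <- seq_len(k)     # a medoid anchors its own cluster
      new_med <- vapply(seq_len(k), function(g) {
        idx <- which(labels == g)
        idx[which.min(colSums(D[idx, idx, drop = FALSE]))]
      }, 0L)
      if (identical(sort(new_med), sort(med)) || iter >= max_iter) {
        med <- new_med
        break
      }
      med <- new_med
    }
    labels <- max.col(-D[, med, drop = FALSE], ties.method = "first")
    labels[med] <- seq_len(k)
    obj <- .objective_from_D(D, labels)
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(labels = labels, medoids = med, iter = iter,
                   objective = obj)
  }
  # medoids in first-appearance order of the relabelled partition
  med_ord <- best$medoids[match(unique(best$labels),
                                best$labels[best$medoids])]
  new_cluster_run(enc$workflow_ids, best$labels, best$objective,
                  enc$workflow_ids[med_ord], "medoid", best$iter,
                  "kmedoids", metric, seed)
}
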