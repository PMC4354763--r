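# Cluster validity indices used to select the number of clusters K:
# Calinski-Harabasz CH(K) = (SS_B/SS_W) * (n-K)/(K-1), logSS(K) =
# log(SS_B/SS_W), and the Silhouette width. SS_B and SS_W are computed with
# squared distances under the run's weighted metric; cluster centers are
# the run's centroids (k-means) or medoids (k-medoids), and the overall
# center is the grand centroid / global medoid accordingly.

# squared distance of each column of X to a center under the metric
.center_sq <- function(X, y, cen, metric) .sqdist_to_center(X, y, cen, metric)

.run_centers <- function(enc, run) {
  e <- .enc_xy(enc)
  K <- run$partition$K
  if (run$center_kind == "medoid") {
    med_idx <- match(run$centers, enc$workflow_ids)
    centers <- e$X[, med_idx, drop = FALSE]
    # global medoid: element minimizing its total distance to all others
    D <- .wdist_matrix(e$X, e$y, run$metric)
    grand <- e$X[, which.min(colSums(D))]
  } else {
    centers <- run$centers
    grand <- rowMeans(e$X)
  }
  list(centers = centers, grand = grand)
}

.ss_decomposition <- function(enc, run) {
  e <- .enc_xy(enc)
  labels <- run$partition$labels
  K <- run$partition$K
  cc <- .run_centers(enc, run)
  ss_b <- 0; ss_w <- 0
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    cen <- cc$centers[, k]
    ss_b <- ss_b + length(idx) *
      .center_sq(matrix(cen, ncol = 1), e$y, cc$grand, run$metric)
    ss_w <- ss_w + sum(.center_sq(e$X[, idx, drop = FALSE], e$y, cen,
                                  run$metric))
  }
  list(ss_b = as.numeric(ss_b), ss_w = as.numeric(ss_w))
}

#' Calinski-Harabasz index of a clustering run
#'
#' Ratio of between- to within-cluster dispersion, scaled by
#' `(n - K)/(K - 1)`. Higher is better; the K maximizing CH is selected.
#'
#' @param enc The `wf_encoding` the run was fitted on.
#' @param run A `wf_cluster_run` with `2 <= K <= n - 1`.
#' @return The CH value.
#' @export
ch_index <- function(enc, run) {
  n <- length(run$partition$ids)
  K <- run$partition$K
  if (K < 2L || K > n - 1L) stop("CH requires 2 <= K <= n - 1")
  ss <- .ss_decomposition(enc, run)
  if (ss$ss_w <= 0) stop("degenerate: zero within-cluster variance")
  (ss$ss_b / ss$ss_w) * (n - K) / (K - 1)
}

#' logSS index of a clustering run
#'
#' Natural logarithm of the between/within dispersion ratio,
#' `log(SS_B / SS_W)`. Only differences between successive K matter for
#' model selection, so the base of the logarithm affects reported values
#' only.
#'
#' @inheritParams ch_index
#' @return The logSS value.
#' @export
logss_index <- function(enc, run) {
  ss <- .ss_decomposition(enc, run)
  if (ss$ss_w <= 0 || ss$ss_b <= 0)
    stop("degenerate: zero within- or between-cluster variance")
  log(ss$ss_b / ss$ss_w)
}

#' Select K from a sequence of logSS values
#'
#' The chosen K minimizes the consecutive difference
#' `logSS(K + 1) - logSS(K)` over the scanned K (signed difference as the
#' selection rule is stated; set `absolute = TRUE` for the |difference|
#' variant). Ties go to the smaller K; a single scanned K is returned
#' as is.
#'
#' @param per_k Named numeric vector of logSS values; names are the K's,
#'   which must be consecutive integers.
#' @param absolute Use the absolute difference instead of the signed one.
#' @return The selected K (integer).
#' @export
logss_choose_k <- function(per_k, absolute = FALSE) {
  ks <- as.integer(names(per_k))
  if (length(ks) == 0L) stop("empty scan range")
  if (length(ks) == 1L) return(ks)
  if (any(diff(ks) != 1L)) stop("scanned K values must be consecutive")
  d <- diff(unname(per_k))
  if (absolute) d <- abs(d)
  ks[which.min(d)]   # which.min ties -> first, i.e. smaller K
}

#' Mean Silhouette width of a partition
#'
#' For element i, `a(i)` is its mean distance to co-members and `b(i)` the
#' smallest mean distance to another cluster; the width is
#' `(b - a)/max(a, b)`, with 0 for members of singleton clusters (and when
#' `a = b = 0`). The returned score macro-averages the per-cluster mean
#' widths `s(k)` over clusters; `per_point = TRUE` gives the more common
#' per-element mean instead.
#'
#' @param enc A `wf_encoding` or a precomputed distance matrix.
#' @param part A `wf_partition` with `2 <= K <= n - 1`.
#' @param metric Metric used when `enc` is an encoding.
#' @param per_point Average over elements instead of clusters.
#' @return Mean Silhouette width in `[-1, 1]`.
#' @export
silhouette_index <- function(enc, part, metric = c("euclidean", "cosine"),
                             per_point = FALSE) {
  D <- if (inherits(enc, "wf_encoding"))
    unclass(distance_matrix(enc, match.arg(metric))) else unclass(enc)
  labels <- part$labels
  n <- length(labels)
  K <- part$K
  if (K < 2L) stop("silhouette requires K >= 2")
  s_i <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s_i[i] <- 0; next }
    a <- sum(D[i, own]) / (length(own) - 1L)
    b <- min(vapply(setdiff(seq_len(K), labels[i]), function(k)
      mean(D[i, labels == k]), 0))
    s_i[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  if (per_point) return(mean(s_i))
  mean(vapply(seq_len(K), function(k) mean(s_i[labels == k]), 0))
}

.index_of_run <- function(enc, run, index, D = NULL) {
  switch(index,
         CH = ch_index(enc, run),
         logSS = logss_index(enc, run),
         SI = silhouette_index(if (is.null(D)) enc else D, run$partition,
                               metric = run$metric))
}

#' Fit partitions over a range of K and select the best K
#'
#' The central model-selection routine: for each K in `k_min..k_max` the
#' best of `n_starts` random-start runs (by the dispersion objective) is
#' retained and its validity index computed; K is then chosen by the
#' index's rule — argmax for CH and Silhouette, the smallest consecutive
#' difference for logSS.
#'
#' @param enc A `wf_encoding`.
#' @param algorithm `"kmeans"` or `"kmedoids"`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param index `"CH"`, `"SI"` or `"logSS"`.
#' @param k_min,k_max Scan range, `2 <= k_min <= k_max <= n - 1`.
#' @param n_starts Random starts per K.
#' @param max_iter Iteration cap per start.
#' @param seed Optional integer seed.
#' @param logss_absolute Passed to [logss_choose_k()].
#' @return An object of class `"wf_kselect"`: list with `per_k`
#'   (data.frame of K, index value, objective, SS_B, SS_W), `runs`,
#'   `chosen_k`, `chosen_partition` and the settings.
#' @seealso [kmeans_weighted()], [kmedoids_weighted()], [ch_index()]
#' @export
select_k <- function(enc, algorithm = c("kmeans", "kmedoids"),
                     metric = c("euclidean", "cosine"),
                     index = c("CH", "SI", "logSS"),
                     k_min = 2L, k_max = NULL, n_starts = 100L,
                     max_iter = 300L, seed = NULL, logss_absolute = FALSE) {
  algorithm <- match.arg(algorithm)
  metric <- match.arg(metric)
  index <- match.arg(index)
  n <- length(enc$workflow_ids)
  if (is.null(k_max)) k_max <- n - 1L
  if (k_min < 2L || k_max > n - 1L || k_min > k_max)
    stop("need 2 <= k_min <= k_max <= n - 1")
  if (!is.null(seed)) set.seed(seed)
  fit <- if (algorithm == "kmeans") kmeans_weighted else kmedoids_weighted
  ks <- k_min:k_max
  runs <- vector("list", length(ks))
  vals <- ssb <- ssw <- obj <- numeric(length(ks))
  for (a in seq_along(ks)) {
    runs[[a]] <- fit(enc, ks[a], metric = metric, n_starts = n_starts,
                     max_iter = max_iter)
    vals[a] <- .index_of_run(enc, runs[[a]], index)
    ss <- .ss_decomposition(enc, runs[[a]])
    ssb[a] <- ss$ss_b; ssw[a] <- ss$ss_w
    obj[a] <- runs[[a]]$objective
  }
  chosen <- if (index == "logSS")
    logss_choose_k(stats::setNames(vals, ks), absolute = logss_absolute)
  else ks[which.max(vals)]
  structure(list(per_k = data.frame(K = ks, index = vals, objective = obj,
                                    ss_b = ssb, ss_w = ssw),
                 runs = stats::setNames(runs, ks),
                 chosen_k = chosen,
                 chosen_partition = runs[[match(chosen, ks)]]$partition,
                 index_name = index, metric = metric,
                 algorithm = algorithm, n_starts = n_starts, seed = seed),
            class = "wf_kselect")
}

#' @export
print.wf_kselect <- function(x, ...) {
  cat(sprintf("K selection by %s (%s, %s, %d starts per K)\n",
              x$index_name, x$algorithm, x$metric, x$n_starts))
  tab <- x$per_k
  tab$index <- signif(tab$index, 6)
  tab$objective <- signif(tab$objective, 6)
  print(tab, row.names = FALSE)
  cat(sprintf("chosen K = %d\n", x$chosen_k))
  print(x$chosen_partition)
  invisible(x)
}

#' @export
summary.wf_kselect <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.wf_kselect <- function(x, ...) {
  graphics::plot(x$per_k$K, x$per_k$index, type = "b", xlab = "K",
                 ylab = x$index_name,
                 main = sprintf("%s across K (%s, %s)", x$index_name,
                                x$algorithm, x$metric), ...)
  graphics::abline(v = x$chosen_k, lty = 2)
  invisible(x)
}
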