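# Weighted Euclidean and weighted cosine distances over an encoding.
# d_euc(i,j) = sqrt( sum_p y_p (w_ip - w_jp)^2 )
# d_cos(i,j) = 1 - sum_p y_p w_ip w_jp / (||w_i||_y ||w_j||_y)
# Zero-norm convention for the cosine: if exactly one column has zero
# weighted norm the distance is 1; if both, 0. This keeps the distance
# total and symmetric on degenerate input.

.enc_xy <- function(enc) {
  stopifnot(inherits(enc, "wf_encoding"))
  list(X = enc$matrix, y = enc$weights)
}

.wdist_cols <- function(a, b, y, metric) {
  if (metric == "euclidean") return(sqrt(sum(y * (a - b)^2)))
  na <- sqrt(sum(y * a^2)); nb <- sqrt(sum(y * b^2))
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(1)
  1 - sum(y * a * b) / (na * nb)
}

#' Weighted Euclidean distance between two workflows
#'
#' @param enc A `wf_encoding`.
#' @param i,j Workflow indices or ids.
#' @return Non-negative distance.
#' @export
weighted_euclidean <- function(enc, i, j) {
  e <- .enc_xy(enc)
  i <- .col_index(enc, i); j <- .col_index(enc, j)
  .wdist_cols(e$X[, i], e$X[, j], e$y, "euclidean")
}

#' Weighted cosine distance between two workflows
#'
#' For non-negative data the value lies in `[0, 1]`; it is invariant to
#' positive rescaling of either column.
#'
#' @inheritParams weighted_euclidean
#' @return Distance in `[0, 2]` (at most 1 for non-negative matrices).
#' @export
weighted_cosine <- function(enc, i, j) {
  e <- .enc_xy(enc)
  i <- .col_index(enc, i); j <- .col_index(enc, j)
  .wdist_cols(e$X[, i], e$X[, j], e$y, "cosine")
}

.col_index <- function(enc, i) {
  if (is.character(i)) i <- match(i, enc$workflow_ids)
  if (is.na(i) || i < 1L || i > length(enc$workflow_ids))
    stop("invalid workflow index")
  as.integer(i)
}

# Fast full matrix from columns X (variables x n) and weights y.
.wdist_matrix <- function(X, y, metric) {
  n <- ncol(X)
  Xw <- X * sqrt(y)
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(t(Xw)))
  } else if (metric == "cosine") {
    G <- crossprod(Xw)                    # weighted inner products
    nrm <- sqrt(diag(G))
    D <- 1 - G / outer(nrm, nrm)
    zero <- nrm == 0
    if (any(zero)) {
      D[zero, ] <- 1; D[, zero] <- 1
      D[zero, zero] <- 0
    }
    diag(D) <- 0
    D[D < 0] <- 0                          # guard rounding
  } else stop("unknown metric: ", metric)
  dimnames(D) <- list(colnames(X), colnames(X))
  D
}

#' All pairwise weighted distances of an encoding
#'
#' @param enc A `wf_encoding` with at least two workflows.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return A symmetric matrix of class `"wf_dist"` with zero diagonal,
#'   workflow ids as dimnames and the metric in `attr(, "metric")`.
#' @export
distance_matrix <- function(enc, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  e <- .enc_xy(enc)
  if (ncol(e$X) < 2L) stop("need at least two workflows")
  D <- .wdist_matrix(e$X, e$y, metric)
  structure(D, metric = metric, class = c("wf_dist", "matrix"))
}

#' @export
print.wf_dist <- function(x, ...) {
  cat(sprintf("%s distance matrix over %d workflows\n",
              attr(x, "metric"), nrow(x)))
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Write a distance matrix as square CSV
#'
#' @param D A `wf_dist` (or square matrix with dimnames).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dist_csv <- function(D, path) {
  utils::write.csv(as.data.frame(unclass(D)), path, row.names = TRUE)
  invisible(path)
}

#' Read a square distance matrix from CSV
#'
#' @param path CSV written by [write_dist_csv()] (row and column ids).
#' @param metric Metric tag to attach.
#' @return A `wf_dist`.
#' @export
read_dist_csv <- function(path, metric = "euclidean") {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("not a symmetric square matrix")
  structure(D, metric = metric, class = c("wf_dist", "matrix"))
}

#' Write a distance matrix in PHYLIP square format
#'
#' Plain-text format consumed by classic distance-based tree programs:
#' first line the number of taxa, then one row per taxon with the name
#' padded to 10 characters followed by the distances.
#'
#' @param D Square distance matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  D <- unclass(D)
  n <- nrow(D)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  nm <- substr(sprintf("%-10s", rownames(D)), 1, 10)
  for (i in seq_len(n))
    writeLines(paste0(nm[i], paste(sprintf("%.6f", D[i, ]),
                                   collapse = "  ")), con)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path File in the format written by [write_phylip_dist()].
#' @return A `wf_dist` (metric tag `"unknown"`).
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[[1L]]))
  if (is.na(n) || length(lines) < n + 1L) stop("malformed PHYLIP matrix")
  nm <- character(n); D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ln <- lines[[i + 1L]]
    nm[i] <- trimws(substr(ln, 1, 10))
    vals <- as.numeric(strsplit(trimws(substring(ln, 11)), "\\s+")[[1L]])
    if (length(vals) != n) stop("malformed PHYLIP matrix row ", i)
    D[i, ] <- vals
  }
  dimnames(D) <- list(nm, nm)
  structure(D, metric = "unknown", class = c("wf_dist", "matrix"))
}
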