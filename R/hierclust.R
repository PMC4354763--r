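# Hierarchical classification of workflow collections: UPGMA (ultrametric)
# and neighbor-joining (additive) trees from a distance matrix, the
# weighted least-squares tree fit score, multifurcating reference trees
# from class labels, Newick I/O and the Robinson-Foulds topological
# distance. Trees are ape "phylo" objects throughout.

.as_square <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("need a square distance matrix")
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix is not symmetric")
  if (is.null(rownames(D))) dimnames(D) <- list(seq_len(nrow(D)),
                                                seq_len(nrow(D)))
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree: all
#' root-to-leaf path lengths are equal, and an ultrametric input matrix is
#' reproduced exactly by the tree's path lengths.
#'
#' @param D A `wf_dist` or square symmetric matrix with dimnames.
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma <- function(D) {
  D <- .as_square(D)
  if (nrow(D) < 2L) stop("need at least two elements")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ on the rate-corrected Q criterion; the returned tree is
#' unrooted and additive: any input satisfying the four-point condition is
#' reproduced exactly by the tree's path lengths. Negative branch lengths
#' can occur on non-additive input; they are preserved and flagged with a
#' warning rather than clamped, so that distance reproduction stays exact.
#'
#' @param D A `wf_dist` or square symmetric matrix with dimnames; at least
#'   three elements.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- .as_square(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least three elements")
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < -1e-12))
    warning("NJ produced negative branch lengths (non-additive input)")
  tr
}

#' Weighted least-squares fit of a tree to a distance matrix
#'
#' `sum_{i<j} (delta_ij - d_ij)^2 / d_ij^p`, where `delta_ij` is the path
#' length between leaves i and j in the tree and `d_ij` the observed
#' distance. `p = 2` is the classic Fitch/Kitsch weighting; `p = 0` gives
#' ordinary (unweighted) least squares. The score is 0 exactly when the
#' tree reproduces the matrix.
#'
#' @param tree A `phylo` tree whose tip labels match `D`'s ids.
#' @param D Square symmetric distance matrix.
#' @param p Weighting exponent (default 2).
#' @return Non-negative fit score.
#' @export
ls_fit_score <- function(tree, D, p = 2) {
  D <- .as_square(D)
  if (!setequal(tree$tip.label, rownames(D)))
    stop("tree leaves do not match the distance matrix ids")
  delta <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  ut <- upper.tri(D)
  if (p > 0 && any(D[ut] <= 0))
    stop("undefined weight: zero off-diagonal distance with p > 0")
  sum((delta[ut] - D[ut])^2 / D[ut]^p)
}

#' Multifurcating reference tree from class labels
#'
#' Builds the reference classification tree used to benchmark hierarchical
#' clusterings: a root with one multifurcating child node per class, whose
#' children are the class's elements; classes with a single member attach
#' their leaf directly to the root. All edges have unit length (only the
#' topology matters for Robinson-Foulds comparison).
#'
#' @param labels Named character vector mapping element id to class label;
#'   at least two classes, each non-empty.
#' @return A rooted `phylo` tree, generally non-binary.
#' @export
reference_tree <- function(labels) {
  if (is.factor(labels)) {
    if (any(table(labels) == 0L)) stop("a class with zero members")
    labels <- stats::setNames(as.character(labels), names(labels))
  }
  ids <- names(labels)
  if (is.null(ids) || any(!nzchar(ids))) stop("labels must be named by id")
  bad <- grepl("[,():;\\[\\]\"' \t]", ids)
  if (any(bad)) stop("element ids contain Newick metacharacters: ",
                     ids[bad][1L])
  classes <- split(ids, labels)
  if (length(classes) < 2L) stop("need at least two classes")
  grp <- vapply(classes, function(m) {
    if (length(m) == 1L) paste0(m, ":1")
    else paste0("(", paste0(m, ":1", collapse = ","), "):1")
  }, "")
  ape::read.tree(text = paste0("(", paste(grp, collapse = ","), ");"))
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the two trees' non-trivial
#' bipartition sets, computed on unrooted topologies; the maximum is
#' `2(n - 3)` for two binary trees on n leaves.
#'
#' @param t1,t2 `phylo` trees over identical leaf sets.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have mismatched leaf sets")
  as.integer(suppressMessages(
    phangorn::RF.dist(t1, t2, check.labels = TRUE, rooted = FALSE)))
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` tree.
#' @param path Optional file; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse a Newick tree
#'
#' @param text Newick string, or `NULL` when reading from `path`.
#' @param path Optional file to read instead of `text`.
#' @return A `phylo` tree; malformed input raises an error.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick input")
  tr
}
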