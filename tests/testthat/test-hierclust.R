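# random ultrametric / additive matrices are built from random trees, so
# the reconstruction checks have known ground truth
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

random_ultrametric <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

test_that("UPGMA agglomerates the three-point example as expected", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  expect_equal(ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")],
               D, tolerance = 1e-12)
  # ((A:1,B:1):1,C:2) topology: A and B form the cherry
  expect_equal(rf_distance(tr, parse_newick("((A:1,B:1):1,C:2);")), 0L)
})

test_that("UPGMA output is ultrametric and recovers ultrametric input", {
  for (seed in 1:4) {
    ru <- random_ultrametric(sample(6:10, 1), seed)
    tr <- upgma(ru$D)
    cph <- ape::cophenetic.phylo(tr)[rownames(ru$D), colnames(ru$D)]
    expect_equal(cph, ru$D, tolerance = 1e-9)
    # equal root-to-leaf depths
    depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    expect_lt(diff(range(depths)), 1e-9)
  }
  # n = 2: a single cherry with half the distance on each branch
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  t2 <- upgma(D2)
  expect_equal(sort(t2$edge.length), c(1.5, 1.5))
})

test_that("neighbor joining exactly recovers additive distances", {
  for (seed in 1:4) {
    ra <- random_additive(sample(6:10, 1), seed)
    tr <- neighbor_joining(ra$D)
    cph <- ape::cophenetic.phylo(tr)[rownames(ra$D), colnames(ra$D)]
    expect_equal(cph, ra$D, tolerance = 1e-9)
    expect_equal(rf_distance(tr, ra$tree), 0L)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)), "three")
})

test_that("least-squares fit score follows the weighted formula", {
  ra <- random_additive(6, 1)
  tr <- neighbor_joining(ra$D)
  expect_equal(ls_fit_score(tr, ra$D), 0, tolerance = 1e-12)
  # single pair: d = 1, delta = 2, p = 2 -> (2-1)^2/1 = 1
  D2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  t2 <- parse_newick("(A:1,B:1);")
  expect_equal(ls_fit_score(t2, D2, p = 2), 1)
  # p = 0 reduces to the unweighted sum of squared residuals
  D3 <- ra$D * 1.3
  delta <- ape::cophenetic.phylo(tr)[rownames(D3), colnames(D3)]
  ut <- upper.tri(D3)
  expect_equal(ls_fit_score(tr, D3, p = 0),
               sum((delta[ut] - D3[ut])^2), tolerance = 1e-9)
  # zero off-diagonal distances are rejected for p > 0
  D0 <- D2; D0["A", "B"] <- D0["B", "A"] <- 0
  expect_error(ls_fit_score(t2, D0), "undefined weight")
})

test_that("reference trees are multifurcating by class", {
  labels <- c(w1 = "a", w2 = "a", w3 = "b", w4 = "b", w5 = "c",
              w6 = "c", w7 = "d", w8 = "d")
  tr <- reference_tree(labels)
  expect_setequal(tr$tip.label, names(labels))
  # root has one child per class
  root <- length(tr$tip.label) + 1L
  expect_identical(sum(tr$edge[, 1] == root), 4L)
  expect_equal(rf_distance(tr, tr), 0L)
  # every element its own class -> star tree with no internal splits
  star <- reference_tree(c(w1 = "a", w2 = "b", w3 = "c", w4 = "d"))
  expect_identical(star$Nnode, 1L)
  expect_error(reference_tree(factor(c(w1 = "a", w2 = "b"),
                                     levels = c("a", "b", "empty"))),
               "zero members")
  expect_error(reference_tree(c(w1 = "a", w2 = "a")), "two classes")
})

test_that("Robinson-Foulds distance counts bipartition differences", {
  q1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  q2 <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rf_distance(q1, q1), 0L)
  expect_equal(rf_distance(q1, star), 1L)
  expect_equal(rf_distance(q1, q2), 2L)
  # metric properties on random trees: symmetry and triangle inequality
  ts <- lapply(1:3, function(s) random_additive(7, s + 10)$tree)
  for (i in 1:3) for (j in 1:3) {
    expect_identical(rf_distance(ts[[i]], ts[[j]]),
                     rf_distance(ts[[j]], ts[[i]]))
  }
  expect_lte(rf_distance(ts[[1]], ts[[3]]),
             rf_distance(ts[[1]], ts[[2]]) + rf_distance(ts[[2]], ts[[3]]))
  # max 2(n-3) for binary trees on n leaves
  expect_lte(rf_distance(ts[[1]], ts[[2]]), 2 * (7 - 3))
  expect_error(rf_distance(q1, parse_newick("(A:1,B:1,X:1);")),
               "mismatched leaf sets")
})

test_that("Newick text round-trips including multifurcations", {
  for (txt in c("((A:1,B:1):1,C:2);",
                "((w1:1,w2:1,w3:1):1,(w4:1,w5:1):1);")) {
    tr <- parse_newick(txt)
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(rf_distance(tr, tr2), 0L)
    expect_equal(sort(ape::cophenetic.phylo(tr2)),
                 sort(ape::cophenetic.phylo(tr)), tolerance = 1e-9)
  }
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(parse_newick("((A:1,B:1):1,C:2);"), path)
  expect_equal(rf_distance(parse_newick(path = path),
                           parse_newick("((A:1,B:1):1,C:2);")), 0L)
  expect_error(parse_newick("((A:1,B:1"), "malformed")
})

test_that("hierarchical methods consume fixture distance matrices", {
  D <- distance_matrix(fixture_encodings()$I, "cosine")
  tu <- upgma(D)
  tn <- neighbor_joining(D)
  expect_setequal(tu$tip.label, rownames(D))
  expect_setequal(tn$tip.label, rownames(D))
  expect_gte(ls_fit_score(tu, D), ls_fit_score(tu, D) * 0)  # finite, >= 0
  expect_true(is.finite(ls_fit_score(tn, D)))
})
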