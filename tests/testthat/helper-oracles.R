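# Shared fixtures and independent brute-force oracles. Every oracle here
# evaluates a formula directly (loops / enumeration), independently of the
# package's vectorized implementations.

fixture_encodings <- function() {
  ws <- figure1_fixture()
  rule <- keyword_rule("HGT")
  list(I = encode_type1(ws), II = encode_type2(ws, rule),
       III = encode_type3(ws), IV = encode_type4(ws, rule))
}

# small random encoding: m variables x n workflows, positive weights
random_encoding <- function(m = 8, n = 6, seed = 1, counts = FALSE) {
  set.seed(seed)
  X <- matrix(if (counts) stats::rpois(m * n, 1.2)
              else stats::rbinom(m * n, 1, 0.5), m, n)
  X[1, X[1, ] == 0] <- 1   # no all-zero column
  dimnames(X) <- list(sprintf("v%02d", seq_len(m)),
                      sprintf("s%d", seq_len(n)))
  wfclust:::new_wf_encoding("I", X, stats::runif(m, 0.1, 2), colnames(X))
}

# one-variable encoding from 1-D points (unit weight)
points_encoding <- function(x, ids = sprintf("p%d", seq_along(x))) {
  X <- matrix(x, nrow = 1, dimnames = list("v", ids))
  wfclust:::new_wf_encoding("I", X, 1, ids)
}

oracle_dist <- function(enc, i, j, metric) {
  X <- enc$matrix; y <- enc$weights
  if (metric == "euclidean") return(sqrt(sum(y * (X[, i] - X[, j])^2)))
  ni <- sqrt(sum(y * X[, i]^2)); nj <- sqrt(sum(y * X[, j]^2))
  if (ni == 0 && nj == 0) return(0)
  if (ni == 0 || nj == 0) return(1)
  1 - sum(y * X[, i] * X[, j]) / (ni * nj)
}

# ordered-pair dispersion objective, triple loop
oracle_objective <- function(enc, labels, metric) {
  n <- length(labels); s <- 0
  for (k in unique(labels)) {
    idx <- which(labels == k); sk <- 0
    for (i in idx) for (j in idx)
      sk <- sk + oracle_dist(enc, i, j, metric)^2
    s <- s + sk / length(idx)
  }
  s
}

oracle_sq <- function(enc, a, cen, metric) {
  y <- enc$weights; x <- enc$matrix[, a]
  if (metric == "euclidean") return(sum(y * (x - cen)^2))
  nx <- sqrt(sum(y * x^2)); nc <- sqrt(sum(y * cen^2))
  d <- if (nx == 0 && nc == 0) 0 else if (nx == 0 || nc == 0) 1 else
    1 - sum(y * x * cen) / (nx * nc)
  max(d, 0)^2
}

# CH from first principles with centroid centers
oracle_ch <- function(enc, labels, metric) {
  X <- enc$matrix; n <- ncol(X); K <- length(unique(labels))
  gm <- rowMeans(X)
  ssb <- ssw <- 0
  for (k in unique(labels)) {
    idx <- which(labels == k)
    cen <- rowMeans(X[, idx, drop = FALSE])
    e2 <- enc; e2$matrix <- cbind(enc$matrix, cen = cen)
    ssb <- ssb + length(idx) * oracle_sq(e2, ncol(e2$matrix), gm, metric)
    for (i in idx) ssw <- ssw + oracle_sq(enc, i, cen, metric)
  }
  (ssb / ssw) * (n - K) / (K - 1)
}

oracle_silhouette <- function(enc, labels, metric, per_point = FALSE) {
  n <- length(labels)
  s_i <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s_i[i] <- 0; next }
    a <- mean(vapply(own, function(j) oracle_dist(enc, i, j, metric), 0))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k)
      mean(vapply(which(labels == k), function(j)
        oracle_dist(enc, i, j, metric), 0)), 0))
    s_i[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  if (per_point) return(mean(s_i))
  mean(vapply(unique(labels), function(k) mean(s_i[labels == k]), 0))
}

oracle_rand <- function(l1, l2) {
  n <- length(l1); agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((l1[i] == l1[j]) == (l2[i] == l2[j]))
  agree / choose(n, 2)
}

# PSG as the plain mean of the full n x n max-support matrix
oracle_psg_global <- function(ps) {
  M <- pmax(ps, 1 - ps)
  mean(M)
}

# all partitions of n elements into exactly K non-empty clusters
all_partitions <- function(n, K) {
  res <- list()
  gen <- function(lab, i, used) {
    if (i > n) {
      if (used == K) res[[length(res) + 1L]] <<- lab
      return(invisible())
    }
    for (k in seq_len(min(used + 1L, K))) gen(c(lab, k), i + 1L,
                                              max(used, k))
  }
  gen(integer(0), 1L, 0L)
  res
}

# random partitions used as synthetic "runs" for stability properties
random_partitions <- function(ids, n_runs, seed) {
  set.seed(seed)
  lapply(seq_len(n_runs), function(q) {
    repeat {
      lab <- sample.int(sample(2:(length(ids) - 1), 1), length(ids),
                        replace = TRUE)
      if (length(unique(lab)) >= 2) break
    }
    wf_partition(ids, lab)
  })
}

# Expected encodings of the five-workflow fixture (matrices and weights),
# as used by the encoder unit tests and the acceptance suite. The
# pair-of-tasks cell "Probcons -> PhyML" for W4 is 0: W4 contains no
# Probcons instance (see the fixture documentation).
table1_expected <- function() {
  W <- c("W1", "W2", "W3", "W4", "W5")
  m <- function(rows) {
    mat <- do.call(rbind, lapply(rows, function(r) as.integer(r[1:5])))
    dimnames(mat) <- list(names(rows), W)
    w <- vapply(rows, function(r) r[[6]], 0)
    list(mat = mat, w = w)
  }
  list(
    I = m(list(
      "Blast (NCBI)"               = c(0,0,0,1,0, 0.35),
      "ClustalW2"                  = c(0,1,0,0,1, 0.49),
      "HGT Detector 3.2"           = c(1,1,1,0,1, 0.88),
      "Muscle"                     = c(1,0,0,0,1, 0.41),
      "PROTML (Phylip)"            = c(1,0,0,0,0, 0.68),
      "PhyML (1)"                  = c(0,1,1,0,1, 1.13),
      "PhyML (2)"                  = c(0,0,0,0,1, 1.13),
      "Probcons"                   = c(0,0,1,0,0, 0.55),
      "Robinson & Foulds distance" = c(0,0,0,1,0, 0.25),
      "SEQBOOT (Phylip)"           = c(1,0,0,0,0, 0.14),
      "Seq-Gen"                    = c(0,1,0,1,0, 0.43))),
    II = m(list(
      "Blast (NCBI)"               = c(0,0,0,1,0, 0.10),
      "ClustalW2"                  = c(0,1,0,0,1, 0.10),
      "HGT Detector 3.2"           = c(1,1,1,0,1, 1.00),
      "Muscle"                     = c(1,0,0,0,1, 0.10),
      "PROTML (Phylip)"            = c(1,0,0,0,0, 0.10),
      "PhyML"                      = c(0,1,1,0,2, 0.10),
      "Probcons"                   = c(0,0,1,0,0, 0.10),
      "Robinson & Foulds distance" = c(0,0,0,1,0, 0.10),
      "SEQBOOT (Phylip)"           = c(1,0,0,0,0, 0.10),
      "Seq-Gen"                    = c(0,1,0,1,0, 0.10))),
    III = m(list(
      "Blast (NCBI)"                          = c(0,0,0,1,0, 0.35),
      "ClustalW2 -> PhyML"                    = c(0,1,0,0,1, 1.62),
      "HGT Detector 3.2"                      = c(1,1,1,0,1, 0.88),
      "Muscle -> PhyML"                       = c(0,0,0,0,1, 1.54),
      "Muscle -> SEQBOOT (Phylip)"            = c(1,0,0,0,0, 0.55),
      "PROTML (Phylip) -> HGT Detector 3.2"   = c(1,0,0,0,0, 1.56),
      "PhyML -> HGT Detector 3.2"             = c(0,1,1,0,2, 2.01),
      "Probcons -> PhyML"                     = c(0,0,1,0,0, 1.68),
      "Robinson & Foulds distance"            = c(0,0,0,1,0, 0.25),
      "SEQBOOT (Phylip) -> PROTML (Phylip)"   = c(1,0,0,0,0, 0.82),
      "Seq-Gen -> Blast (NCBI)"               = c(0,0,0,1,0, 0.78),
      "Seq-Gen -> ClustalW2"                  = c(0,1,0,0,0, 0.92))),
    IV = m(list(
      "Blast (NCBI)"                          = c(0,0,0,1,0, 0.10),
      "ClustalW2 -> PhyML"                    = c(0,1,0,0,1, 0.10),
      "HGT Detector 3.2"                      = c(1,1,1,0,1, 1.00),
      "Muscle -> PhyML"                       = c(0,0,0,0,1, 0.10),
      "Muscle -> SEQBOOT (Phylip)"            = c(1,0,0,0,0, 0.10),
      "PROTML (Phylip) -> HGT Detector 3.2"   = c(1,0,0,0,0, 1.00),
      "PhyML -> HGT Detector 3.2"             = c(0,1,1,0,2, 1.00),
      "Probcons -> PhyML"                     = c(0,0,1,0,0, 0.10),
      "Robinson & Foulds distance"            = c(0,0,0,1,0, 0.10),
      "SEQBOOT (Phylip) -> PROTML (Phylip)"   = c(1,0,0,0,0, 0.10),
      "Seq-Gen -> Blast (NCBI)"               = c(0,0,0,1,0, 0.10),
      "Seq-Gen -> ClustalW2"                  = c(0,1,0,0,0, 0.10),
      "INPUT_Sequences"                       = c(1,0,1,0,1, 1.00),
      "INPUT_Tree"                            = c(1,1,1,2,0, 1.00),
      "OUTPUT_Blast (NCBI)"                   = c(0,0,0,1,0, 1.00),
      "OUTPUT_Matrix"                         = c(1,1,1,1,1, 1.00),
      "OUTPUT_MultipleTrees"                  = c(0,0,0,1,0, 1.00),
      "OUTPUT_OutputText"                     = c(1,1,1,2,1, 1.00),
      "OUTPUT_Results"                        = c(1,1,1,1,1, 1.00))))
}
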