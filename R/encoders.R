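# Four encodings of a workflow collection into a variables x workflows
# matrix W plus a non-negative per-variable weight vector y. All variable
# orderings use a locale-independent radix sort so matrices are reproducible
# bit-exactly.

.sort_names <- function(x) x[order(x, method = "radix")]

new_wf_encoding <- function(type, mat, weights, ids) {
  stopifnot(nrow(mat) == length(weights), ncol(mat) == length(ids))
  if (any(mat < 0)) stop("matrix entries must be non-negative")
  if (any(weights < 0)) stop("weights must be non-negative")
  structure(list(encoding_type = type,
                 variables = rownames(mat),
                 matrix = mat,
                 weights = stats::setNames(as.numeric(weights), rownames(mat)),
                 workflow_ids = ids),
            class = "wf_encoding")
}

#' @export
print.wf_encoding <- function(x, ...) {
  cat(sprintf("Encoding of Type %s: %d variables x %d workflows\n",
              x$encoding_type, nrow(x$matrix), ncol(x$matrix)))
  m <- cbind(as.data.frame(x$matrix), weight = round(x$weights, 2))
  print(m, ...)
  invisible(x)
}

#' Keyword weighting rule
#'
#' Variables whose task name or annotations contain the keyword
#' (case-insensitive substring) receive `match_weight`; all others receive
#' `default_weight`. Used by the occurrence (Type II) and ports (Type IV)
#' encodings; the conventional choice of 1.0 vs 0.1 makes keyword-bearing
#' tasks dominate the distances.
#'
#' @param keyword Keyword string.
#' @param match_weight Weight of matching variables (default 1.0).
#' @param default_weight Weight of the remaining variables (default 0.1).
#' @return A list of class `"wf_keyword_rule"`.
#' @export
keyword_rule <- function(keyword, match_weight = 1.0, default_weight = 0.1) {
  stopifnot(is.character(keyword), length(keyword) == 1L,
            match_weight >= 0, default_weight >= 0)
  structure(list(keyword = keyword, match_weight = match_weight,
                 default_weight = default_weight),
            class = "wf_keyword_rule")
}

.task_matches <- function(task, rule) {
  hay <- tolower(paste(c(task$name, task$annotations), collapse = " "))
  grepl(tolower(rule$keyword), hay, fixed = TRUE)
}

# occurrence counts of each task id in each workflow: tasks x workflows
.occurrence_counts <- function(ws) {
  ids <- workflow_ids(ws)
  tids <- names(ws$task_pool)
  out <- sapply(ws$workflows, function(w)
    tabulate(match(w$instances, tids), length(tids)))
  out <- matrix(out, nrow = length(tids), dimnames = list(tids, ids))
  out
}

#' Presence-absence encoding (Type I)
#'
#' One binary variable per task-instance slot. When some task occurs up to
#' `M >= 2` times in a single workflow it contributes `M` variables named
#' `"Task (1)" ... "Task (M)"`; the k-th is 1 for workflows using the task
#' at least k times. Each variable is weighted by the task's average
#' execution time.
#'
#' @param ws A `workflow_set`.
#' @return A `wf_encoding` with binary matrix entries.
#' @export
encode_type1 <- function(ws) {
  stopifnot(n_workflows(ws) >= 1L)
  occ <- .occurrence_counts(ws)
  rows <- list(); wts <- numeric()
  for (tid in rownames(occ)) {
    m <- max(occ[tid, ])
    if (m == 0L) next
    task <- ws$task_pool[[tid]]
    for (k in seq_len(m)) {
      nm <- if (m > 1L) sprintf("%s (%d)", task$name, k) else task$name
      rows[[nm]] <- as.integer(occ[tid, ] >= k)
      wts[[nm]] <- task$avg_exec_time
    }
  }
  vn <- .sort_names(names(rows))
  mat <- do.call(rbind, rows[vn])
  dimnames(mat) <- list(vn, workflow_ids(ws))
  new_wf_encoding("I", mat, wts[vn], workflow_ids(ws))
}

#' Occurrence encoding (Type II)
#'
#' One variable per task type, whose entry is the number of instances of
#' that task in the workflow. Weights follow the keyword rule: tasks
#' matching the keyword receive `rule$match_weight`, all others
#' `rule$default_weight`.
#'
#' @param ws A `workflow_set`.
#' @param rule A [keyword_rule()].
#' @return A `wf_encoding` with count entries.
#' @export
encode_type2 <- function(ws, rule) {
  stopifnot(n_workflows(ws) >= 1L, inherits(rule, "wf_keyword_rule"))
  occ <- .occurrence_counts(ws)
  keep <- rowSums(occ) > 0
  occ <- occ[keep, , drop = FALSE]
  nms <- vapply(ws$task_pool[rownames(occ)], `[[`, "", "name")
  wts <- vapply(ws$task_pool[rownames(occ)], function(t)
    if (.task_matches(t, rule)) rule$match_weight else rule$default_weight, 0)
  rownames(occ) <- nms; names(wts) <- nms
  vn <- .sort_names(nms)
  new_wf_encoding("II", occ[vn, , drop = FALSE], wts[vn], workflow_ids(ws))
}

# Internal: pair-of-tasks variables shared by Types III and IV.
# Edge variables "Src -> Dst" count directed instance edges between task
# types; singleton variables are task types terminal (out-degree zero) in at
# least one workflow, counting terminal instances.
.pair_variables <- function(ws) {
  ids <- workflow_ids(ws)
  n <- length(ids)
  edge_counts <- list()   # name -> counts vector
  term_counts <- list()   # task id -> counts vector
  for (j in seq_len(n)) {
    w <- ws$workflows[[j]]
    if (nrow(w$edges)) {
      src <- w$instances[w$edges[, 1L]]
      dst <- w$instances[w$edges[, 2L]]
      for (e in seq_along(src)) {
        key <- paste(src[[e]], dst[[e]], sep = "\r")
        if (is.null(edge_counts[[key]])) edge_counts[[key]] <- integer(n)
        edge_counts[[key]][j] <- edge_counts[[key]][j] + 1L
      }
    }
    for (tid in w$instances[terminal_tasks(w)]) {
      if (is.null(term_counts[[tid]])) term_counts[[tid]] <- integer(n)
      term_counts[[tid]][j] <- term_counts[[tid]][j] + 1L
    }
  }
  rows <- list(); meta <- list()
  for (key in names(edge_counts)) {
    p <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    src <- ws$task_pool[[p[[1L]]]]; dst <- ws$task_pool[[p[[2L]]]]
    nm <- paste(src$name, "->", dst$name)
    rows[[nm]] <- edge_counts[[key]]
    meta[[nm]] <- list(kind = "pair", tasks = list(src, dst),
                       weight = src$avg_exec_time + dst$avg_exec_time)
  }
  for (tid in names(term_counts)) {
    task <- ws$task_pool[[tid]]
    rows[[task$name]] <- term_counts[[tid]]
    meta[[task$name]] <- list(kind = "singleton", tasks = list(task),
                              weight = task$avg_exec_time)
  }
  vn <- .sort_names(names(rows))
  mat <- do.call(rbind, rows[vn])
  dimnames(mat) <- list(vn, ids)
  list(mat = mat, meta = meta[vn])
}

#' Pair-of-tasks encoding (Type III)
#'
#' Structural encoding: one variable per distinct directed task-to-task
#' edge, named `"Src -> Dst"` and counting instance edges, weighted by the
#' sum of the two tasks' average execution times; plus one singleton
#' variable per task type that is terminal (no outgoing edge) in at least
#' one workflow, counting terminal instances and weighted by the task's
#' execution time.
#'
#' @param ws A `workflow_set`.
#' @return A `wf_encoding`.
#' @export
encode_type3 <- function(ws) {
  stopifnot(n_workflows(ws) >= 1L)
  pv <- .pair_variables(ws)
  wts <- vapply(pv$meta, `[[`, 0, "weight")
  new_wf_encoding("III", pv$mat, wts, workflow_ids(ws))
}

#' Pair-of-tasks encoding with input/output ports (Type IV)
#'
#' The Type III variables re-weighted by the keyword rule (a pair matches if
#' either member task matches), plus one count variable per workflow-level
#' port data type, named `"INPUT_<datatype>"` / `"OUTPUT_<datatype>"` and
#' weighted with `rule$match_weight`.
#'
#' @param ws A `workflow_set`.
#' @param rule A [keyword_rule()].
#' @return A `wf_encoding`.
#' @export
encode_type4 <- function(ws, rule) {
  stopifnot(n_workflows(ws) >= 1L, inherits(rule, "wf_keyword_rule"))
  pv <- .pair_variables(ws)
  wts <- vapply(pv$meta, function(m)
    if (any(vapply(m$tasks, .task_matches, NA, rule)))
      rule$match_weight else rule$default_weight, 0)
  ids <- workflow_ids(ws)
  port_rows <- list()
  for (j in seq_along(ids)) {
    w <- ws$workflows[[j]]
    for (dt in w$inputs) {
      nm <- paste0("INPUT_", dt)
      if (is.null(port_rows[[nm]])) port_rows[[nm]] <- integer(length(ids))
      port_rows[[nm]][j] <- port_rows[[nm]][j] + 1L
    }
    for (dt in w$outputs) {
      nm <- paste0("OUTPUT_", dt)
      if (is.null(port_rows[[nm]])) port_rows[[nm]] <- integer(length(ids))
      port_rows[[nm]][j] <- port_rows[[nm]][j] + 1L
    }
  }
  pn <- .sort_names(names(port_rows))
  pmat <- do.call(rbind, port_rows[pn])
  mat <- rbind(pv$mat, pmat)
  rownames(mat) <- c(rownames(pv$mat), pn)
  wts <- c(wts, stats::setNames(rep(rule$match_weight, length(pn)), pn))
  new_wf_encoding("IV", mat, wts, ids)
}

#' Drop the variable weights of an encoding
#'
#' Replaces every weight by 1.0, turning the weighted distances into their
#' plain unweighted counterparts. Idempotent.
#'
#' @param enc A `wf_encoding`.
#' @return The same encoding with unit weights.
#' @export
strip_weights <- function(enc) {
  stopifnot(inherits(enc, "wf_encoding"))
  enc$weights[] <- 1.0
  enc
}

#' Write an encoding to CSV
#'
#' First column is the variable name, then one integer column per workflow,
#' last column the variable weight.
#'
#' @param enc A `wf_encoding`.
#' @param path Output file.
#' @param digits Decimals used for weights (default 2).
#' @return `path`, invisibly.
#' @export
write_encoding_csv <- function(enc, path, digits = 2) {
  d <- data.frame(variable = enc$variables, enc$matrix,
                  weight = formatC(enc$weights, format = "f", digits = digits),
                  check.names = FALSE, row.names = NULL)
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
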