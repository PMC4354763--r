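#' Create a task description
#'
#' A task is a computational method (e.g. an aligner or a tree-inference
#' program) that may appear, possibly several times, inside workflows of a
#' collection. The average execution time is used as a variable weight by the
#' presence-absence and pair-of-tasks encodings.
#'
#' @param id Unique identifier of the task within a collection's pool.
#' @param name Display name (defaults to `id`).
#' @param category Optional category string (e.g. `"alignment"`).
#' @param avg_exec_time Non-negative average execution time (arbitrary units).
#' @param annotations Character vector of keyword annotations.
#' @return A list of class `"wf_task"`.
#' @export
wf_task <- function(id, name = id, category = NULL, avg_exec_time = 0,
                    annotations = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(avg_exec_time) || length(avg_exec_time) != 1L ||
      is.na(avg_exec_time) || avg_exec_time < 0)
    stop("avg_exec_time must be a single non-negative number")
  structure(list(id = id, name = name, category = category,
                 avg_exec_time = as.numeric(avg_exec_time),
                 annotations = as.character(annotations)),
            class = "wf_task")
}

#' Create a workflow
#'
#' A workflow is a directed acyclic graph whose nodes are *task instances*:
#' ordered references into a collection's task pool. The same task may occur
#' more than once. Workflow-level input and output ports carry data-type
#' names, with multiplicity expressed by repetition.
#'
#' @param id Workflow identifier, unique within a collection.
#' @param instances Character vector of task ids, in instance order.
#' @param edges Two-column matrix (or list of length-2 vectors) of directed
#'   instance-index pairs `(source, target)`, 1-based. `NULL` for no edges.
#' @param inputs,outputs Character vectors of port data-type names.
#' @param class_label Optional reference class label.
#' @return A list of class `"wf_workflow"`.
#' @export
wf_workflow <- function(id, instances, edges = NULL,
                        inputs = character(), outputs = character(),
                        class_label = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.character(instances))
  if (is.list(edges)) edges <- do.call(rbind, edges)
  if (is.null(edges) || length(edges) == 0L)
    edges <- matrix(integer(), ncol = 2L)
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("src", "dst")))
  structure(list(id = id, instances = instances, edges = edges,
                 inputs = as.character(inputs), outputs = as.character(outputs),
                 class_label = class_label),
            class = "wf_workflow")
}

#' Create a workflow collection
#'
#' @param task_pool List of [wf_task()] objects with unique ids.
#' @param workflows List of [wf_workflow()] objects with unique ids.
#' @param validate Check all structural invariants (default `TRUE`).
#' @return A list of class `"workflow_set"` with elements `task_pool`
#'   (named by task id) and `workflows` (named by workflow id).
#' @export
workflow_set <- function(task_pool, workflows, validate = TRUE) {
  tids <- vapply(task_pool, `[[`, "", "id")
  if (anyDuplicated(tids)) stop("duplicate task ids in pool")
  wids <- vapply(workflows, `[[`, "", "id")
  if (anyDuplicated(wids)) stop("duplicate workflow ids")
  names(task_pool) <- tids
  names(workflows) <- wids
  ws <- structure(list(task_pool = task_pool, workflows = workflows),
                  class = "workflow_set")
  if (validate) {
    for (w in workflows) {
      v <- validate_workflow(w, task_pool)
      if (length(v)) stop("workflow '", w$id, "': ", v[[1L]])
    }
  }
  ws
}

#' @export
print.workflow_set <- function(x, ...) {
  cat(sprintf("Workflow collection: %d workflows, %d tasks in pool\n",
              length(x$workflows), length(x$task_pool)))
  for (w in x$workflows) {
    cat(sprintf("  %s: %d task instances, %d edges%s\n", w$id,
                length(w$instances), nrow(w$edges),
                if (!is.null(w$class_label))
                  paste0(" [", w$class_label, "]") else ""))
  }
  invisible(x)
}

#' Number of workflows in a collection
#' @param ws A `workflow_set`.
#' @return Integer count.
#' @export
n_workflows <- function(ws) length(ws$workflows)

#' Workflow ids of a collection, in order
#' @param ws A `workflow_set`.
#' @return Character vector.
#' @export
workflow_ids <- function(ws) unname(vapply(ws$workflows, `[[`, "", "id"))

# Kahn topological check; returns TRUE iff the instance-level edge
# relation is acyclic.
.is_acyclic <- function(n, edges) {
  if (nrow(edges) == 0L) return(TRUE)
  indeg <- tabulate(edges[, 2L], n)
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(n)))
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (u in adj[[v]]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) queue <- c(queue, u)
    }
  }
  seen == n
}

#' Validate a workflow against its task pool
#'
#' Checks every structural invariant and returns descriptions of the
#' violations rather than raising conditions.
#'
#' @param w A `wf_workflow`.
#' @param task_pool Named list of tasks (as in a `workflow_set`), or a
#'   `workflow_set` from which the pool is taken.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_workflow <- function(w, task_pool) {
  if (inherits(task_pool, "workflow_set")) task_pool <- task_pool$task_pool
  out <- character()
  n <- length(w$instances)
  if (n < 1L) out <- c(out, "workflow has no task instances")
  unknown <- setdiff(w$instances, names(task_pool))
  if (length(unknown))
    out <- c(out, paste0("unknown task: ", paste(unknown, collapse = ", ")))
  e <- w$edges
  if (nrow(e)) {
    bad <- e[, 1L] < 1L | e[, 1L] > n | e[, 2L] < 1L | e[, 2L] > n | is.na(e)
    if (any(bad))
      out <- c(out, paste0("edge endpoint out of range at edge ",
                           which(rowSums(matrix(bad, ncol = 2L)) > 0)[1L]))
    else {
      self <- e[, 1L] == e[, 2L]
      if (any(self))
        out <- c(out, paste0("self-edge at instance ", e[which(self)[1L], 1L],
                             ": workflow is not acyclic"))
      else if (!.is_acyclic(n, e))
        out <- c(out, "acyclicity violated: workflow is not acyclic")
    }
  }
  for (tid in intersect(unique(w$instances), names(task_pool))) {
    if (task_pool[[tid]]$avg_exec_time < 0)
      out <- c(out, paste0("non-negative time violated for task ", tid))
  }
  out
}

#' Terminal task instances of a workflow
#'
#' Instances with no outgoing edge to another task instance, in instance
#' order. These are the workflow's end points and serve as the singleton
#' variables of the pair-of-tasks encodings.
#'
#' @param w A `wf_workflow`.
#' @return Integer vector of instance indices, named by task id.
#' @export
terminal_tasks <- function(w) {
  n <- length(w$instances)
  idx <- setdiff(seq_len(n), unique(w$edges[, 1L]))
  names(idx) <- w$instances[idx]
  idx
}

#' Read a workflow collection from JSON
#'
#' The document must have top-level keys `task_pool` (list of objects with
#' `id`, `name`, `category`, `avg_exec_time`, `annotations`) and `workflows`
#' (list of objects with `id`, `instances` — task ids — , `edges` — list of
#' 1-based `[src, dst]` instance-index pairs —, `inputs`, `outputs` and
#' optional `class_label`).
#'
#' @param path Path to a JSON file.
#' @return A validated [workflow_set()].
#' @export
load_workflows <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed document: ",
                                           conditionMessage(e)))
  if (!is.list(doc) || is.null(doc$task_pool) || is.null(doc$workflows))
    stop("malformed document: missing task_pool or workflows")
  pool <- lapply(doc$task_pool, function(t)
    wf_task(id = t$id, name = t$name %||% t$id,
            category = t$category %||% NULL,
            avg_exec_time = t$avg_exec_time %||% 0,
            annotations = unlist(t$annotations) %||% character()))
  wfs <- lapply(doc$workflows, function(d) {
    edges <- if (length(d$edges))
      do.call(rbind, lapply(d$edges, as.integer)) else NULL
    wf_workflow(id = d$id, instances = unlist(d$instances),
                edges = edges,
                inputs = unlist(d$inputs) %||% character(),
                outputs = unlist(d$outputs) %||% character(),
                class_label = d$class_label %||% NULL)
  })
  tids <- vapply(pool, `[[`, "", "id")
  for (w in wfs) {
    unknown <- setdiff(w$instances, tids)
    if (length(unknown)) stop("unknown task: ", unknown[[1L]])
    v <- validate_workflow(w, stats::setNames(pool, tids))
    if (length(v)) stop(v[[1L]])
  }
  workflow_set(pool, wfs, validate = FALSE)
}

#' Write a workflow collection to JSON
#'
#' Inverse of [load_workflows()]: the written document loads back to an
#' identical collection.
#'
#' @param ws A `workflow_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_workflows <- function(ws, path) {
  doc <- list(
    task_pool = lapply(unname(ws$task_pool), function(t)
      list(id = t$id, name = t$name, category = t$category,
           avg_exec_time = t$avg_exec_time,
           annotations = as.list(t$annotations))),
    workflows = lapply(unname(ws$workflows), function(w)
      list(id = w$id, instances = as.list(w$instances),
           edges = lapply(seq_len(nrow(w$edges)),
                          function(i) as.list(w$edges[i, ])),
           inputs = as.list(w$inputs), outputs = as.list(w$outputs),
           class_label = w$class_label)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read reference class labels
#'
#' @param path CSV file with header and two columns, `workflow_id` and
#'   `class_label`.
#' @return Named character vector mapping workflow id to class label.
#' @export
read_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("workflow_id", "class_label") %in% names(d)))
    stop("label file must have columns workflow_id, class_label")
  stats::setNames(as.character(d$class_label), d$workflow_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The five-workflow example collection
#'
#' Reconstructs the small collection of five phylogenetic-analysis workflows
#' used throughout the package's documentation and tests: pipelines chaining
#' sequence simulation, multiple alignment (Muscle, ClustalW2, Probcons),
#' tree inference (PhyML, PROTML) and horizontal-gene-transfer detection.
#' Workflow W5 contains two PhyML instances; workflow W4 has two Tree input
#' ports, no alignment task (its pipeline is Seq-Gen feeding Blast, plus an
#' isolated Robinson & Foulds instance) and in particular no Probcons, so
#' its pair-of-tasks column contains no Probcons edge. Task execution times
#' (in arbitrary units) are the weights used by the presence-absence
#' encoding.
#'
#' @return A `workflow_set` of five workflows (`W1`--`W5`) over a pool of
#'   ten tasks.
#' @export
figure1_fixture <- function() {
  pool <- list(
    wf_task("blast",    "Blast (NCBI)",               "hgt-detection", 0.35),
    wf_task("clustalw2","ClustalW2",                  "alignment",     0.49),
    wf_task("hgt",      "HGT Detector 3.2",           "hgt-detection", 0.88,
            annotations = "HGT"),
    wf_task("muscle",   "Muscle",                     "alignment",     0.41),
    wf_task("protml",   "PROTML (Phylip)",            "tree-inference",0.68),
    wf_task("phyml",    "PhyML",                      "tree-inference",1.13),
    wf_task("probcons", "Probcons",                   "alignment",     0.55),
    wf_task("rf",       "Robinson & Foulds distance", "hgt-detection", 0.25),
    wf_task("seqboot",  "SEQBOOT (Phylip)",           "tree-inference",0.14),
    wf_task("seqgen",   "Seq-Gen",                    "simulation",    0.43))
  std_out <- c("Matrix", "OutputText", "Results")
  wfs <- list(
    wf_workflow("W1", c("muscle", "seqboot", "protml", "hgt"),
                cbind(1:3, 2:4),
                inputs = c("Sequences", "Tree"), outputs = std_out),
    wf_workflow("W2", c("seqgen", "clustalw2", "phyml", "hgt"),
                cbind(1:3, 2:4),
                inputs = "Tree", outputs = std_out),
    wf_workflow("W3", c("probcons", "phyml", "hgt"),
                cbind(1:2, 2:3),
                inputs = c("Sequences", "Tree"), outputs = std_out),
    wf_workflow("W4", c("seqgen", "blast", "rf"),
                cbind(1L, 2L),
                inputs = c("Tree", "Tree"),
                outputs = c("Blast (NCBI)", "Matrix", "MultipleTrees",
                            "OutputText", "OutputText", "Results")),
    wf_workflow("W5", c("muscle", "clustalw2", "phyml", "phyml", "hgt"),
                cbind(c(1L, 2L, 3L, 4L), c(3L, 4L, 5L, 5L)),
                inputs = "Sequences", outputs = std_out))
  workflow_set(pool, wfs)
}
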