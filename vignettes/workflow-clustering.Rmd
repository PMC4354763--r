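---
title: "Weighted clustering of scientific workflows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted clustering of scientific workflows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfclust)
```

## The problem

A scientific workflow is a directed acyclic graph of computational tasks —
in bioinformatics, typically a pipeline chaining sequence simulation,
multiple alignment, phylogenetic inference and downstream analyses such as
horizontal-gene-transfer detection. Laboratories and workflow-management
systems accumulate collections of such pipelines, and several practical
questions (grouping workflows for co-scheduling, dispatching long pipelines
to different servers, keyword-driven retrieval) reduce to the same
statistical one: *which workflows in a collection are similar, and how many
natural groups are there?*

`wfclust` answers this with a matrix-encoding step followed by weighted
partitioning or hierarchical classification, a model-selection layer for
the number of clusters, and a stability layer that quantifies how much a
clustering can be trusted.

## Encoding a collection

A collection of $n$ workflows over $m$ variables is represented by a
non-negative matrix $W = (w_{ip})$ (variables in rows, workflows in
columns) together with a non-negative weight vector
$y = (y_1, \dots, y_m)$. Four encodings are provided:

* **Type I (presence–absence).** One binary variable per task-instance
  slot. A task occurring up to $M \ge 2$ times in a single workflow
  contributes variables `"Task (1)" … "Task (M)"`, the $k$-th being 1 for
  workflows using the task at least $k$ times. Weights are the tasks'
  average execution times, so the induced distances emphasise the
  expensive parts of a pipeline.
* **Type II (occurrence).** One count variable per task type. Weights
  follow a keyword rule ([keyword_rule()]): tasks whose name or
  annotations contain the keyword (case-insensitive substring) receive
  `match_weight` (default 1.0), all others `default_weight` (default 0.1).
* **Type III (pair of tasks).** Structural encoding: one count variable
  per distinct directed task→task edge, weighted by the sum of the two
  tasks' execution times, plus one singleton variable per task type that
  is *terminal* (out-degree zero) in at least one workflow, counting
  terminal instances. The terminal-task rule is the package's definition
  of the singleton variables: it makes the end points of a pipeline —
  which carry its analytical intent — visible to the distance even when
  the final task has no outgoing pair.
* **Type IV (pairs + ports).** The Type III variables re-weighted by the
  keyword rule (a pair matches when either member task matches), plus one
  count variable per workflow-level input/output port data type
  (`INPUT_<datatype>`, `OUTPUT_<datatype>`), weighted with the match
  weight. Only workflow-level ports are encoded; data types flowing
  between intermediate tasks are not.

Variables are ordered by a locale-independent radix sort and all counts
are integers, so encodings are reproducible bit-exactly across platforms.
`strip_weights()` converts any encoding to its unweighted variant.

## Distances

Two weighted distances operate on an encoding:

$$d^{\mathrm{euc}}_{ij} = \sqrt{\sum_p y_p (w_{ip} - w_{jp})^2},
  \qquad
  d^{\mathrm{cos}}_{ij} = 1 -
  \frac{\sum_p y_p\, w_{ip} w_{jp}}
       {\sqrt{\sum_p y_p w_{ip}^2}\,\sqrt{\sum_p y_p w_{jp}^2}}.$$

The weighted Euclidean distance equals the plain Euclidean distance after
scaling each variable by $\sqrt{y_p}$; the cosine distance is invariant to
positive rescaling of columns and is the natural choice for sparse
count matrices. When a column has zero weighted norm the cosine distance
to it is defined as 1 (or 0 between two zero columns); this convention
keeps the distance matrix total and symmetric on degenerate input.

## Partitioning and the objective

Both partitioning algorithms minimize, heuristically, the within-cluster
dispersion

$$\sum_{k=1}^{K} \frac{1}{n_k} \sum_{i,j \in C_k} d_{ij}^2$$

(the inner sum running over ordered pairs; for the Euclidean metric this
equals twice the within-cluster sum of squared distances to the
centroid).

* `kmeans_weighted()` is Lloyd iteration from a **random starting
  partition** (uniform labels, repaired to non-empty clusters), with
  centroids the arithmetic means of member columns and reassignment by
  the chosen weighted distance; for the cosine metric the centroid is
  still the arithmetic mean and assignment uses the cosine distance to
  it. Iteration stops when assignments are stable (cap `max_iter = 300`).
* `kmedoids_weighted()` is Voronoi iteration: distinct random initial
  medoids, nearest-medoid assignment, then medoid update as the member
  minimizing the within-cluster distance sum. The swap-phase (PAM)
  variant is deliberately out of scope.

Ties in assignment and in medoid updates go to the lowest index; an empty
cluster is repaired by moving in the element farthest from its own
center. These deterministic tie-breaks, together with explicit `seed`
arguments on every stochastic routine, make all results exactly
reproducible. The best of `n_starts` starts (by the dispersion objective)
is returned; on small collections (up to eight workflows) the tests
verify that the multi-start optimum coincides with exhaustive enumeration
over all partitions.

## Choosing the number of clusters

`select_k()` scans $K \in [k_{\min}, k_{\max}]$, keeps the best run per
$K$ and applies one of three validity indices:

* **Calinski–Harabasz**: $CH(K) = \frac{SS_B}{SS_W}\cdot\frac{n-K}{K-1}$,
  maximized. $SS_B$ and $SS_W$ are between- and within-cluster
  dispersions computed with squared distances under the run's own metric
  and centers (centroids for k-means, medoids for k-medoids; the overall
  center is the grand centroid or global medoid accordingly). For cosine
  runs the squared cosine distance to the center replaces the squared
  norm — the index is kept metric-consistent rather than mixing cosine
  assignment with Euclidean scoring.
* **logSS**: $\log(SS_B/SS_W)$ (natural log; the base shifts reported
  values but not the selection). The selected $K$ minimizes the *signed*
  consecutive difference $\mathrm{logSS}(K{+}1) - \mathrm{logSS}(K)$,
  ties to the smaller $K$; an absolute-difference variant is available
  via `logss_choose_k(..., absolute = TRUE)` since either reading of
  "smallest difference" is defensible.
* **Silhouette**: widths $s(i) = (b_i - a_i)/\max(a_i, b_i)$ with
  $s(i) = 0$ for members of singleton clusters; the reported score
  macro-averages the per-cluster means $s(k)$ over clusters. The more
  common per-element mean is available with `per_point = TRUE`; the two
  differ when cluster sizes are unbalanced.

The scan range is restricted to $2 \le K \le n-1$: at $K = 1$ the ratio
indices are undefined ($K-1 = 0$, and no "nearest other cluster" exists
for the Silhouette), and at $K = n$ the within-cluster dispersion
vanishes. Degenerate inputs (zero $SS_W$, i.e. duplicated columns filling
every cluster) raise an error rather than returning an infinite index.

## Clustering stability: PS and PSG

Partitioning heuristics reach local optima that depend on the starting
partition. `stability_run()` turns this nuisance into a measurement: over
$Q$ independent randomized runs it records, for each pair of workflows,
the fraction of runs in which they are co-clustered (*pairwise support*,
PS), and for each workflow the fraction of runs in which it forms a
singleton cluster (diagonal of the PS matrix). Each run fits every
candidate $K$ from a fresh random partition and re-selects $K$ with the
validity index, so the support reflects both assignment and
model-selection variability.

The global and per-element summaries aggregate $\max(PS, 1-PS)$:

$$PSG = \frac{2\sum_{i<j}\max(PS_{ij}, 1-PS_{ij}) +
              \sum_i \max(PS_i, 1-PS_i)}{n^2},
\qquad
PSG(w_i) = \frac{\sum_{j\neq i}\max(PS_{ij}, 1-PS_{ij}) +
                 \max(PS_i, 1-PS_i)}{n}.$$

A pair always co-clustered or never co-clustered contributes 1 (perfectly
stable either way); a pair co-clustered in half of the runs contributes
the minimum 0.5. The normalization applies the factor 2 to the pairwise
sum only: this is the unique scaling of the two sums under which both
indices attain exactly the range $[0.5, 1]$, with 1 reached by any fully
reproducible clustering and 0.5 by maximal instability. The per-element
score uses the element's own singleton support in its second term, the
only reading that does not depend on an arbitrary partner $j$.

By default each of the $Q$ runs uses a **single** random start per
candidate $K$, so PS measures the raw variability of one optimizer
trajectory — the quantity of interest when asking "can I trust one run of
this program?". The `n_starts_per_k` argument lets each run keep the best
of several restarts instead; supports then grow monotonically toward 1 as
restarts filter out optimizer noise, and the choice of restart count is a
statement about the protocol being assessed, not a tuning knob of the
index itself.

## Hierarchical classification

`upgma()` (average-linkage agglomeration, ultrametric output) and
`neighbor_joining()` (canonical rate-corrected NJ, additive output)
build trees directly from any distance matrix; both exactly reproduce
ultrametric and additive inputs respectively, which the tests verify on
randomly generated trees. NJ may produce negative branch lengths on
non-additive input; they are preserved (with a warning) rather than
clamped so that path lengths keep reproducing the input where it is
additive. The weighted least-squares score
$\sum_{i<j} (\delta_{ij} - d_{ij})^2 / d_{ij}^p$ (default $p = 2$,
unordered pairs) evaluates any tree — including trees produced by
external programs and parsed from Newick — against a distance matrix.
`reference_tree()` builds the benchmark topology from class labels: one
multifurcating node per class under the root, unit branch lengths (only
the topology matters for comparison). `rf_distance()` counts bipartitions
present in exactly one of two trees, always on unrooted topologies.
Distance matrices can be exchanged with classic tree programs in PHYLIP
square format (`write_phylip_dist()` / `read_phylip_dist()`).

## The synthetic generator

`simulate_workflows()` emulates a small curated collection of
single-purpose pipelines: `n_classes` workflow classes (default 4), each
with its own disjoint pool of `tasks_per_class` tasks (default 4, i.e. a
pool of 16 — the scale of a small laboratory's tool chest), workflows of
1–8 tasks assigned to classes round-robin, chain-with-occasional-branching
topology (every non-first instance receives an edge from a uniformly
chosen earlier instance — the shape of real analysis pipelines, which are
mostly linear with occasional fan-in), log-normal execution times
(`meanlog = log 0.5`, `sdlog = 0.6`, matching the spread of the built-in
example collection's task times) and one annotation keyword per class.
The `mixing` parameter $\varepsilon$ is the probability that a task slot
draws from a foreign class pool; at $\varepsilon = 0$ classes are
perfectly separated, and increasing $\varepsilon$ degrades every
encoding's recoverability, which the tests check as a monotone trend on
the mean Rand index over 20 replicates. Within a workflow a pool hands
out distinct tasks before repeating any, so a workflow with at least
`tasks_per_class` own-class tasks covers its entire pool — this makes
zero-mixing collections exactly recoverable (Rand index 1) rather than
recoverable only on average.

What the generator does **not** emulate: heterogeneous repository
metadata (all ports are a constant `"Data"`/`"Results"` pair, so the
port variables of Type IV are uninformative on synthetic data),
correlation between execution time and task category, task reuse across
class pools, and workflows with multiple disconnected components beyond
the single isolated-instance case. Passing tests on synthetic data
therefore demonstrate correct recovery of planted block structure under
the stated noise model, not performance on real repository collections.

## Numerical choices and limitations

* All distances and dispersions are computed in double precision with
  materialized $n \times n$ matrices; the intended scale is collections
  of up to a few hundred workflows.
* The tests and examples run at deliberately small sizes — the built-in
  five-workflow collection, synthetic collections of 24–40 workflows, and
  stability protocols of $Q = 1000$ runs — chosen so the full suite
  completes in well under a minute while still exercising every code
  path; all protocols scale to larger settings unchanged.
* Heuristic partitioning carries no global-optimality guarantee; the
  enumeration cross-checks hold only at the small sizes where
  enumeration is feasible.
* Type I variable *names* depend on the maximum task multiplicity in the
  collection (a task observed twice anywhere is renamed
  `"Task (1)"`/`"Task (2)"` everywhere), so appending a workflow can
  rename rows even though existing entries never change.
* CH and logSS are undefined when $SS_W = 0$ (every cluster a set of
  duplicated columns); `select_k()` surfaces this as an error instead of
  silently skipping the $K$.
* The Rand index is reported in its plain (unadjusted) form deliberately,
  and comparisons between partitions with different numbers of clusters
  are allowed — both properties are needed when the selected $K$ varies
  across protocol settings.

## A worked example

```{r example, eval = FALSE}
ws <- figure1_fixture()
enc <- encode_type1(ws)

# model selection under the execution-time-weighted Euclidean distance
fit <- select_k(enc, algorithm = "kmeans", metric = "euclidean",
                index = "CH", k_min = 2, k_max = 4,
                n_starts = 1000, seed = 1)
print(fit)

# how stable is that clustering across random restarts?
st <- stability_run(enc, algorithm = "kmeans", metric = "cosine",
                    index = "CH", k_min = 2, k_max = 4,
                    Q = 1000, seed = 1)
print(st)
```
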