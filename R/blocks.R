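# Fiber building blocks: each fiber plus its regulators (and any feedback
# path from the fiber back to them), classified by the branching ratio n of
# the fiber's input tree and the number l of external regulators, written
# |n, l> in reports.

#' Extract the building block of a fiber
#'
#' The block consists of the fiber, its regulators (typed in-neighbors of
#' fiber members that lie outside the fiber) and any feedback nodes: nodes on
#' directed paths leading from the fiber back to a regulator. Feedback nodes
#' are found by reachability — a node outside the fiber and regulator sets
#' belongs to the feedback set when it is reachable from the fiber and some
#' regulator is reachable from it.
#'
#' @param graph a [signed_digraph]
#' @param fiber character vector of fiber members (nonempty)
#' @return object of class `building_block`: list with `fiber`, `regulators`,
#'   `feedback_nodes` and `subgraph` (the induced [signed_digraph])
#' @export
extract_building_block <- function(graph, fiber) {
  stopifnot_digraph(graph)
  fiber <- as.character(fiber)
  if (!length(fiber)) stop("fiber must be nonempty")
  if (!all(fiber %in% graph$nodes)) stop("fiber members missing from graph")
  e <- graph$edges
  regulators <- sort(setdiff(unique(e$source[e$target %in% fiber]), fiber))
  feedback <- character()
  if (length(regulators)) {
    ig <- as_igraph(graph)
    fwd <- reachable_from(ig, fiber)          # nodes the fiber can reach
    bwd <- reaching_to(ig, regulators)        # nodes that can reach a regulator
    feedback <- sort(setdiff(intersect(fwd, bwd), c(fiber, regulators)))
  }
  members <- unique(c(fiber, regulators, feedback))
  structure(list(fiber = sort(fiber), regulators = regulators,
                 feedback_nodes = feedback,
                 subgraph = induced_subgraph_sd(graph, members)),
            class = "building_block")
}

reachable_from <- function(ig, nodes) {
  r <- igraph::subcomponent(ig, nodes[1L], mode = "out")$name
  for (v in nodes[-1L]) {
    r <- union(r, igraph::subcomponent(ig, v, mode = "out")$name)
  }
  r
}

reaching_to <- function(ig, nodes) {
  r <- igraph::subcomponent(ig, nodes[1L], mode = "in")$name
  for (v in nodes[-1L]) {
    r <- union(r, igraph::subcomponent(ig, v, mode = "in")$name)
  }
  r
}

#' @export
print.building_block <- function(x, ...) {
  cat(sprintf(
    "<building_block: fiber {%s}; regulators {%s}; feedback {%s}>\n",
    paste(x$fiber, collapse = ","), paste(x$regulators, collapse = ","),
    paste(x$feedback_nodes, collapse = ",")))
  invisible(x)
}

#' Branching ratio of a building block
#'
#' The asymptotic growth rate of the fiber's input tree inside the block: the
#' ratio of consecutive layer sizes at depth `depth`. Finite trees (acyclic
#' blocks) give 0. A self-loop alone gives 1 (feedforward fiber); two
#' intertwined loops give 2; a self-loop plus a feedback loop through a
#' regulator gives the golden ratio (the Fibonacci fiber), because the layer
#' sizes then satisfy the Fibonacci recurrence.
#'
#' @param block a `building_block`
#' @param depth layers to expand (>= 10; default 40)
#' @param tolerance maximal allowed fluctuation between the last two ratio
#'   estimates before the estimate is flagged unstable
#' @return numeric ratio with attribute `stable` (logical)
#' @export
branching_ratio <- function(block, depth = 40L, tolerance = 1e-3) {
  if (!inherits(block, "building_block")) stop("need a building_block")
  if (depth < 10L) stop("depth must be >= 10")
  member <- block$fiber[1L]
  sizes <- input_layer_sizes(block$subgraph, member, depth)
  if (length(sizes) < depth) {          # tree terminated: acyclic history
    return(structure(0, stable = TRUE))
  }
  r_last <- sizes[depth] / sizes[depth - 1L]
  r_prev <- sizes[depth - 1L] / sizes[depth - 2L]
  structure(r_last, stable = abs(r_last - r_prev) <= tolerance)
}

#' Number of external regulators of a block
#'
#' Counts every regulator node of the fiber (out-of-fiber typed
#' in-neighbors), including regulators that participate in a feedback loop
#' with the fiber: the worked Fibonacci example counts its loop regulator in
#' l. See the package vignette for a discussion of this convention.
#'
#' @param block a `building_block`
#' @return integer l >= 0
#' @export
count_external_regulators <- function(block) {
  length(block$regulators)
}

#' Classify a building block
#'
#' Classes, by branching ratio r and feedback structure:
#' \itemize{
#'   \item `trivial`: r = 0 (no loops feeding the fiber's history);
#'   \item `fff`: r = 1 via a fiber self-loop, no feedback to regulators
#'     (the feedforward fiber, l-FFF);
#'   \item `n_ary`: integer r >= 2 (e.g. the n=2 fiber with two loops
#'     through the synchronized genes), no feedback to regulators;
#'   \item `fibonacci`: non-integer 1 < r < 2 with a feedback connection
#'     from the fiber back to a regulator;
#'   \item `composite`: anything else (chained mixtures of the primitives).
#' }
#'
#' @param block a `building_block`
#' @param depth,tolerance passed to [branching_ratio]
#' @return object of class `block_class`: list with `ratio`, `ell`, `kind`
#'   and `label` (the |n, l> notation)
#' @export
classify_block <- function(block, depth = 40L, tolerance = 1e-3) {
  r <- branching_ratio(block, depth = depth, tolerance = tolerance)
  ell <- count_external_regulators(block)
  stable <- isTRUE(attr(r, "stable"))
  r <- as.numeric(r)
  has_feedback <- block_has_feedback(block)
  fiber_selfloop <- any(block$subgraph$edges$source %in% block$fiber &
                          block$subgraph$edges$source ==
                            block$subgraph$edges$target)
  is_int <- abs(r - round(r)) < 1e-6
  kind <-
    if (r == 0) "trivial"
    else if (is_int && round(r) == 1 && !has_feedback && fiber_selfloop) "fff"
    else if (is_int && round(r) >= 1 && !has_feedback) "n_ary"
    else if (!is_int && r > 1 && r < 2 && has_feedback && stable) "fibonacci"
    else "composite"
  ratio_lab <- if (is_int) sprintf("%d", as.integer(round(r)))
               else sprintf("%.4f", r)
  structure(list(ratio = r, ell = ell, kind = kind, stable = stable,
                 label = sprintf("|%s,%d>", ratio_lab, ell)),
            class = "block_class")
}

# does any path lead from the fiber back to a regulator?
block_has_feedback <- function(block) {
  if (!length(block$regulators)) return(FALSE)
  if (length(block$feedback_nodes)) return(TRUE)
  e <- block$subgraph$edges
  any(e$source %in% block$fiber & e$target %in% block$regulators)
}

#' @export
print.block_class <- function(x, ...) {
  cat(sprintf("<block_class %s: kind=%s ratio=%.4f ell=%d%s>\n", x$label,
              x$kind, x$ratio, x$ell,
              if (x$stable) "" else " (ratio unstable)"))
  invisible(x)
}

#' Census of all nontrivial-fiber building blocks of a graph
#'
#' @param graph a [signed_digraph]
#' @param partition a `fiber_partition` of `graph`
#' @param include_trivial also classify singleton fibers (default FALSE)
#' @return data frame `fiber_id`, `kind`, `ratio`, `ell`, `label`, `members`
#' @export
block_census <- function(graph, partition, include_trivial = FALSE) {
  ids <- seq_along(partition$fibers)
  if (!include_trivial) ids <- ids[lengths(partition$fibers) >= 2L]
  rows <- lapply(ids, function(i) {
    bl <- extract_building_block(graph, partition$fibers[[i]])
    cl <- classify_block(bl)
    data.frame(fiber_id = i, kind = cl$kind, ratio = cl$ratio, ell = cl$ell,
               label = cl$label,
               members = paste(partition$fibers[[i]], collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(fiber_id = integer(), kind = character(),
                      ratio = numeric(), ell = integer(), label = character(),
                      members = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
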