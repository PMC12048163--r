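# Core container: a signed directed (multi)graph over named nodes.
# Edges carry one of three regulatory effects. Parallel edges of *different*
# effect between the same ordered pair are always meaningful; exact duplicate
# (source, target, effect) rows are permitted at the container level because
# quotient graphs keep edge multiplicities (parser-level deduplication lives
# in read_grn_edge_list()).

#' Regulatory effect levels
#'
#' The three edge types a signed regulatory network distinguishes:
#' `"activation"`, `"repression"` and `"dual"` (a regulator reported as both
#' activator and repressor of the same target).
#'
#' @export
EFFECTS <- c("activation", "repression", "dual")

#' Construct a signed directed graph
#'
#' @param edges data frame with character columns `source`, `target`,
#'   `effect`; `effect` must be one of [EFFECTS]. May be `NULL` or empty for
#'   an edgeless graph. Rows may repeat: the edge set is a multiset.
#' @param nodes additional (possibly isolated) node identifiers; endpoints of
#'   `edges` are always included.
#' @return object of class `signed_digraph`: a list with sorted character
#'   `nodes` and a canonically ordered `edges` data frame.
#' @examples
#' g <- signed_digraph(data.frame(source = "a", target = "b",
#'                                effect = "activation"))
#' node_count(g)
#' @export
signed_digraph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        effect = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges)
  need <- c("source", "target", "effect")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns source, target, effect")
  }
  edges <- edges[, need, drop = FALSE]
  for (cn in need) edges[[cn]] <- as.character(edges[[cn]])
  bad <- setdiff(unique(edges$effect), EFFECTS)
  if (length(bad)) {
    stop("unknown effect value(s): ", paste(bad, collapse = ", "))
  }
  nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  edges <- edges[order(edges$source, edges$target, edges$effect), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat(sprintf("<signed_digraph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    print(utils::head(x$edges, 10L))
    if (nrow(x$edges) > 10L) cat("...\n")
  }
  invisible(x)
}

#' Number of nodes
#' @param graph a `signed_digraph`
#' @export
node_count <- function(graph) length(graph$nodes)

#' Number of edges (with multiplicity)
#' @param graph a `signed_digraph`
#' @export
edge_count <- function(graph) nrow(graph$edges)

stopifnot_digraph <- function(graph) {
  if (!inherits(graph, "signed_digraph")) stop("not a signed_digraph")
  invisible(graph)
}

#' Test two graphs for equality of labelled node and edge multisets
#' @param a,b `signed_digraph` objects
#' @export
graph_equal <- function(a, b) {
  stopifnot_digraph(a); stopifnot_digraph(b)
  identical(a$nodes, b$nodes) &&
    nrow(a$edges) == nrow(b$edges) &&
    all(a$edges == b$edges)
}

#' Induced subgraph on a node subset
#' @param graph a `signed_digraph`
#' @param nodes node identifiers to keep
#' @export
induced_subgraph_sd <- function(graph, nodes) {
  stopifnot_digraph(graph)
  nodes <- intersect(graph$nodes, nodes)
  e <- graph$edges
  keep <- e$source %in% nodes & e$target %in% nodes
  signed_digraph(e[keep, , drop = FALSE], nodes = nodes)
}

#' Convert to an igraph object
#'
#' Edge attribute `effect` and vertex names are preserved; the result is a
#' directed multigraph.
#'
#' @param graph a `signed_digraph`
#' @export
as_igraph <- function(graph) {
  stopifnot_digraph(graph)
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}

#' Convert an igraph object (with `effect` edge attribute) back
#' @param g an igraph graph whose edges carry an `effect` attribute
#' @export
from_igraph <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  v <- igraph::as_data_frame(g, what = "vertices")
  if (!"effect" %in% names(e) && nrow(e)) stop("igraph edges lack 'effect'")
  names(e)[1:2] <- c("source", "target")
  signed_digraph(e[, intersect(c("source", "target", "effect"), names(e)),
                   drop = FALSE],
                 nodes = v$name)
}

# out-degree per node (counting multiplicity; self-loops count once)
out_degrees <- function(graph) {
  d <- stats::setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) {
    t <- table(graph$edges$source)
    d[names(t)] <- as.integer(t)
  }
  d
}

in_degrees <- function(graph) {
  d <- stats::setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) {
    t <- table(graph$edges$target)
    d[names(t)] <- as.integer(t)
  }
  d
}

# list: for each node, data.frame of its in-edges
in_edge_list <- function(graph) {
  out <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) {
    sp <- split(graph$edges, graph$edges$target)
    out[names(sp)] <- sp
  }
  out
}

#' Typed input set of a node
#'
#' The multiset of (source node, effect) pairs over all in-edges of `node`,
#' the first layer of its input tree. Source nodes (in-degree 0) have an
#' empty input set.
#'
#' @param graph a `signed_digraph`
#' @param node a node identifier present in `graph`
#' @return data frame with columns `source`, `effect`, one row per in-edge
#' @export
input_set <- function(graph, node) {
  stopifnot_digraph(graph)
  if (!node %in% graph$nodes) stop("unknown node: ", node)
  e <- graph$edges
  out <- e[e$target == node, c("source", "effect"), drop = FALSE]
  rownames(out) <- NULL
  out
}
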