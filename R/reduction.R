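# Step II (pruning to the out-degree k-core) and Step III (strongly
# connected components, node roles, master SCC).

#' Out-degree k-core of a directed graph
#'
#' Iteratively deletes every node whose out-degree within the remaining
#' subgraph is below `k`, recording each deletion round as a shell, until the
#' remainder is stable. For k = 1 the core is exactly the set of nodes with a
#' directed path to some cycle (self-loops count as cycles): everything else
#' lies on dead-end paths and is trimmed. The result does not depend on
#' deletion order because rounds remove all sub-threshold nodes at once.
#'
#' @param graph a [signed_digraph]
#' @param k minimal out-degree (>= 1)
#' @return object of class `kcore_result`: list with `k`, `core` (node set),
#'   `shells` (list of node sets, outermost first) and `core_graph` (the
#'   induced [signed_digraph])
#' @export
kout_core <- function(graph, k = 1L) {
  stopifnot_digraph(graph)
  if (k < 1L) stop("k must be >= 1")
  alive <- graph$nodes
  e <- graph$edges
  shells <- list()
  repeat {
    keep <- e$source %in% alive & e$target %in% alive
    deg <- stats::setNames(integer(length(alive)), alive)
    if (any(keep)) {
      t <- table(e$source[keep])
      deg[names(t)] <- as.integer(t)
    }
    doomed <- alive[deg < k]
    if (!length(doomed)) break
    shells <- c(shells, list(sort(doomed)))
    alive <- setdiff(alive, doomed)
  }
  structure(list(k = as.integer(k), core = sort(alive), shells = shells,
                 core_graph = induced_subgraph_sd(graph, alive)),
            class = "kcore_result")
}

#' @export
print.kcore_result <- function(x, ...) {
  cat(sprintf("<kout_core k=%d: core %d nodes, %d shell round(s) (%d nodes)>\n",
              x$k, length(x$core), length(x$shells),
              sum(lengths(x$shells))))
  invisible(x)
}

#' Strongly connected components and condensation
#'
#' Components are the maximal node sets in which every node reaches every
#' other. Components of >= 2 nodes are "counted" SCCs (the signal vortices
#' where computation and memory can reside); single nodes whose only cycle is
#' a self-loop are tracked separately as `selfloop_singletons`. The
#' condensation has one vertex per component and a deduplicated typed edge
#' for every regulation between distinct components; it is always acyclic.
#'
#' @param graph a [signed_digraph]
#' @return object of class `scc_decomposition`: list with `components` (list
#'   of node sets, ordered by smallest member), `membership` (named integer
#'   vector), `condensation` (data frame `from`, `to`, `effect` over
#'   component indices), `counted_sccs` (indices of components with >= 2
#'   nodes), `selfloop_singletons` (node set), `roles` (filled by
#'   [classify_roles], else NULL)
#' @export
strongly_connected_components <- function(graph) {
  stopifnot_digraph(graph)
  if (!length(graph$nodes)) {
    return(structure(list(components = list(),
                          membership = stats::setNames(integer(), character()),
                          condensation = data.frame(from = integer(),
                                                    to = integer(),
                                                    effect = character()),
                          counted_sccs = integer(),
                          selfloop_singletons = character(), roles = NULL),
                     class = "scc_decomposition"))
  }
  ig <- as_igraph(graph)
  comp <- igraph::components(ig, mode = "strong")
  memb <- stats::setNames(as.integer(comp$membership[graph$nodes]),
                          graph$nodes)
  components <- split(graph$nodes, memb)
  components <- lapply(components, sort)
  ord <- order(vapply(components, `[[`, "", 1L))
  components <- unname(components[ord])
  relabel <- stats::setNames(seq_along(ord),
                             names(split(graph$nodes, memb))[ord])
  memb <- stats::setNames(relabel[as.character(memb)], graph$nodes)
  e <- graph$edges
  cond <- data.frame(from = integer(), to = integer(), effect = character(),
                     stringsAsFactors = FALSE)
  if (nrow(e)) {
    cf <- unname(memb[e$source]); ct <- unname(memb[e$target])
    cross <- cf != ct
    if (any(cross)) {
      cond <- unique(data.frame(from = cf[cross], to = ct[cross],
                                effect = e$effect[cross],
                                stringsAsFactors = FALSE))
      cond <- cond[order(cond$from, cond$to, cond$effect), , drop = FALSE]
      rownames(cond) <- NULL
    }
  }
  selfloops <- unique(e$source[e$source == e$target])
  singles <- which(lengths(components) == 1L)
  selfloop_singletons <- sort(unlist(components[singles])[
    unlist(components[singles]) %in% selfloops])
  if (is.null(selfloop_singletons)) selfloop_singletons <- character()
  structure(list(components = components, membership = memb,
                 condensation = cond,
                 counted_sccs = which(lengths(components) >= 2L),
                 selfloop_singletons = selfloop_singletons, roles = NULL),
            class = "scc_decomposition")
}

#' @export
print.scc_decomposition <- function(x, ...) {
  cat(sprintf(
    "<scc_decomposition: %d components, %d counted SCC(s), %d self-loop singleton(s)>\n",
    length(x$components), length(x$counted_sccs),
    length(x$selfloop_singletons)))
  invisible(x)
}

#' Assign roles to minimal-network nodes
#'
#' Every node of the minimal (pruned) network is either an `scc_member`
#' (member of a counted SCC, or a self-loop singleton), a `connector`
#' (outside the SCCs but reachable from an SCC member: it relays signals
#' between SCCs, possibly through a chain of other connectors), or a
#' `controller` (sends signals into the SCCs but never receives any back).
#'
#' @param minimal the pruned [signed_digraph] (a k_out = 1 core)
#' @param decomp the `scc_decomposition` of `minimal`
#' @return `decomp` with `roles` filled (named character vector)
#' @export
classify_roles <- function(minimal, decomp) {
  stopifnot_digraph(minimal)
  members <- unique(c(unlist(decomp$components[decomp$counted_sccs]),
                      decomp$selfloop_singletons))
  if (is.null(members)) members <- character()
  roles <- stats::setNames(rep("controller", length(minimal$nodes)),
                           minimal$nodes)
  roles[members] <- "scc_member"
  rest <- setdiff(minimal$nodes, members)
  if (length(rest) && length(members)) {
    ig <- as_igraph(minimal)
    downstream <- reachable_from(ig, members)
    roles[intersect(rest, downstream)] <- "connector"
  }
  decomp$roles <- roles
  decomp
}

#' Identify the master SCC
#'
#' The counted SCC that regulates the most other counted SCCs in the
#' condensation (direct out-neighbors among counted components). Ties are
#' broken by component size, then by lexicographically smallest member.
#'
#' @param decomp an `scc_decomposition`
#' @return index (into `decomp$components`) of the master SCC
#' @export
master_scc <- function(decomp) {
  counted <- decomp$counted_sccs
  if (!length(counted)) stop("no counted SCC (>= 2 nodes) present")
  outreach <- vapply(counted, function(i) {
    tos <- unique(decomp$condensation$to[decomp$condensation$from == i])
    length(intersect(tos, counted))
  }, 0L)
  size <- lengths(decomp$components[counted])
  rep_ <- vapply(decomp$components[counted], `[[`, "", 1L)
  counted[order(-outreach, -size, rep_)][1L]
}

#' Tabulate the minimal network
#'
#' @param minimal the pruned [signed_digraph]
#' @param decomp an `scc_decomposition` with roles filled
#' @param fiber_representatives optional character vector of nodes that
#'   stand for collapsed fibers
#' @return data frame `node`, `role`, `scc_id`, `is_fiber_representative`
#' @export
minimal_network_report <- function(minimal, decomp,
                                   fiber_representatives = character()) {
  if (is.null(decomp$roles)) stop("roles not classified yet")
  data.frame(
    node = minimal$nodes,
    role = unname(decomp$roles[minimal$nodes]),
    scc_id = unname(decomp$membership[minimal$nodes]),
    is_fiber_representative = minimal$nodes %in% fiber_representatives,
    stringsAsFactors = FALSE)
}

#' Export the condensation as a Graphviz DOT file
#'
#' Counted SCCs are drawn as filled component blobs sized by membership;
#' other nodes as plain ellipses.
#'
#' @param decomp an `scc_decomposition`
#' @param path output path
#' @export
write_condensation_dot <- function(decomp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph condensation {", con)
  for (i in seq_along(decomp$components)) {
    comp <- decomp$components[[i]]
    if (i %in% decomp$counted_sccs) {
      writeLines(sprintf(
        "  c%d [label=\"%s\", shape=circle, style=filled, fillcolor=\"#b19cd9\", width=%.2f];",
        i, paste(comp, collapse = "\\n"), 0.5 + 0.1 * length(comp)), con)
    } else {
      writeLines(sprintf("  c%d [label=\"%s\"];", i, comp[1L]), con)
    }
  }
  ce <- unique(decomp$condensation[, c("from", "to")])
  if (nrow(ce)) {
    writeLines(sprintf("  c%d -> c%d;", ce$from, ce$to), con)
  }
  writeLines("}", con)
  invisible(path)
}
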