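# Step I: input trees, minimal balanced coloring (fibers) and the quotient
# by the minimal surjective fibration.
#
# Fibers are found by iterative partition refinement (the equitable-partition
# / balanced-coloring fixpoint): each round recolors every node by its current
# color together with the multiset of (in-neighbor color, edge effect) pairs.
# This is equivalent to comparing typed input trees to depth N-1 but avoids
# materializing the (generally infinite) trees; explicit trees remain
# available for small-instance inspection and oracles.

#' Build the typed input tree of a node
#'
#' The input tree collects all reverse regulatory paths ending at a node: the
#' root is the node itself, each next layer holds the typed in-neighbors of
#' every occurrence in the previous layer. Children are ordered canonically
#' by (effect, recursive canonical form) so that equal trees print equally.
#'
#' Trees grow exponentially with depth on cyclic graphs; use
#' [input_layer_sizes] when only layer counts are needed.
#'
#' @param graph a [signed_digraph]
#' @param node root node identifier
#' @param depth number of layers below the root (>= 0)
#' @return object of class `input_tree`: list with `root`, `depth`, `tree`
#'   (nested lists with `node`, `effect`, `children`), `layers` (per-layer
#'   data frames of (node, effect)) and `canonical` (a canonical string,
#'   root label excluded)
#' @export
input_tree <- function(graph, node, depth) {
  stopifnot_digraph(graph)
  if (!node %in% graph$nodes) stop("unknown node: ", node)
  if (depth < 0) stop("depth must be >= 0")
  inl <- in_edge_list(graph)
  build <- function(v, d) {
    if (d == 0L || is.null(inl[[v]]) || nrow(inl[[v]]) == 0L) {
      return(list(node = v, children = list()))
    }
    ie <- inl[[v]]
    ch <- lapply(seq_len(nrow(ie)), function(i) {
      sub <- build(ie$source[i], d - 1L)
      sub$effect <- ie$effect[i]
      sub
    })
    # canonical order: by (effect, canonical subtree form)
    keys <- vapply(ch, function(s) paste0(s$effect, "|", canon_str(s)), "")
    list(node = v, children = ch[order(keys)])
  }
  tr <- build(node, as.integer(depth))
  layers <- list()
  frontier <- list(tr)
  for (k in seq_len(depth)) {
    nxt <- unlist(lapply(frontier, `[[`, "children"), recursive = FALSE)
    if (!length(nxt)) break
    layers[[k]] <- data.frame(
      node = vapply(nxt, `[[`, "", "node"),
      effect = vapply(nxt, `[[`, "", "effect"),
      stringsAsFactors = FALSE)
    frontier <- nxt
  }
  structure(list(root = node, depth = length(layers),
                 requested_depth = as.integer(depth), tree = tr,
                 layers = layers, canonical = canon_str(tr)),
            class = "input_tree")
}

# canonical string of a (sub)tree, ignoring node labels: children already
# canonically ordered at construction
canon_str <- function(tr) {
  if (!length(tr$children)) return("()")
  inner <- vapply(tr$children, function(s) {
    paste0(substr(s$effect, 1, 1), canon_str(s))
  }, "")
  paste0("(", paste(sort(inner), collapse = ""), ")")
}

#' @export
print.input_tree <- function(x, ...) {
  cat(sprintf("<input_tree rooted at %s, %d layers; sizes: %s>\n", x$root,
              x$depth, paste(vapply(x$layers, nrow, 0L), collapse = ",")))
  invisible(x)
}

#' Test two input trees for typed isomorphism
#'
#' Trees are isomorphic when they have the same shape and matching edge
#' effects at every position (root labels are ignored). For infinite trees,
#' comparing the first N-1 layers (N nodes in the graph) decides isomorphism,
#' so both trees must have been built at least that deep.
#'
#' @param a,b `input_tree` objects
#' @param require_depth minimal construction depth both trees must have
#'   requested (defaults to 0: caller's responsibility); trees that
#'   terminated earlier of their own accord are fine
#' @export
input_trees_isomorphic <- function(a, b, require_depth = 0L) {
  if (!inherits(a, "input_tree") || !inherits(b, "input_tree")) {
    stop("arguments must be input_tree objects")
  }
  if (require_depth > 0L &&
      min(a$requested_depth, b$requested_depth) < require_depth) {
    stop("trees built to insufficient depth for a decisive comparison")
  }
  identical(a$canonical, b$canonical)
}

#' Input-tree layer sizes without materializing the tree
#'
#' Computes the number of nodes in each layer of the input tree of `node`
#' via the counting recurrence: occurrences at layer k+1 are the in-edges of
#' all occurrences at layer k. Linear in edges per layer; layer sizes may
#' still grow geometrically (they do exactly when the branching ratio
#' exceeds 1).
#'
#' @param graph a [signed_digraph]
#' @param node root node
#' @param depth number of layers
#' @return numeric vector of length <= depth (stops early if a layer is
#'   empty), `sizes[k]` = number of tree nodes in layer k
#' @export
input_layer_sizes <- function(graph, node, depth) {
  stopifnot_digraph(graph)
  if (!node %in% graph$nodes) stop("unknown node: ", node)
  n <- length(graph$nodes)
  idx <- stats::setNames(seq_len(n), graph$nodes)
  e <- graph$edges
  si <- idx[e$source]; ti <- idx[e$target]
  occ <- numeric(n); occ[idx[[node]]] <- 1
  sizes <- numeric(0)
  indeg_counts <- function(o) {
    nxt <- numeric(n)
    if (length(si)) {
      w <- o[ti]
      nz <- w > 0
      if (any(nz)) {
        agg <- rowsum(w[nz], si[nz])
        nxt[as.integer(rownames(agg))] <- agg[, 1L]
      }
    }
    nxt
  }
  for (k in seq_len(depth)) {
    occ <- indeg_counts(occ)
    s <- sum(occ)
    if (s == 0) break
    sizes[k] <- s
  }
  sizes
}

#' Minimal balanced coloring (fiber partition)
#'
#' Finds the coarsest balanced partition of the nodes: any two nodes of one
#' color receive equal multisets of (in-neighbor color, effect). Its classes
#' are the fibers — the sets of nodes with isomorphic typed input trees,
#' which synchronize under any dynamics driven through the typed inputs.
#'
#' `source_policy` controls in-degree-0 nodes. Mathematically their input
#' trees are all trivially isomorphic (`"merge"`), but in a regulatory
#' network they stand for distinct unmodeled external inputs, so the default
#' `"distinct"` keeps each in its own class (which can also split nodes
#' downstream of different sources).
#'
#' @param graph a [signed_digraph]
#' @param source_policy `"distinct"` (default) or `"merge"`
#' @return object of class `fiber_partition`: list with `coloring` (named
#'   integer vector node -> color), `fibers` (list of character vectors,
#'   ordered by their lexicographically smallest member), and
#'   `nontrivial_fibers` (the classes with >= 2 members)
#' @export
minimal_balanced_coloring <- function(graph,
                                      source_policy = c("distinct", "merge")) {
  stopifnot_digraph(graph)
  source_policy <- match.arg(source_policy)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) {
    return(structure(list(coloring = stats::setNames(integer(), character()),
                          fibers = list(), nontrivial_fibers = list(),
                          source_policy = source_policy),
                     class = "fiber_partition"))
  }
  idx <- stats::setNames(seq_len(n), nodes)
  e <- graph$edges
  si <- unname(idx[e$source]); ti <- unname(idx[e$target])
  eff <- e$effect
  indeg <- tabulate(ti, nbins = n)
  color <- rep(1L, n)
  if (source_policy == "distinct") {
    src <- which(indeg == 0L)
    # each source its own class; non-sources share one starting class
    color[src] <- seq_along(src) + 1L
  }
  # pre-split in-edges by target for signature building
  by_target <- split(seq_along(ti), ti)
  repeat {
    sig <- character(n)
    for (v in seq_len(n)) {
      rows <- by_target[[as.character(v)]]
      inpart <- if (length(rows)) {
        paste(sort(paste0(color[si[rows]], substr(eff[rows], 1, 1))),
              collapse = ",")
      } else ""
      sig[v] <- paste0(color[v], "|", inpart)
    }
    newcolor <- match(sig, unique(sig))
    if (length(unique(newcolor)) == length(unique(color))) {
      color <- newcolor
      break
    }
    color <- newcolor
  }
  fibers <- split(nodes, color)
  reps <- vapply(fibers, min, "")
  fibers <- unname(fibers[order(reps)])
  coloring <- stats::setNames(integer(n), nodes)
  for (i in seq_along(fibers)) coloring[fibers[[i]]] <- i
  structure(list(coloring = coloring, fibers = fibers,
                 nontrivial_fibers = fibers[lengths(fibers) >= 2L],
                 source_policy = source_policy),
            class = "fiber_partition")
}

#' @export
print.fiber_partition <- function(x, ...) {
  cat(sprintf("<fiber_partition: %d fibers (%d nontrivial), policy=%s>\n",
              length(x$fibers), length(x$nontrivial_fibers),
              x$source_policy))
  invisible(x)
}

# is `partition` balanced on `graph`? (every color class has equal
# (in-color, effect) multisets)
is_balanced <- function(graph, coloring) {
  e <- graph$edges
  sigs <- vapply(graph$nodes, function(v) {
    ie <- e[e$target == v, , drop = FALSE]
    paste(sort(paste0(coloring[ie$source], ie$effect)), collapse = ",")
  }, "")
  all(vapply(split(sigs, coloring[graph$nodes]),
             function(s) length(unique(s)) == 1L, TRUE))
}

#' Collapse fibers into the base graph (minimal surjective fibration)
#'
#' Each fiber is replaced by a single representative node (its
#' lexicographically smallest member). The base keeps, for every
#' representative, the representative's typed in-edges with sources renamed
#' to their representatives — multiplicities included, because edges
#' targeting one node are never merged (the lifting property requires each
#' base in-edge to lift uniquely at every pre-image).
#'
#' @param graph a [signed_digraph]
#' @param partition a `fiber_partition` for `graph` (must be balanced)
#' @return list with `base` (a [signed_digraph]), `node_map` (named character
#'   vector node -> base node) and `representative` (named character vector
#'   fiber index -> representative)
#' @export
collapse_fibers <- function(graph, partition) {
  stopifnot_digraph(graph)
  if (!inherits(partition, "fiber_partition")) stop("need a fiber_partition")
  if (!setequal(names(partition$coloring), graph$nodes)) {
    stop("partition does not cover the graph's nodes")
  }
  if (!is_balanced(graph, partition$coloring)) {
    stop("partition is not balanced on this graph")
  }
  reps <- vapply(partition$fibers, min, "")
  node_map <- stats::setNames(
    reps[partition$coloring[graph$nodes]], graph$nodes)
  e <- graph$edges
  keep <- e$target %in% reps        # in-edges of representatives only
  be <- e[keep, , drop = FALSE]
  if (nrow(be)) be$source <- unname(node_map[be$source])
  base <- signed_digraph(be, nodes = reps)
  list(base = base, node_map = node_map,
       representative = stats::setNames(reps, seq_along(reps)))
}

#' Verify the lifting property of a quotient map
#'
#' A morphism G -> B is a fibration iff every base edge targeting the image
#' of a node lifts to exactly one edge targeting that node. With edge
#' multiplicities this says: for every node i, the multiset of
#' (image of source, effect) over i's in-edges equals the in-edge multiset of
#' its image in the base.
#'
#' @param graph the total [signed_digraph]
#' @param base the candidate base [signed_digraph]
#' @param node_map named character vector mapping every `graph` node to a
#'   `base` node
#' @return `TRUE` iff the lifting property holds at every node
#' @export
verify_lifting_property <- function(graph, base, node_map) {
  stopifnot_digraph(graph); stopifnot_digraph(base)
  if (!all(graph$nodes %in% names(node_map))) stop("node_map not total")
  if (!all(node_map[graph$nodes] %in% base$nodes)) return(FALSE)
  be <- base$edges
  base_in <- function(v) {
    ie <- be[be$target == v, , drop = FALSE]
    sort(paste0(ie$source, "|", ie$effect))
  }
  ge <- graph$edges
  for (i in graph$nodes) {
    ie <- ge[ge$target == i, , drop = FALSE]
    lifted <- sort(paste0(unname(node_map[ie$source]), "|", ie$effect))
    if (!identical(lifted, base_in(unname(node_map[[i]])))) return(FALSE)
  }
  TRUE
}

#' Write a fiber report
#'
#' TSV with columns `fiber_id`, `size`, `members` (comma-separated) and
#' `representative`.
#'
#' @param partition a `fiber_partition`
#' @param path output path
#' @export
write_fiber_report <- function(partition, path) {
  df <- fiber_report(partition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate a fiber partition
#' @param partition a `fiber_partition`
#' @return data frame with one row per fiber
#' @export
fiber_report <- function(partition) {
  data.frame(
    fiber_id = seq_along(partition$fibers),
    size = lengths(partition$fibers),
    members = vapply(partition$fibers, paste, "", collapse = ","),
    representative = vapply(partition$fibers, min, ""),
    stringsAsFactors = FALSE)
}
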