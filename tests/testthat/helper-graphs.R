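# Shared fixtures and independent oracles.
# Oracles deliberately use different algorithms from the package code paths
# they check (explicit tree canonicalization instead of partition refinement,
# reachability instead of iterative peeling, subset/rotation enumeration
# instead of rooted DFS).

fib_fixture <- function() make_canonical_block("fibonacci")

# random signed digraph: n nodes, on average `density` * n directed edges,
# effects sampled from the full alphabet
random_graph <- function(n, density = 1.4,
                         effects = c("activation", "repression", "dual"),
                         p_selfloop = 0.1) {
  nodes <- sprintf("v%02d", seq_len(n))
  m <- max(1L, rpois(1L, density * n))
  src <- sample(nodes, m, replace = TRUE)
  tgt <- sample(nodes, m, replace = TRUE)
  keep_self <- runif(m) < p_selfloop
  drop <- src == tgt & !keep_self
  e <- data.frame(source = src[!drop], target = tgt[!drop],
                  effect = sample(effects, sum(!drop), replace = TRUE),
                  stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$source, e$target, e$effect)), , drop = FALSE]
  signed_digraph(e, nodes = nodes)
}

# ---- oracle 1: fiber partition via explicit canonical input-tree forms ----

# canonical string of the depth-d input tree of v; sources optionally carry
# their identity (the "distinct" treatment of in-degree-0 nodes)
oracle_canon <- function(graph, v, depth, label_sources) {
  ins <- graph$edges[graph$edges$target == v, , drop = FALSE]
  if (nrow(ins) == 0L) {
    return(if (label_sources) paste0("[", v, "]") else "()")
  }
  if (depth == 0L) return("()")
  inner <- sort(vapply(seq_len(nrow(ins)), function(i) {
    paste0(substr(ins$effect[i], 1L, 1L),
           oracle_canon(graph, ins$source[i], depth - 1L, label_sources))
  }, ""))
  paste0("(", paste(inner, collapse = ""), ")")
}

# partition of the nodes by input-tree isomorphism at depth N (>= N-1, the
# decisive depth), as a canonical list of sorted classes
oracle_fiber_partition <- function(graph, policy) {
  n <- length(graph$nodes)
  canon <- vapply(graph$nodes, oracle_canon, "", graph = graph, depth = n,
                  label_sources = (policy == "distinct"))
  classes <- split(graph$nodes, canon)
  classes <- lapply(classes, sort)
  unname(classes[order(vapply(classes, `[[`, "", 1L))])
}

partition_as_classes <- function(partition) {
  classes <- lapply(partition$fibers, sort)
  unname(classes[order(vapply(classes, `[[`, "", 1L))])
}

# ---- oracle 2: k_out = 1 core as "has a directed path to a cycle" --------

oracle_core1 <- function(graph) {
  ig <- as_igraph(graph)
  comp <- igraph::components(ig, mode = "strong")
  big <- names(comp$membership)[comp$membership %in%
                                  which(comp$csize >= 2L)]
  selfloop <- unique(graph$edges$source[graph$edges$source ==
                                          graph$edges$target])
  cyclic <- union(big, selfloop)
  if (!length(cyclic)) return(character())
  reach <- cyclic
  for (v in cyclic) {
    reach <- union(reach, igraph::subcomponent(ig, v, mode = "in")$name)
  }
  sort(reach)
}

# ---- oracle 3: simple cycles by subset + rotation enumeration ------------

oracle_simple_cycles <- function(graph) {
  nodes <- graph$nodes
  e <- graph$edges[graph$edges$source != graph$edges$target, , drop = FALSE]
  has_edge <- unique(paste(e$source, e$target, sep = "\r"))
  found <- character()
  n <- length(nodes)
  for (k in 2:max(2, n)) {
    if (k > n) break
    subs <- utils::combn(nodes, k, simplify = FALSE)
    for (s in subs) {
      first <- s[1L]                       # smallest member anchors rotation
      rest <- s[-1L]
      perms <- all_perms(rest)
      for (p in perms) {
        cyc <- c(first, p)
        edges_ok <- all(paste(cyc, c(cyc[-1L], cyc[1L]),
                              sep = "\r") %in% has_edge)
        if (edges_ok) found <- c(found, paste(cyc, collapse = ","))
      }
    }
  }
  sort(unique(found))
}

all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

# random input-multiset-respecting Boolean rules: threshold on a weighted
# activator/repressor balance
random_boolean_rule <- function() {
  w <- sample(1:2, 1L)
  th <- sample(0:1, 1L)
  force(w); force(th)
  function(act, rep, act_tot, rep_tot) as.integer(act - w * rep >= th)
}
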