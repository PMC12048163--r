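# Steps IV and V: two-node logic circuits embedded in the SCCs and the
# census of simple directed cycles.

#' Find all two-node circuits (reciprocal regulation pairs)
#'
#' One record per unordered node pair with at least one edge in each
#' direction, in lexicographic pair order. `forward` refers to the
#' direction first-member -> second-member. When parallel edges of different
#' effect run in one direction, all effects are recorded.
#'
#' @param graph a [signed_digraph]
#' @return list of `circuit_record` objects: `pair` (sorted length-2
#'   character), `forward_effects`, `backward_effects`, `self_effects`
#'   (named list member -> effects of its self-loops), `circuit_class`
#'   (NULL until [classify_circuit]), `breaking_inputs` (NULL until
#'   [symmetry_breaking_inputs])
#' @export
find_two_node_circuits <- function(graph) {
  stopifnot_digraph(graph)
  e <- graph$edges
  e <- e[e$source != e$target, , drop = FALSE]
  if (!nrow(e)) return(list())
  fwd <- paste(e$source, e$target, sep = "\r")
  pairs <- unique(t(apply(unique(e[, c("source", "target")]), 1L, sort)))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- unname(pairs[i, 1L]); b <- unname(pairs[i, 2L])
    fe <- sort(unique(e$effect[e$source == a & e$target == b]))
    be <- sort(unique(e$effect[e$source == b & e$target == a]))
    if (!length(fe) || !length(be)) next
    key <- paste(a, b)
    out[[key]] <- structure(
      list(pair = c(a, b), forward_effects = fe, backward_effects = be,
           self_effects = self_loop_effects(graph, c(a, b)),
           circuit_class = NULL, breaking_inputs = NULL),
      class = "circuit_record")
  }
  if (!length(out)) return(list())
  out[order(names(out))]
}

self_loop_effects <- function(graph, nodes) {
  e <- graph$edges
  stats::setNames(lapply(nodes, function(v) {
    sort(unique(e$effect[e$source == v & e$target == v]))
  }), nodes)
}

#' Classify a two-node circuit
#'
#' Rules, on the reciprocal effect pair:
#' \itemize{
#'   \item mutual repression -> `toggle_switch` (bistable memory; set/reset
#'     flip-flop);
#'   \item mixed activation/repression -> `nfbl_oscillator` (negative
#'     feedback loop), upgraded to `smolen_oscillator` when both members
#'     carry self-loops;
#'   \item mutual activation -> `lock_on` (latch, typically with positive
#'     autoregulation);
#'   \item any dual edge, or parallel edges of different effect in one
#'     direction -> `various` (capable of several behaviors).
#' }
#'
#' @param record a `circuit_record`
#' @return the record with `circuit_class` filled
#' @export
classify_circuit <- function(record) {
  if (!inherits(record, "circuit_record")) stop("need a circuit_record")
  fe <- record$forward_effects; be <- record$backward_effects
  cls <-
    if ("dual" %in% c(fe, be) || length(fe) > 1L || length(be) > 1L) {
      "various"
    } else if (fe == "repression" && be == "repression") {
      "toggle_switch"
    } else if (fe == "activation" && be == "activation") {
      "lock_on"
    } else {
      both_self <- all(lengths(record$self_effects[record$pair]) > 0L)
      if (both_self) "smolen_oscillator" else "nfbl_oscillator"
    }
  record$circuit_class <- cls
  record
}

#' @export
print.circuit_record <- function(x, ...) {
  cat(sprintf("<circuit %s <-> %s: %s/%s%s>\n", x$pair[1L], x$pair[2L],
              paste(x$forward_effects, collapse = "+"),
              paste(x$backward_effects, collapse = "+"),
              if (is.null(x$circuit_class)) ""
              else paste0(" [", x$circuit_class, "]")))
  invisible(x)
}

#' Symmetry-breaking inputs of a circuit
#'
#' For each member, the typed regulators (excluding the pair itself) that the
#' other member does not share. A regulator shared with equal effect is
#' symmetric; sharing with different effects breaks the symmetry for both
#' members. An unbroken pair (both sets empty) is a candidate n=2 fiber
#' rather than a functional memory/oscillator circuit.
#'
#' @param graph a [signed_digraph]
#' @param record a `circuit_record`
#' @return the record with `breaking_inputs` filled: named list member ->
#'   data frame (`source`, `effect`)
#' @export
symmetry_breaking_inputs <- function(graph, record) {
  stopifnot_digraph(graph)
  a <- record$pair[1L]; b <- record$pair[2L]
  inp <- function(v) {
    s <- input_set(graph, v)
    s <- s[!s$source %in% record$pair, , drop = FALSE]
    unique(paste(s$source, s$effect, sep = "\r"))
  }
  ia <- inp(a); ib <- inp(b)
  unpack <- function(keys) {
    if (!length(keys)) {
      return(data.frame(source = character(), effect = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(keys, "\r", fixed = TRUE)
    df <- data.frame(source = vapply(parts, `[[`, "", 1L),
                     effect = vapply(parts, `[[`, "", 2L),
                     stringsAsFactors = FALSE)
    df[order(df$source, df$effect), , drop = FALSE]
  }
  record$breaking_inputs <- stats::setNames(
    list(unpack(setdiff(ia, ib)), unpack(setdiff(ib, ia))), c(a, b))
  record
}

#' Feedforward-fiber circuits
#'
#' Finds triples (fff fiber, its regulators, downstream circuit) where some
#' members of a feedforward fiber regulate both nodes of a detected two-node
#' circuit, so the synchronized fiber drives the circuit's inputs jointly.
#'
#' @param graph a [signed_digraph]
#' @param partition a `fiber_partition` of `graph`
#' @param circuits list of `circuit_record` (see [find_two_node_circuits])
#' @return list of lists with `fiber`, `regulators`, `circuit`
#' @export
find_fff_circuits <- function(graph, partition, circuits) {
  stopifnot_digraph(graph)
  out <- list()
  e <- graph$edges
  for (i in seq_along(partition$fibers)) {
    fib <- partition$fibers[[i]]
    if (length(fib) < 2L) next
    bl <- extract_building_block(graph, fib)
    cl <- classify_block(bl)
    if (cl$kind != "fff") next
    for (rec in circuits) {
      reach_a <- any(e$source %in% fib & e$target == rec$pair[1L])
      reach_b <- any(e$source %in% fib & e$target == rec$pair[2L])
      if (reach_a && reach_b) {
        out[[length(out) + 1L]] <- list(fiber = fib,
                                        regulators = bl$regulators,
                                        circuit = rec)
      }
    }
  }
  out
}

#' Enumerate simple directed cycles
#'
#' All elementary directed cycles of length >= 2 (self-loops are excluded
#' from the census; they are reported elsewhere as n-ary fiber loops or
#' autoregulation). Each cycle is reported once, rotated to start at its
#' smallest node. Enumeration is a Johnson-style search: cycles are rooted at
#' their smallest node and the DFS never revisits a node within the current
#' path nor descends below the root.
#'
#' @param graph a [signed_digraph]
#' @param max_length maximal cycle length (default `Inf`)
#' @param max_cycles abort with an error if more than this many cycles are
#'   found (default 100000), advising a `max_length` bound
#' @return list of `cycle_record` objects: `nodes` (canonical rotation),
#'   `length`, `overall_sign` (NULL until [cycle_sign]),
#'   `circuits_traversed` (NULL until [annotate_cycles])
#' @export
simple_cycles <- function(graph, max_length = Inf, max_cycles = 1e5) {
  stopifnot_digraph(graph)
  nodes <- graph$nodes
  e <- graph$edges
  e <- e[e$source != e$target, , drop = FALSE]
  adj <- stats::setNames(lapply(nodes, function(v) {
    sort(unique(e$target[e$source == v]))
  }), nodes)
  cycles <- list()
  path <- character()
  on_path <- new.env(parent = emptyenv())
  root <- NULL
  dfs <- function(v) {
    path[[length(path) + 1L]] <<- v
    assign(v, TRUE, envir = on_path)
    for (w in adj[[v]]) {
      if (w < root) next               # cycles are rooted at their minimum
      if (w == root) {
        if (length(path) >= 2L) {
          if (length(cycles) >= max_cycles) {
            stop("more than ", max_cycles,
                 " simple cycles; pass a max_length bound")
          }
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (!isTRUE(mget(w, envir = on_path,
                              ifnotfound = FALSE)[[1L]])) {
        if (length(path) < max_length) dfs(w)
      }
    }
    path <<- path[-length(path)]
    assign(v, FALSE, envir = on_path)
  }
  for (r in nodes) {
    root <- r
    path <- character()
    dfs(r)
  }
  lapply(cycles, function(cy) {
    structure(list(nodes = unlist(cy), length = length(cy),
                   overall_sign = NULL, sign_combinations = NULL,
                   circuits_traversed = NULL),
              class = "cycle_record")
  })
}

#' @export
print.cycle_record <- function(x, ...) {
  cat(sprintf("<cycle [%s]%s>\n", paste(x$nodes, collapse = " -> "),
              if (is.null(x$overall_sign)) ""
              else paste0(" ", x$overall_sign)))
  invisible(x)
}

#' Overall sign of a cycle
#'
#' The product of edge signs around the cycle (activation = +1, repression =
#' -1): an even number of repressions makes an overall activation (positive
#' feedback), an odd number an overall inhibition (negative feedback). A dual
#' edge anywhere makes the sign `undetermined`. When parallel edges of
#' different sign connect consecutive nodes, every achievable sign
#' combination is computed (`sign_combinations`); `overall_sign` is the
#' unique value when there is one and `undetermined` otherwise.
#'
#' @param record a `cycle_record`
#' @param graph the [signed_digraph] the cycle lives in
#' @return the record with `overall_sign` and `sign_combinations` filled
#' @export
cycle_sign <- function(record, graph) {
  stopifnot_digraph(graph)
  nds <- record$nodes
  e <- graph$edges
  step_signs <- vector("list", length(nds))
  for (i in seq_along(nds)) {
    s <- nds[i]; t <- nds[if (i == length(nds)) 1L else i + 1L]
    effs <- unique(e$effect[e$source == s & e$target == t])
    if (!length(effs)) stop("cycle edge ", s, " -> ", t, " not in graph")
    step_signs[[i]] <- effs
  }
  if (any(vapply(step_signs, function(x) "dual" %in% x, TRUE))) {
    record$overall_sign <- "undetermined"
    record$sign_combinations <- character()
    return(record)
  }
  prods <- Reduce(function(acc, effs) {
    unique(as.vector(outer(acc, ifelse(effs == "activation", 1L, -1L), `*`)))
  }, step_signs, accumulate = FALSE, init = 1L)
  combos <- sort(ifelse(prods > 0, "activation", "inhibition"))
  record$sign_combinations <- combos
  record$overall_sign <- if (length(combos) == 1L) combos else "undetermined"
  record
}

#' Annotate cycles with the circuits they traverse
#'
#' A circuit is traversed by a cycle when both its members lie on the cycle.
#' Cycles of length 2 that are themselves circuits list themselves.
#'
#' @param cycles list of `cycle_record`
#' @param circuits list of `circuit_record`
#' @return the cycles with `circuits_traversed` filled (list of pairs)
#' @export
annotate_cycles <- function(cycles, circuits) {
  pairs <- unname(lapply(circuits, `[[`, "pair"))
  lapply(cycles, function(cy) {
    cy$circuits_traversed <- Filter(function(p) all(p %in% cy$nodes), pairs)
    cy
  })
}

#' Tabulate circuits
#' @param circuits list of classified `circuit_record`
#' @return data frame, one row per circuit
#' @export
circuit_report <- function(circuits) {
  if (!length(circuits)) {
    return(data.frame(member_a = character(), member_b = character(),
                      class = character(), self_effects = character(),
                      breaking_inputs = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(circuits, function(x) {
    se <- vapply(x$pair, function(v) {
      eff <- x$self_effects[[v]]
      if (!length(eff)) "" else paste(eff, collapse = "+")
    }, "")
    bi <- if (is.null(x$breaking_inputs)) "" else {
      paste(vapply(x$pair, function(v) {
        df <- x$breaking_inputs[[v]]
        if (!nrow(df)) "-" else paste(paste0(df$source, "(", substr(df$effect, 1, 1), ")"),
                                      collapse = ",")
      }, ""), collapse = " | ")
    }
    data.frame(member_a = x$pair[1L], member_b = x$pair[2L],
               class = if (is.null(x$circuit_class)) NA_character_
                       else x$circuit_class,
               self_effects = paste(se, collapse = " | "),
               breaking_inputs = bi, stringsAsFactors = FALSE)
  }))
}

#' Tabulate cycles
#' @param cycles list of `cycle_record`
#' @return data frame, one row per cycle
#' @export
cycle_report <- function(cycles) {
  if (!length(cycles)) {
    return(data.frame(length = integer(), nodes = character(),
                      overall_sign = character(),
                      circuits_traversed = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(cycles, function(x) {
    data.frame(
      length = x$length, nodes = paste(x$nodes, collapse = ","),
      overall_sign = if (is.null(x$overall_sign)) NA_character_
                     else x$overall_sign,
      circuits_traversed = if (is.null(x$circuits_traversed)) NA_character_
        else paste(vapply(x$circuits_traversed, paste, "", collapse = "-"),
                   collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}
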