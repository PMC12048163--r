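# Canonical building-block fixtures, a planted-structure synthetic network
# generator, and a synchronous Boolean dynamics checker for the fiber
# synchronization property.

#' Canonical building-block and circuit fixtures
#'
#' Deterministic small graphs realizing each fiber building-block class and
#' logic-circuit archetype:
#' \itemize{
#'   \item `trivial`: fiber `f1..fn` with no internal loops, `ell` external
#'     regulators driving every member identically;
#'   \item `fff`: feedforward fiber, every member self-looped, `ell` external
#'     regulators (branching ratio 1);
#'   \item `n_ary` / `n2`: fiber of `n` (>= 2) genes, each regulated by all
#'     `n` fiber members including itself (branching ratio n; `n2` is the
#'     two-loop case);
#'   \item `fibonacci`: the four-node block on nodes 1..4 with edges
#'     1->2, 1->3, 2->1, 2->2, 2->3, 4->2, 4->3 (all activation): fiber
#'     {2,3}, a self-loop plus feedback to regulator 1, external regulator 4;
#'     branching ratio = golden ratio, l = 2. Extra external regulators are
#'     added for `ell` > 2;
#'   \item `toggle`: mutual repression a|-b, b|-a;
#'   \item `nfbl`: a->b activation, b|-a repression;
#'   \item `smolen`: `nfbl` plus activating self-loops on both members;
#'   \item `lock_on`: mutual activation plus a positive self-loop on a.
#' }
#'
#' @param kind fixture name (see above)
#' @param n fiber size / branching parameter where applicable
#' @param ell number of external regulators where applicable
#' @return a [signed_digraph]
#' @export
make_canonical_block <- function(kind = c("fibonacci", "trivial", "n_ary",
                                          "fff", "n2", "toggle", "nfbl",
                                          "smolen", "lock_on"),
                                 n = 2L, ell = 2L) {
  kind <- match.arg(kind)
  act <- function(s, t) data.frame(source = s, target = t,
                                   effect = "activation",
                                   stringsAsFactors = FALSE)
  rep_ <- function(s, t) data.frame(source = s, target = t,
                                    effect = "repression",
                                    stringsAsFactors = FALSE)
  fiber_nodes <- function(n) paste0("f", seq_len(n))
  reg_nodes <- function(l) if (l > 0L) paste0("r", seq_len(l)) else character()
  drive <- function(regs, fib) {
    if (!length(regs)) return(NULL)
    act(rep(regs, each = length(fib)), rep(fib, times = length(regs)))
  }
  if (kind == "fibonacci") {
    if (ell < 2L) stop("the fibonacci block needs ell >= 2")
    e <- act(c("1", "1", "2", "2", "2", "4", "4"),
             c("2", "3", "1", "2", "3", "2", "3"))
    if (ell > 2L) {
      extra <- paste0("r", seq_len(ell - 2L))
      e <- rbind(e, act(rep(extra, each = 2L), rep(c("2", "3"), ell - 2L)))
    }
    return(signed_digraph(e))
  }
  if (kind == "trivial") {
    if (n < 2L) stop("trivial fiber fixture needs n >= 2")
    if (ell < 1L) stop("trivial fiber fixture needs ell >= 1")
    fib <- fiber_nodes(n)
    return(signed_digraph(drive(reg_nodes(ell), fib)))
  }
  if (kind == "fff") {
    if (n < 2L) stop("fff fixture needs n >= 2")
    fib <- fiber_nodes(n)
    e <- rbind(act(fib, fib), drive(reg_nodes(ell), fib))
    return(signed_digraph(e))
  }
  if (kind %in% c("n_ary", "n2")) {
    if (kind == "n2") n <- 2L
    if (n < 2L) stop("n_ary fixture needs n >= 2")
    fib <- fiber_nodes(n)
    e <- act(rep(fib, each = n), rep(fib, times = n))  # all n^2 fiber edges
    e <- rbind(e, drive(reg_nodes(ell), fib))
    return(signed_digraph(e))
  }
  if (kind == "toggle") {
    return(signed_digraph(rbind(rep_("a", "b"), rep_("b", "a"))))
  }
  if (kind == "nfbl") {
    return(signed_digraph(rbind(act("a", "b"), rep_("b", "a"))))
  }
  if (kind == "smolen") {
    return(signed_digraph(rbind(act("a", "b"), rep_("b", "a"),
                                act("a", "a"), act("b", "b"))))
  }
  # lock_on
  signed_digraph(rbind(act("a", "b"), act("b", "a"), act("a", "a")))
}

#' Generate a synthetic regulatory network with planted structure
#'
#' Emulates the architecture of reduced bacterial regulatory networks: a
#' feedforward chain of strongly connected components (signal vortices),
#' controllers feeding into them, and synchronized fiber genes hanging off
#' the SCC outputs into the periphery. The planted truth is recoverable by
#' construction:
#' \itemize{
#'   \item SCCs of size >= 3 are directed cycles with a chord (node 1 ->
#'     node 3), which makes every member's input history distinct, so no
#'     accidental fibers arise inside an SCC;
#'   \item 2-node SCCs are reciprocal pairs (the planted circuits); when a
#'     pair would be input-symmetric (equal effects, no external input) its
#'     effects are made unequal, so no accidental n=2 fiber arises;
#'   \item planted fibers are sets of sink genes driven identically by a
#'     regulator set unique to the fiber (so distinct fibers never merge);
#'   \item controllers are in-degree-0 nodes with edges into SCC entry
#'     points.
#' }
#'
#' @param n_sccs number of strongly connected components (>= 1)
#' @param scc_size_range length-2 integer range of SCC sizes (min >= 2)
#' @param n_fibers number of planted (nontrivial) fibers
#' @param fiber_size_range length-2 integer range of fiber sizes (min >= 2)
#' @param n_controllers number of controller nodes
#' @param effect_mix named numeric probabilities over [EFFECTS] for edge
#'   effects inside SCCs (fiber-drive and controller edges are activation)
#' @param seed integer seed; generation is deterministic per seed
#' @return list with `graph` (a [signed_digraph]) and `truth`: `fibers`
#'   (list of node sets), `scc_count`, `sccs` (list of node sets),
#'   `circuits` (list of `pair` + `class`), `controller_nodes`
#' @export
generate_synthetic_grn <- function(n_sccs = 3L, scc_size_range = c(3L, 6L),
                                   n_fibers = 2L, fiber_size_range = c(2L, 4L),
                                   n_controllers = 2L,
                                   effect_mix = c(activation = 0.6,
                                                  repression = 0.35,
                                                  dual = 0.05),
                                   seed = 1L) {
  stopifnot(n_sccs >= 1L, scc_size_range[1L] >= 2L,
            scc_size_range[2L] >= scc_size_range[1L],
            fiber_size_range[1L] >= 2L)
  effect_mix <- effect_mix[intersect(names(effect_mix), EFFECTS)]
  effect_mix <- effect_mix / sum(effect_mix)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  rand_eff <- function(k) sample(names(effect_mix), k, replace = TRUE,
                                 prob = effect_mix)
  edges <- list()
  add <- function(s, t, eff) {
    edges[[length(edges) + 1L]] <<- data.frame(source = s, target = t,
                                               effect = eff,
                                               stringsAsFactors = FALSE)
  }
  sccs <- list()
  circuits <- list()
  sizes <- sample(seq(scc_size_range[1L], scc_size_range[2L]), n_sccs,
                  replace = TRUE)
  for (i in seq_len(n_sccs)) {
    m <- sizes[i]
    vs <- sprintf("s%02d_%02d", i, seq_len(m))
    sccs[[i]] <- vs
    if (m == 2L) {
      effs <- rand_eff(2L)
      # a symmetric pair with no asymmetric external input would be a fiber,
      # not a circuit; make the reciprocal effects differ
      has_external <- i > 1L || n_controllers > 0L
      if (effs[1L] == effs[2L] && !has_external) {
        effs[2L] <- if (effs[1L] == "activation") "repression" else "activation"
      }
      add(vs[1L], vs[2L], effs[1L])
      add(vs[2L], vs[1L], effs[2L])
      circuits[[length(circuits) + 1L]] <-
        list(pair = sort(vs), class = circuit_class_of(effs, self_loops = 0L))
    } else if (m == 3L) {
      # a chord inside 3 nodes would create an unplanted 2-cycle; break the
      # rotational symmetry through the edge effects instead
      effs <- rand_eff(3L)
      if (length(unique(effs)) == 1L) {
        effs[1L] <- if (effs[1L] == "activation") "repression" else "activation"
      }
      add(vs, c(vs[-1L], vs[1L]), effs)
    } else {
      nxt <- c(vs[-1L], vs[1L])
      add(vs, nxt, rand_eff(m))
      # chord: breaks cycle symmetry; fixed repression so the chorded node's
      # typed input set can never coincide with a planted fiber's (fiber
      # drive is purely activating)
      add(vs[1L], vs[3L], "repression")
    }
  }
  # feedforward chain between SCC entry nodes (condensation stays acyclic)
  if (n_sccs > 1L) {
    for (i in seq_len(n_sccs - 1L)) {
      add(sccs[[i]][1L], sccs[[i + 1L]][1L], rand_eff(1L))
    }
  }
  controllers <- character()
  if (n_controllers > 0L) {
    controllers <- sprintf("c%02d", seq_len(n_controllers))
    for (i in seq_len(n_controllers)) {
      add(controllers[i], sccs[[1L + (i - 1L) %% n_sccs]][1L], "activation")
    }
  }
  fibers <- list()
  if (n_fibers > 0L) {
    core_nodes <- unlist(sccs)
    if (n_fibers > length(core_nodes) - 1L) {
      stop("too many fibers for the core size: need n_fibers <= total SCC nodes - 1")
    }
    for (i in seq_len(n_fibers)) {
      fs <- sample(seq(fiber_size_range[1L], fiber_size_range[2L]), 1L)
      fib <- sprintf("g%02d_%02d", i, seq_len(fs))
      # each fiber is driven (activation) by a distinct pair of consecutive
      # core nodes; no core node carries exactly such an activating pair as
      # its input set, so planted fibers are exactly the nontrivial fibers
      regs <- core_nodes[c(i, i + 1L)]
      for (r in regs) add(rep(r, fs), fib, "activation")
      fibers[[length(fibers) + 1L]] <- fib
    }
  }
  graph <- signed_digraph(do.call(rbind, edges))
  list(graph = graph,
       truth = list(fibers = fibers, scc_count = n_sccs, sccs = sccs,
                    circuits = circuits, controller_nodes = controllers))
}

# ground-truth class of a reciprocal effect pair (no dual handling needed
# for generated circuits beyond the fall-through)
circuit_class_of <- function(effs, self_loops) {
  if ("dual" %in% effs) return("various")
  n_rep <- sum(effs == "repression")
  if (n_rep == 2L) "toggle_switch"
  else if (n_rep == 0L) "lock_on"
  else if (self_loops >= 2L) "smolen_oscillator"
  else "nfbl_oscillator"
}

#' Synchronous Boolean simulation
#'
#' Updates all nodes simultaneously. The default rule `"activator_or"`: a
#' node switches on iff no active repressor targets it and (it has at least
#' one active activator, or it has no activator inputs at all). Dual edges
#' act as activators under the default (`dual_as` knob). Nodes without any
#' inputs (sources) hold their initial value. Any rule that is a function of
#' the typed input multiset keeps fiber members synchronized when they start
#' equal.
#'
#' @param graph a [signed_digraph]
#' @param initial named 0/1 vector covering all nodes
#' @param steps number of synchronous updates
#' @param rule `"activator_or"` or a function
#'   `(n_act_active, n_rep_active, n_act_total, n_rep_total) -> 0/1`
#'   (dual edges folded per `dual_as` before the call)
#' @param dual_as treat dual edges as `"activation"` (default) or
#'   `"repression"`
#' @return object of class `boolean_trajectory`: `states` is a
#'   (steps+1) x nodes 0/1 matrix, row 1 the initial state
#' @export
boolean_simulate <- function(graph, initial, steps = 50L,
                             rule = "activator_or",
                             dual_as = c("activation", "repression")) {
  stopifnot_digraph(graph)
  dual_as <- match.arg(dual_as)
  nodes <- graph$nodes
  if (!all(nodes %in% names(initial))) stop("initial must cover all nodes")
  init <- as.integer(initial[nodes] != 0)
  e <- graph$edges
  eff <- ifelse(e$effect == "dual", dual_as, e$effect)
  idx <- stats::setNames(seq_along(nodes), nodes)
  si <- unname(idx[e$source]); ti <- unname(idx[e$target])
  is_act <- eff == "activation"
  n_act_total <- tabulate(ti[is_act], nbins = length(nodes))
  n_rep_total <- tabulate(ti[!is_act], nbins = length(nodes))
  is_source <- (n_act_total + n_rep_total) == 0L
  f <- if (is.function(rule)) {
    rule
  } else if (identical(rule, "activator_or")) {
    function(act, rep, act_tot, rep_tot) {
      as.integer(rep == 0L & (act > 0L | act_tot == 0L))
    }
  } else {
    stop("unknown rule: ", rule)
  }
  states <- matrix(NA_integer_, nrow = steps + 1L, ncol = length(nodes),
                   dimnames = list(NULL, nodes))
  states[1L, ] <- init
  s <- init
  for (t in seq_len(steps)) {
    on <- s[si] == 1L
    act <- tabulate(ti[is_act & on], nbins = length(nodes))
    rep <- tabulate(ti[!is_act & on], nbins = length(nodes))
    ns <- as.integer(f(act, rep, n_act_total, n_rep_total))
    ns[is_source] <- s[is_source]
    s <- ns
    states[t + 1L, ] <- s
  }
  structure(list(states = states, rule = if (is.function(rule)) "custom"
                 else rule, dual_as = dual_as, initial = init),
            class = "boolean_trajectory")
}

#' @export
print.boolean_trajectory <- function(x, ...) {
  cat(sprintf("<boolean_trajectory: %d steps x %d nodes (rule %s)>\n",
              nrow(x$states) - 1L, ncol(x$states), x$rule))
  invisible(x)
}

#' Are all trajectories fiber-wise constant?
#'
#' @param traj a `boolean_trajectory`
#' @param partition a `fiber_partition` over the same nodes
#' @return TRUE iff at every time step all members of each fiber share one
#'   state
#' @export
is_fiberwise_constant <- function(traj, partition) {
  for (fib in partition$fibers) {
    if (length(fib) < 2L) next
    sub <- traj$states[, fib, drop = FALSE]
    if (any(sub != sub[, 1L])) return(FALSE)
  }
  TRUE
}
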