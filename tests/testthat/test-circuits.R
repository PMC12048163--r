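test_that("reciprocal pairs are detected with their effects", {
  g <- make_canonical_block("toggle")
  cc <- find_two_node_circuits(g)
  expect_length(cc, 1L)
  expect_equal(cc[[1L]]$pair, c("a", "b"))
  expect_equal(cc[[1L]]$forward_effects, "repression")

  one_way <- signed_digraph(data.frame(source = "a", target = "b",
                                       effect = "activation"))
  expect_length(find_two_node_circuits(one_way), 0L)

  dual_back <- signed_digraph(data.frame(
    source = c("a", "b"), target = c("b", "a"),
    effect = c("activation", "dual")))
  cc <- find_two_node_circuits(dual_back)
  expect_equal(cc[[1L]]$backward_effects, "dual")
})

test_that("circuit classes follow the reciprocal sign rules", {
  cls <- function(g) {
    vapply(lapply(find_two_node_circuits(g), classify_circuit),
           `[[`, "", "circuit_class")
  }
  expect_equal(unname(cls(make_canonical_block("toggle"))), "toggle_switch")
  expect_equal(unname(cls(make_canonical_block("nfbl"))), "nfbl_oscillator")
  expect_equal(unname(cls(make_canonical_block("smolen"))),
               "smolen_oscillator")
  expect_equal(unname(cls(make_canonical_block("lock_on"))), "lock_on")
  # dual edges, or parallel edges of differing effect one way, -> various
  gd <- signed_digraph(data.frame(source = c("a", "b"), target = c("b", "a"),
                                  effect = c("dual", "repression")))
  expect_equal(unname(cls(gd)), "various")
  gp <- signed_digraph(data.frame(
    source = c("a", "a", "b"), target = c("b", "b", "a"),
    effect = c("activation", "repression", "repression")))
  expect_equal(unname(cls(gp)), "various")
})

test_that("classification does not depend on pair orientation", {
  g1 <- signed_digraph(data.frame(source = c("a", "b"), target = c("b", "a"),
                                  effect = c("activation", "repression")))
  g2 <- signed_digraph(data.frame(source = c("b", "a"), target = c("a", "b"),
                                  effect = c("activation", "repression")))
  c1 <- classify_circuit(find_two_node_circuits(g1)[[1L]])
  c2 <- classify_circuit(find_two_node_circuits(g2)[[1L]])
  expect_equal(c1$circuit_class, "nfbl_oscillator")
  expect_equal(c2$circuit_class, "nfbl_oscillator")
})

test_that("symmetry-breaking inputs are the unshared typed regulators", {
  # set/reset switches: s -> a only, r -> b only
  g <- signed_digraph(data.frame(
    source = c("a", "b", "s", "r"), target = c("b", "a", "a", "b"),
    effect = c("repression", "repression", "activation", "activation")))
  rec <- symmetry_breaking_inputs(g, find_two_node_circuits(g)[[1L]])
  expect_equal(rec$breaking_inputs[["a"]]$source, "s")
  expect_equal(rec$breaking_inputs[["b"]]$source, "r")

  # identical external inputs: unbroken symmetry (candidate n=2 fiber)
  g2 <- signed_digraph(data.frame(
    source = c("a", "b", "s", "s"), target = c("b", "a", "a", "b"),
    effect = c("repression", "repression", "activation", "activation")))
  rec2 <- symmetry_breaking_inputs(g2, find_two_node_circuits(g2)[[1L]])
  expect_equal(nrow(rec2$breaking_inputs[["a"]]), 0L)
  expect_equal(nrow(rec2$breaking_inputs[["b"]]), 0L)

  # shared regulator with different effects breaks symmetry on both sides
  g3 <- signed_digraph(data.frame(
    source = c("a", "b", "s", "s"), target = c("b", "a", "a", "b"),
    effect = c("repression", "repression", "activation", "repression")))
  rec3 <- symmetry_breaking_inputs(g3, find_two_node_circuits(g3)[[1L]])
  expect_equal(rec3$breaking_inputs[["a"]]$source, "s")
  expect_equal(rec3$breaking_inputs[["b"]]$source, "s")
})

test_that("feedforward fibers driving both circuit members are reported", {
  # planted fff fiber {p,q} (self-loops + shared regulator) whose members
  # regulate both nodes of a toggle pair
  e <- data.frame(
    source = c("r", "r", "p", "q", "p", "p", "q", "q", "a", "b"),
    target = c("p", "q", "p", "q", "a", "b", "a", "b", "b", "a"),
    effect = c(rep("activation", 8L), "repression", "repression"))
  g <- signed_digraph(e)
  part <- minimal_balanced_coloring(g)
  circuits <- lapply(find_two_node_circuits(g), classify_circuit)
  trip <- find_fff_circuits(g, part, circuits)
  expect_length(trip, 1L)
  expect_setequal(trip[[1L]]$fiber, c("p", "q"))
  expect_equal(trip[[1L]]$circuit$pair, c("a", "b"))

  # fiber regulating only one member is excluded
  e2 <- e[!(e$source == "q" & e$target == "b") &
            !(e$source == "p" & e$target == "b"), ]
  g2 <- signed_digraph(e2)
  expect_length(
    find_fff_circuits(g2, minimal_balanced_coloring(g2),
                      find_two_node_circuits(g2)), 0L)
  # no fff fibers at all
  expect_length(
    find_fff_circuits(make_canonical_block("toggle"),
                      minimal_balanced_coloring(make_canonical_block("toggle")),
                      find_two_node_circuits(make_canonical_block("toggle"))),
    0L)
})

test_that("simple cycle census: canonical rotations, no self-loops", {
  cyc3 <- signed_digraph(data.frame(source = c("a", "b", "c"),
                                    target = c("b", "c", "a"),
                                    effect = "activation"))
  expect_length(simple_cycles(cyc3), 1L)

  # complete digraph on 3 nodes: three 2-cycles and two 3-cycles
  k3 <- signed_digraph(data.frame(
    source = c("a", "b", "a", "c", "b", "c"),
    target = c("b", "a", "c", "a", "c", "b"), effect = "activation"))
  cys <- simple_cycles(k3)
  expect_length(cys, 5L)
  expect_setequal(vapply(cys, function(x) paste(x$nodes, collapse = ","), ""),
                  c("a,b", "a,c", "b,c", "a,b,c", "a,c,b"))

  selfies <- signed_digraph(data.frame(source = c("a", "b"),
                                       target = c("a", "b"),
                                       effect = "activation"))
  expect_length(simple_cycles(selfies), 0L)
  expect_error(simple_cycles(k3, max_cycles = 2), "max_length")
  expect_length(simple_cycles(k3, max_length = 2), 3L)
})

test_that("cycle counts match exhaustive enumeration on random graphs", {
  set.seed(43)
  for (trial in 1:60) {
    g <- random_graph(sample(3:8, 1L), density = 1.6)
    got <- sort(vapply(simple_cycles(g),
                       function(x) paste(x$nodes, collapse = ","), ""))
    expect_identical(got, oracle_simple_cycles(g),
                     info = paste("trial", trial))
  }
})

test_that("every 2-cycle corresponds to exactly one circuit record", {
  set.seed(47)
  for (trial in 1:25) {
    g <- random_graph(sample(3:9, 1L), density = 1.8)
    two <- Filter(function(x) x$length == 2L, simple_cycles(g))
    circuits <- find_two_node_circuits(g)
    expect_equal(length(two), length(circuits))
    expect_setequal(
      vapply(two, function(x) paste(sort(x$nodes), collapse = ","), ""),
      vapply(circuits, function(x) paste(x$pair, collapse = ","), ""))
  }
})

test_that("cycle sign is the product of edge signs", {
  mk <- function(effs) {
    n <- length(effs)
    nodes <- letters[seq_len(n)]
    signed_digraph(data.frame(source = nodes,
                              target = c(nodes[-1L], nodes[1L]),
                              effect = effs))
  }
  sgn <- function(effs) {
    g <- mk(effs)
    cycle_sign(simple_cycles(g)[[1L]], g)$overall_sign
  }
  expect_equal(sgn(c("activation", "activation", "repression")), "inhibition")
  expect_equal(sgn(c("repression", "repression")), "activation")
  expect_equal(sgn(c("activation", "dual", "activation")), "undetermined")
  # parallel edges of both signs on one step: both combinations reported
  g <- signed_digraph(data.frame(
    source = c("a", "a", "b"), target = c("b", "b", "a"),
    effect = c("activation", "repression", "activation")))
  rec <- cycle_sign(simple_cycles(g)[[1L]], g)
  expect_equal(rec$sign_combinations, c("activation", "inhibition"))
  expect_equal(rec$overall_sign, "undetermined")
})

test_that("cycles are annotated with the circuits they traverse", {
  # 4-cycle a->b->c->d->a containing the toggle pair {a,b}
  e <- data.frame(
    source = c("a", "b", "c", "d", "b", "x", "y"),
    target = c("b", "c", "d", "a", "a", "y", "x"),
    effect = c("repression", "activation", "activation", "activation",
               "repression", "activation", "activation"))
  g <- signed_digraph(e)
  circuits <- lapply(find_two_node_circuits(g), classify_circuit)
  cycles <- annotate_cycles(simple_cycles(g), circuits)
  four <- Filter(function(x) x$length == 4L, cycles)[[1L]]
  expect_equal(four$circuits_traversed, list(c("a", "b")))
  # the 2-cycle that is itself a circuit lists itself
  two <- Filter(function(x) setequal(x$nodes, c("a", "b")), cycles)[[1L]]
  expect_equal(two$circuits_traversed, list(c("a", "b")))
  # a cycle holding one member each of two circuits gets no annotation
  e2 <- data.frame(
    source = c("a", "b", "c", "d", "b", "c", "e"),
    target = c("b", "a", "d", "c", "c", "e", "b"),
    effect = "repression")
  g2 <- signed_digraph(e2)
  circuits2 <- find_two_node_circuits(g2)
  cycles2 <- annotate_cycles(simple_cycles(g2), circuits2)
  mixed <- Filter(function(x) setequal(x$nodes, c("b", "c", "e")),
                  cycles2)[[1L]]
  expect_length(mixed$circuits_traversed, 0L)
})

test_that("circuit and cycle reports tabulate one row per record", {
  g <- make_canonical_block("smolen")
  circuits <- lapply(find_two_node_circuits(g), classify_circuit)
  circuits <- lapply(circuits, function(x) symmetry_breaking_inputs(g, x))
  df <- circuit_report(circuits)
  expect_equal(nrow(df), 1L)
  expect_equal(df$class, "smolen_oscillator")
  cycles <- annotate_cycles(lapply(simple_cycles(g), cycle_sign, graph = g),
                            circuits)
  dfc <- cycle_report(cycles)
  expect_equal(nrow(dfc), 1L)
  expect_equal(dfc$overall_sign, "inhibition")
})
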