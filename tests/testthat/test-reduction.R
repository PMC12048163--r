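test_that("k_out=1 pruning trims dead-end paths iteratively", {
  # pure DAG: everything is shell
  dag <- signed_digraph(data.frame(source = c("a", "b"), target = c("b", "c"),
                                   effect = "activation"))
  res <- kout_core(dag)
  expect_equal(res$core, character())
  expect_equal(sort(unlist(res$shells)), c("a", "b", "c"))

  # 2-cycle with a pendant
  g <- signed_digraph(data.frame(source = c("a", "b", "b"),
                                 target = c("b", "a", "c"),
                                 effect = "activation"))
  res <- kout_core(g)
  expect_equal(res$core, c("a", "b"))
  expect_equal(res$shells, list("c"))

  # worked example: node 3 has no outputs; the rest reach the {1,2} cycle
  res <- kout_core(fib_fixture())
  expect_equal(res$core, c("1", "2", "4"))
  expect_equal(res$shells, list("3"))
})

test_that("k_out=1 core equals the reaches-a-cycle oracle", {
  set.seed(13)
  for (trial in 1:200) {
    g <- random_graph(sample(3:12, 1L))
    expect_identical(kout_core(g)$core, oracle_core1(g),
                     info = paste("trial", trial))
  }
})

test_that("core is confluent under randomized sequential deletion", {
  # deleting sub-threshold nodes one at a time in any order gives the same
  # core as the round-based rule
  seq_core <- function(g, order_seed) {
    set.seed(order_seed)
    alive <- g$nodes
    repeat {
      e <- g$edges[g$edges$source %in% alive & g$edges$target %in% alive, ]
      deg <- table(factor(e$source, levels = alive))
      doomed <- alive[deg < 1L]
      if (!length(doomed)) return(sort(alive))
      alive <- setdiff(alive, sample(doomed, 1L))
    }
  }
  set.seed(17)
  for (trial in 1:20) {
    g <- random_graph(sample(4:10, 1L))
    ref <- kout_core(g)$core
    for (os in 1:3) expect_identical(seq_core(g, os), ref)
  }
})

test_that("core and shells partition the nodes at any k", {
  set.seed(19)
  for (trial in 1:20) {
    g <- random_graph(sample(3:15, 1L), density = 2)
    for (k in 1:2) {
      res <- kout_core(g, k)
      expect_setequal(c(res$core, unlist(res$shells)), g$nodes)
      # every core node keeps out-degree >= k inside the core
      e <- g$edges[g$edges$source %in% res$core &
                     g$edges$target %in% res$core, ]
      if (length(res$core)) {
        expect_true(all(table(factor(e$source, levels = res$core)) >= k))
      }
    }
  }
})

test_that("SCC decomposition separates counted SCCs and singletons", {
  cyc3 <- signed_digraph(data.frame(source = c("a", "b", "c"),
                                    target = c("b", "c", "a"),
                                    effect = "activation"))
  d <- strongly_connected_components(cyc3)
  expect_equal(length(d$counted_sccs), 1L)
  expect_equal(d$components[[d$counted_sccs]], c("a", "b", "c"))

  # two 2-cycles with a bridge: condensation A -> B
  g <- signed_digraph(data.frame(
    source = c("a1", "a2", "b1", "b2", "a1"),
    target = c("a2", "a1", "b2", "b1", "b1"),
    effect = "activation"))
  d <- strongly_connected_components(g)
  expect_equal(length(d$counted_sccs), 2L)
  expect_equal(nrow(d$condensation), 1L)
  cmpA <- d$membership[["a1"]]; cmpB <- d$membership[["b1"]]
  expect_equal(d$condensation$from, cmpA)
  expect_equal(d$condensation$to, cmpB)

  # worked example's core: {1,2} counted, 4 a singleton, 2 self-looped
  d <- strongly_connected_components(kout_core(fib_fixture())$core_graph)
  expect_equal(d$components[d$counted_sccs], list(c("1", "2")))
  expect_equal(d$selfloop_singletons, character())
  dl <- strongly_connected_components(signed_digraph(data.frame(
    source = "a", target = "a", effect = "activation")))
  expect_equal(dl$selfloop_singletons, "a")
})

test_that("condensation is acyclic with counted or self-loop sinks in cores", {
  set.seed(29)
  for (trial in 1:30) {
    g <- random_graph(sample(4:14, 1L), density = 1.8)
    core <- kout_core(g)$core_graph
    if (!node_count(core)) next
    d <- strongly_connected_components(core)
    if (nrow(d$condensation)) {
      cg <- igraph::graph_from_data_frame(d$condensation[, 1:2])
      expect_true(igraph::is_dag(cg))
    }
    sinks <- setdiff(seq_along(d$components),
                     unique(d$condensation$from))
    for (s in sinks) {
      expect_true(s %in% d$counted_sccs ||
                    all(d$components[[s]] %in% d$selfloop_singletons))
    }
  }
})

test_that("roles: controllers feed SCCs, connectors relay between them", {
  # controller c -> SCC{a,b}; SCC -> x -> SCC2{d,e}: x is a connector
  g <- signed_digraph(data.frame(
    source = c("c", "a", "b", "a", "x", "d", "e"),
    target = c("a", "b", "a", "x", "d", "e", "d"),
    effect = "activation"))
  d <- classify_roles(g, strongly_connected_components(g))
  expect_equal(unname(d$roles[c("c", "x", "a", "d")]),
               c("controller", "connector", "scc_member", "scc_member"))

  # one big SCC: everyone is a member
  cyc <- signed_digraph(data.frame(source = c("a", "b", "c"),
                                   target = c("b", "c", "a"),
                                   effect = "activation"))
  d <- classify_roles(cyc, strongly_connected_components(cyc))
  expect_true(all(d$roles == "scc_member"))
})

test_that("every minimal-network non-member reaches a counted SCC", {
  set.seed(37)
  for (trial in 1:30) {
    g <- random_graph(sample(5:14, 1L), density = 1.8)
    core <- kout_core(g)$core_graph
    if (!node_count(core)) next
    d <- classify_roles(core, strongly_connected_components(core))
    members <- names(d$roles)[d$roles == "scc_member"]
    others <- names(d$roles)[d$roles != "scc_member"]
    if (!length(others)) next
    ig <- as_igraph(core)
    for (v in others) {
      down <- igraph::subcomponent(ig, v, mode = "out")$name
      expect_true(any(down %in% members), info = v)
    }
    # bookkeeping identity: roles cover the minimal network
    expect_equal(sum(d$roles == "scc_member") +
                   sum(d$roles == "controller") +
                   sum(d$roles == "connector"),
                 node_count(core))
  }
})

test_that("master SCC maximizes outreach with size then lexicographic ties", {
  # hub feeding three SCCs
  mk2 <- function(p) data.frame(source = c(p[1], p[2]),
                                target = c(p[2], p[1]),
                                effect = "activation")
  e <- rbind(mk2(c("h1", "h2")), mk2(c("x1", "x2")), mk2(c("y1", "y2")),
             mk2(c("z1", "z2")),
             data.frame(source = "h1", target = c("x1", "y1", "z1"),
                        effect = "activation"))
  d <- strongly_connected_components(signed_digraph(e))
  expect_equal(sort(d$components[[master_scc(d)]]), c("h1", "h2"))

  # tie on outreach: larger component wins
  e2 <- rbind(mk2(c("a1", "a2")),
              data.frame(source = c("b1", "b2", "b3", "b1"),
                         target = c("b2", "b3", "b1", "a0"),
                         effect = "activation"),
              data.frame(source = "a1", target = "q1", effect = "activation"),
              mk2(c("q1", "q2")), mk2(c("a0", "a9")))
  d2 <- strongly_connected_components(signed_digraph(e2))
  expect_equal(sort(d2$components[[master_scc(d2)]]), c("b1", "b2", "b3"))
  expect_error(master_scc(strongly_connected_components(signed_digraph())),
               "no counted SCC")
})

test_that("single-SCC graphs return themselves as master", {
  cyc <- signed_digraph(data.frame(source = c("a", "b"), target = c("b", "a"),
                                   effect = "repression"))
  d <- strongly_connected_components(cyc)
  expect_equal(master_scc(d), d$counted_sccs)
})
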