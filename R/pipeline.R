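# Orchestration of the full reduction: Step 0 (optional transcription-unit
# collapse) -> Step I (fiber collapse) -> Step II (k_out pruning) -> Step III
# (SCCs and roles) -> Step IV (circuits) -> Step V (cycles) -> optional null
# model.

#' Run the full network-reduction pipeline
#'
#' @param graph a [signed_digraph], or a path to a TSV edge list
#' @param tumap optional gene -> transcription-unit map (named character
#'   vector or path to a two-column TSV) applied as Step 0
#' @param source_policy handling of in-degree-0 nodes in the fiber search,
#'   see [minimal_balanced_coloring]
#' @param k out-degree threshold for the pruning step (default 1)
#' @param null_config optional [randomization_config]; when supplied the
#'   null-model ensemble is run on the input network
#' @param max_cycle_length bound for the simple-cycle census
#' @param out_dir optional directory: reports (TSV, JSON, DOT) are written
#'   there
#' @param verbose log one line per stage
#' @return object of class `coresym_result`; see Details
#'
#' @details The result bundles every stage: `input`, `tu` (collapse result or
#' NULL), `partition`, `quotient` (base graph + node map), `core`
#' (`kcore_result` on the base), `minimal` (the pruned graph), `decomp`
#' (SCCs with roles), `master` (master SCC index or NA), `blocks` (building
#' block census), `circuits`, `fff_circuits`, `cycles` (classified, signed,
#' annotated; computed on the minimal network), `nullmodel` (or NULL) and
#' `summary` (stage node counts with percentages relative to the input
#' network, fiber-collapsed node counts in parentheses in the printed form).
#' @export
run_pipeline <- function(graph, tumap = NULL,
                         source_policy = c("distinct", "merge"), k = 1L,
                         null_config = NULL, max_cycle_length = Inf,
                         out_dir = NULL, verbose = FALSE) {
  source_policy <- match.arg(source_policy)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(graph)) graph <- read_grn_edge_list(graph)
  stopifnot_digraph(graph)
  input <- graph
  say("step 0.1: input network: %d nodes, %d edges", node_count(input),
      edge_count(input))
  tu <- NULL
  if (!is.null(tumap)) {
    if (is.character(tumap) && length(tumap) == 1L && file.exists(tumap)) {
      tumap <- read_tu_map(tumap)
    }
    tu <- collapse_transcription_units(graph, tumap)
    graph <- tu$graph
    say("step 0.2: TU-collapsed: %d nodes", node_count(graph))
  }
  partition <- minimal_balanced_coloring(graph, source_policy = source_policy)
  quotient <- collapse_fibers(graph, partition)
  say("step I: base network: %d nodes (%d nontrivial fibers)",
      node_count(quotient$base), length(partition$nontrivial_fibers))
  core <- kout_core(quotient$base, k = k)
  minimal <- core$core_graph
  say("step II: minimal network: %d nodes", node_count(minimal))
  decomp <- strongly_connected_components(minimal)
  decomp <- classify_roles(minimal, decomp)
  master <- if (length(decomp$counted_sccs)) master_scc(decomp) else NA_integer_
  say("step III: %d counted SCC(s), master = %s",
      length(decomp$counted_sccs),
      if (is.na(master)) "none"
      else paste(decomp$components[[master]], collapse = ","))
  blocks <- block_census(graph, partition)
  circuits <- find_two_node_circuits(minimal)
  circuits <- lapply(circuits, classify_circuit)
  circuits <- lapply(circuits, function(x) symmetry_breaking_inputs(minimal, x))
  fffc <- find_fff_circuits(graph, partition, circuits)
  say("step IV: %d two-node circuit(s)", length(circuits))
  cycles <- simple_cycles(minimal, max_length = max_cycle_length)
  cycles <- lapply(cycles, cycle_sign, graph = minimal)
  cycles <- annotate_cycles(cycles, circuits)
  say("step V: %d simple cycle(s)", length(cycles))
  nullm <- NULL
  if (!is.null(null_config)) {
    nullm <- ensemble_stats(
      graph, default_null_statistics(source_policy), null_config)
    say("null model: %d replicates done", null_config$replicates)
  }
  n0 <- node_count(input)
  fib_reps <- vapply(partition$nontrivial_fibers, min, "")
  stages <- data.frame(
    stage = c("step0.1_input",
              if (!is.null(tu)) "step0.2_tu_collapsed",
              "step1_base", "step2_minimal"),
    nodes = c(n0, if (!is.null(tu)) node_count(tu$graph),
              node_count(quotient$base), node_count(minimal)),
    stringsAsFactors = FALSE)
  stages$percent <- round(100 * stages$nodes / n0, 1)
  stages$fiber_collapsed_nodes <- vapply(seq_len(nrow(stages)), function(i) {
    if (stages$stage[i] == "step1_base") length(fib_reps)
    else if (stages$stage[i] == "step2_minimal") {
      sum(minimal$nodes %in% fib_reps)
    } else NA_integer_
  }, 0L)
  res <- structure(
    list(input = input, tu = tu, graph = graph, partition = partition,
         quotient = quotient, core = core, minimal = minimal,
         decomp = decomp, master = master, blocks = blocks,
         circuits = circuits, fff_circuits = fffc, cycles = cycles,
         nullmodel = nullm, summary = stages,
         config = list(source_policy = source_policy, k = k)),
    class = "coresym_result")
  if (!is.null(out_dir)) write_reports(res, out_dir)
  res
}

#' @export
print.coresym_result <- function(x, ...) {
  cat("CoReSym reduction\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    extra <- if (!is.na(s$fiber_collapsed_nodes[i])) {
      sprintf(" (%d fiber-collapsed)", s$fiber_collapsed_nodes[i])
    } else ""
    cat(sprintf("  %-22s %5d nodes  %5.1f%%%s\n", s$stage[i], s$nodes[i],
                s$percent[i], extra))
  }
  cat(sprintf("  counted SCCs: %d; circuits: %d; simple cycles: %d\n",
              length(x$decomp$counted_sccs), length(x$circuits),
              length(x$cycles)))
  if (!is.na(x$master)) {
    cat(sprintf("  master SCC: {%s}\n",
                paste(x$decomp$components[[x$master]], collapse = ",")))
  }
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' Writes `summary.tsv`, `summary.json`, `fibers.tsv`, `blocks.tsv`,
#' `minimal.tsv`, `circuits.tsv`, `cycles.tsv`, `condensation.dot`,
#' `base.tsv` (+ `quotient_map.tsv`) and, when the null model ran,
#' `nullmodel.tsv`.
#'
#' @param result a `coresym_result`
#' @param dir output directory (created if missing)
#' @export
write_reports <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(result$summary, "summary.tsv")
  w(fiber_report(result$partition), "fibers.tsv")
  w(result$blocks, "blocks.tsv")
  fib_reps <- vapply(result$partition$nontrivial_fibers, min, "")
  w(minimal_network_report(result$minimal, result$decomp, fib_reps),
    "minimal.tsv")
  w(circuit_report(result$circuits), "circuits.tsv")
  w(cycle_report(result$cycles), "cycles.tsv")
  write_network(result$quotient$base, file.path(dir, "base.tsv"),
                format = "edge-list")
  utils::write.table(
    data.frame(node = names(result$quotient$node_map),
               base_node = unname(result$quotient$node_map)),
    file.path(dir, "quotient_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_condensation_dot(result$decomp, file.path(dir, "condensation.dot"))
  if (!is.null(result$nullmodel)) w(result$nullmodel$table, "nullmodel.tsv")
  summary_json <- list(
    stages = result$summary,
    n_counted_sccs = length(result$decomp$counted_sccs),
    scc_sizes = lengths(result$decomp$components[result$decomp$counted_sccs]),
    master_scc = if (is.na(result$master)) NULL
                 else result$decomp$components[[result$master]],
    n_circuits = length(result$circuits),
    circuit_classes = vapply(result$circuits, `[[`, "", "circuit_class"),
    n_cycles = length(result$cycles),
    roles = as.list(table(result$decomp$roles)))
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
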