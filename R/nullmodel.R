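# Degree- and edge-type-preserving randomization and empirical Z-scores.
# The null hypothesis: the observed large-scale structure (several separate
# SCCs, specific circuit and fiber counts) arises by chance in networks with
# the same per-node, per-effect in/out degrees.

#' Randomization configuration
#'
#' @param replicates ensemble size (>= 1); 1000 by default, standard practice
#'   for motif-style significance estimates
#' @param swap_factor attempted double-edge swaps per edge (>= 1); 10 by
#'   default, ample for mixing at regulatory-network densities
#' @param seed integer master seed; per-replicate streams are derived from
#'   (seed, replicate index) so ensembles are reproducible and parallelizable
#' @param swap_self_loops if `FALSE` (default) self-loops are frozen: they
#'   are dynamically meaningful (they define feedforward/n-ary fibers and
#'   Smolen oscillators) and the null preserves them exactly
#' @export
randomization_config <- function(replicates = 1000L, swap_factor = 10,
                                 seed = 1L, swap_self_loops = FALSE) {
  stopifnot(replicates >= 1L, swap_factor >= 1)
  structure(list(replicates = as.integer(replicates),
                 swap_factor = swap_factor, seed = as.integer(seed),
                 swap_self_loops = isTRUE(swap_self_loops)),
            class = "randomization_config")
}

derive_seed <- function(seed, replicate_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(replicate_index) * 69621) %%
               2147483647)
}

#' Degree-preserving randomization of a signed network
#'
#' Performs repeated double-edge swaps within each effect class: two edges
#' a->b and c->d of the same effect are rewired to a->d and c->b. Swaps that
#' would create a duplicate (source, target, effect) edge or a new self-loop
#' are rejected, and existing self-loops are frozen unless
#' `config$swap_self_loops`. Per-node, per-effect in- and out-degrees are
#' therefore identical to the input's. Deterministic given
#' (config$seed, replicate_index).
#'
#' @param graph a [signed_digraph]
#' @param config a [randomization_config]
#' @param replicate_index which ensemble member to generate (>= 1)
#' @return a randomized [signed_digraph]
#' @export
randomize <- function(graph, config = randomization_config(),
                      replicate_index = 1L) {
  stopifnot_digraph(graph)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(derive_seed(config$seed, replicate_index))
  pieces <- lapply(split(graph$edges, graph$edges$effect), function(e) {
    swap_class(e, config$swap_factor, config$swap_self_loops)
  })
  signed_digraph(do.call(rbind, unname(pieces)), nodes = graph$nodes)
}

swap_class <- function(e, swap_factor, swap_self_loops) {
  src <- e$source; tgt <- e$target
  movable <- if (swap_self_loops) seq_along(src) else which(src != tgt)
  if (length(movable) < 2L) return(e)
  attempts <- max(1L, round(swap_factor * nrow(e)))
  have <- new.env(parent = emptyenv(), size = nrow(e) * 2L)
  for (i in seq_along(src)) {
    assign(paste0(src[i], "\r", tgt[i]), TRUE, envir = have)
  }
  pick <- matrix(movable[sample.int(length(movable),
                                    2L * attempts, replace = TRUE)],
                 ncol = 2L)
  for (a in seq_len(attempts)) {
    i <- pick[a, 1L]; j <- pick[a, 2L]
    if (i == j) next
    s1 <- src[i]; t1 <- tgt[i]; s2 <- src[j]; t2 <- tgt[j]
    if (!swap_self_loops && (s1 == t2 || s2 == t1)) next  # no new self-loops
    k1 <- paste0(s1, "\r", t2); k2 <- paste0(s2, "\r", t1)
    if (exists(k1, envir = have, inherits = FALSE) ||
        exists(k2, envir = have, inherits = FALSE)) next  # no duplicates
    rm(list = c(paste0(s1, "\r", t1), paste0(s2, "\r", t2)), envir = have)
    assign(k1, TRUE, envir = have)
    assign(k2, TRUE, envir = have)
    tgt[i] <- t2; tgt[j] <- t1
  }
  data.frame(source = src, target = tgt, effect = e$effect,
             stringsAsFactors = FALSE)
}

#' Empirical Z-score against replicate values
#'
#' @param observed observed statistic
#' @param replicate_values numeric vector of the statistic over the null
#'   ensemble (length >= 2)
#' @return `(observed - mean) / sd` with the sample (n-1) standard
#'   deviation; `NA` with attribute `undefined = TRUE` when the ensemble is
#'   constant
#' @export
zscore <- function(observed, replicate_values) {
  if (length(replicate_values) < 2L) stop("need >= 2 replicate values")
  s <- stats::sd(replicate_values)
  if (s == 0) return(structure(NA_real_, undefined = TRUE))
  (observed - mean(replicate_values)) / s
}

#' Default graph statistics for the null ensemble
#'
#' Each statistic runs the full reduction (fiber collapse with the given
#' source policy, k_out = 1 pruning, SCC decomposition, circuit detection) on
#' the graph it receives and measures one structural quantity of the minimal
#' network.
#'
#' @param source_policy passed to [minimal_balanced_coloring]
#' @return named list of functions `signed_digraph -> numeric`
#' @export
default_null_statistics <- function(source_policy = "distinct") {
  reduce <- function(g) {
    part <- minimal_balanced_coloring(g, source_policy = source_policy)
    q <- collapse_fibers(g, part)
    core <- kout_core(q$base, k = 1L)
    decomp <- strongly_connected_components(core$core_graph)
    list(core = core$core_graph, decomp = decomp)
  }
  list(
    n_counted_sccs = function(g) length(reduce(g)$decomp$counted_sccs),
    largest_scc_size = function(g) {
      d <- reduce(g)$decomp
      if (!length(d$counted_sccs)) 0
      else max(lengths(d$components[d$counted_sccs]))
    },
    minimal_nodes = function(g) node_count(reduce(g)$core),
    n_circuits = function(g) length(find_two_node_circuits(reduce(g)$core)),
    n_nontrivial_fibers = function(g) {
      length(minimal_balanced_coloring(
        g, source_policy = source_policy)$nontrivial_fibers)
    })
}

#' Null-ensemble statistics and Z-scores
#'
#' Evaluates each statistic on the observed graph and on `config$replicates`
#' degree-preserving randomizations, and reports ensemble mean, sample
#' standard deviation and Z-score per statistic.
#'
#' @param graph a [signed_digraph]
#' @param statistics named list of functions `signed_digraph -> numeric`;
#'   defaults to [default_null_statistics()]
#' @param config a [randomization_config]
#' @return object of class `null_ensemble_stats`: list with `table` (data
#'   frame `statistic`, `observed`, `mean`, `sd`, `z`) and `replicates`
#'   (matrix statistic x replicate)
#' @export
ensemble_stats <- function(graph, statistics = default_null_statistics(),
                           config = randomization_config()) {
  stopifnot_digraph(graph)
  observed <- vapply(statistics, function(f) as.numeric(f(graph)), 0)
  reps <- matrix(NA_real_, nrow = length(statistics),
                 ncol = config$replicates,
                 dimnames = list(names(statistics), NULL))
  for (r in seq_len(config$replicates)) {
    rg <- randomize(graph, config, replicate_index = r)
    reps[, r] <- vapply(statistics, function(f) as.numeric(f(rg)), 0)
  }
  z <- vapply(seq_along(statistics), function(i) {
    as.numeric(zscore(observed[i], reps[i, ]))
  }, 0)
  tab <- data.frame(statistic = names(statistics), observed = observed,
                    mean = rowMeans(reps), sd = apply(reps, 1L, stats::sd),
                    z = z, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, replicates = reps, config = config),
            class = "null_ensemble_stats")
}

#' @export
print.null_ensemble_stats <- function(x, ...) {
  cat(sprintf("<null ensemble: %d replicates>\n", ncol(x$replicates)))
  print(x$table)
  invisible(x)
}
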