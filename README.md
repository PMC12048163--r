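# coresym

Reduce a signed, directed gene regulatory network (GRN) to its minimal
computational core, and describe that core's anatomy.

Bacterial GRNs are dominated by periphery: groups of genes that receive
identical regulatory signal histories (and therefore synchronize), and
dead-end pathways that receive signals but never send any back into the
regulatory machinery. `coresym` removes both in a principled way and
reports what remains — the small subnetwork of signal vortices, logic
circuits and feedback cycles that performs the network's computation. It is
aimed at systems biologists working with curated regulatory edge lists
(RegulonDB- or SubtiWiki-style TSVs) and at network scientists studying
fibration symmetry in directed graphs.

## The method

For a graph $G$ with typed edges (activation / repression / dual), the
*input tree* $T_i$ of node $i$ stacks the typed in-neighborhoods along all
reverse paths ending at $i$. Nodes with isomorphic input trees form a
*fiber*; fibers are the classes of the coarsest *balanced coloring* (any
two nodes of one color see the same multiset of (in-neighbor color, effect)
pairs), found here by fixpoint partition refinement. Collapsing each fiber
to a representative is a surjective graph *fibration* $\varphi: G \to B$ —
every base edge into $\varphi(i)$ lifts to exactly one edge into $i$ (the
lifting property) — so the quotient preserves every surviving node's input
tree and hence its admissible dynamics.

The pipeline:

| Step | Operation | Function |
|------|-----------|----------|
| 0 | collapse operon transcription units (trivial fibers) | `collapse_transcription_units()` |
| I | fibers + quotient ("collapsing") | `minimal_balanced_coloring()`, `collapse_fibers()` |
| II | $k_\mathrm{out}=1$ core ("pruning" dead ends) | `kout_core()` |
| III | SCCs, controller/connector roles, master SCC | `strongly_connected_components()`, `classify_roles()`, `master_scc()` |
| IV | two-node logic circuits (toggle / NFBL / Smolen / lock-on) | `find_two_node_circuits()`, `classify_circuit()` |
| V | simple-cycle census with signs and circuit annotation | `simple_cycles()`, `cycle_sign()`, `annotate_cycles()` |

Each fiber's building block is classified $|n,\ell\rangle$ by its branching
ratio $n$ (input-tree layer growth: 0 trivial, 1 feedforward, integer $n$
n-ary, golden ratio $\varphi$ for the Fibonacci fiber) and regulator count
$\ell$ (`classify_block()`). Significance is assessed against a null
ensemble of degree- and edge-type-preserving edge swaps with empirical
Z-scores (`randomize()`, `ensemble_stats()`). A planted-structure synthetic
generator and a synchronous Boolean simulator (`generate_synthetic_grn()`,
`boolean_simulate()`) back the test suite.

## Worked example

The canonical four-node Fibonacci building block — fiber {2,3} with a
self-loop on 2, feedback to regulator 1, external regulator 4:

```r
library(coresym)
g <- make_canonical_block("fibonacci")
run_pipeline(g)
#> CoReSym reduction
#>   step0.1_input              4 nodes  100.0%
#>   step1_base                 3 nodes   75.0% (1 fiber-collapsed)
#>   step2_minimal              3 nodes   75.0% (1 fiber-collapsed)
#>   counted SCCs: 1; circuits: 1; simple cycles: 1
#>   master SCC: {1,2}

classify_block(extract_building_block(g, c("2", "3")))
#> <block_class |1.6180,2>: kind=fibonacci ratio=1.6180 ell=2>
```

Genes 2 and 3 have isomorphic input trees, so Step I collapses them
(4 → 3 nodes); nothing is pruned in Step II because every survivor reaches
the {1,2} cycle; the minimal network is one SCC plus the controller 4. The
fiber's input-tree layers grow as Fibonacci numbers, so its branching ratio
converges to $\varphi \approx 1.6180$ with $\ell = 2$ regulators.

Null-model use on a synthetic network with three planted SCCs:

```r
sg  <- generate_synthetic_grn(n_sccs = 3, n_fibers = 2, n_controllers = 2, seed = 1)
ns  <- ensemble_stats(sg$graph, default_null_statistics()["n_counted_sccs"],
                      randomization_config(replicates = 200, seed = 2))
ns$table
#>        statistic observed  mean        sd        z
#> 1 n_counted_sccs        3 1.465 0.6409596 2.394847
```

Randomized degree-matched networks mostly collapse into a single vortex;
three separate SCCs is already a z ≈ 2.4 deviation at this toy size.

## Command line

```sh
exec/coresym run --edges grn.tsv --tu-map tus.tsv --out results/
exec/coresym synth --preset fibonacci --out fib.tsv
exec/coresym simulate --edges fib.tsv --init init.tsv --steps 20
```

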