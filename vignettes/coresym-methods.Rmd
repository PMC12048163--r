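---
title: "Reducing regulatory networks to their computational core"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing regulatory networks to their computational core}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresym)
```

## The problem

A bacterial gene regulatory network (GRN) is a signed directed graph:
transcription factors regulate target genes by activation, repression, or
both ("dual"). Most of such a network is periphery — large sets of genes
that receive identical regulatory signals and therefore cannot behave
independently, and dead-end pathways that receive signals but send none
back. `coresym` strips both away to expose the small core that actually
performs the network's signal processing, and then describes that core's
anatomy: its signal vortices (strongly connected components, SCCs), the
memory and clock circuits embedded in them, and the cycles that connect
those circuits.

The reduction is justified by symmetry, not by heuristics. Two genes whose
*input trees* — the rooted trees of all reverse regulatory paths ending at
them, with edge types — are isomorphic receive identical signal histories,
so under any dynamics driven through the typed inputs they synchronize.
Such classes of genes are *fibers* (balanced-coloring classes). Collapsing
each fiber to one representative is a surjective graph *fibration*: a graph
morphism with the lifting property (every base edge targeting a node's
image lifts to exactly one edge targeting the node), which is precisely the
condition under which the quotient preserves each surviving node's input
tree and hence its dynamics.

## The pipeline

1. **Step 0 (optional).** Collapse transcription units: operon genes under
   the same promoters are trivially synchronized and merged by a supplied
   gene-to-TU map (`collapse_transcription_units()`). Deriving TU
   annotations from promoter records is database-specific and out of scope;
   a two-column TSV is the interface.
2. **Step I.** `minimal_balanced_coloring()` finds the coarsest balanced
   partition by fixpoint refinement: each round recolors every node by its
   current color plus the multiset of (in-neighbor color, effect) pairs.
   This is equivalent to comparing typed input trees to depth $N-1$ ($N$
   nodes) but runs in rounds over the edge list instead of materializing
   exponentially growing trees; explicit trees (`input_tree()`) are kept
   for small-instance inspection and for the test oracles.
   `collapse_fibers()` then builds the base graph over fiber
   representatives. Edge multiplicities are kept: edges targeting one node
   are never merged, which is what `verify_lifting_property()` checks.
3. **Step II.** `kout_core(k = 1)` iteratively deletes nodes with no
   outputs among the survivors — the dead-end paths. For $k=1$ the result
   is exactly the set of nodes with a directed path to some cycle
   (self-loops count); the rounds are recorded as shells. The remainder is
   the *minimal network*.
4. **Step III.** `strongly_connected_components()` + `classify_roles()`:
   components with at least two nodes are the counted SCCs; single nodes
   whose only cycle is a self-loop are tracked separately (they survive
   pruning and are booked as SCC members). Remaining nodes are *connectors*
   when reachable from an SCC member (they relay between SCCs, possibly in
   chains) and *controllers* otherwise (they send signals in but never
   receive any back). `master_scc()` names the component regulating the
   most other counted SCCs.
5. **Step IV.** `find_two_node_circuits()` + `classify_circuit()`: mutual
   repression is a toggle switch (one stored bit); mixed signs are a
   negative-feedback-loop oscillator, upgraded to the more robust Smolen
   oscillator when both members carry self-loops; mutual activation is a
   lock-on latch; anything involving dual edges or parallel edges of
   different sign is "various". `symmetry_breaking_inputs()` reports each
   member's unshared typed regulators — the set/reset lines that make a
   broken n=2 fiber into a functional circuit.
6. **Step V.** `simple_cycles()` enumerates elementary directed cycles
   (length ≥ 2) with a rooted Johnson-style DFS; `cycle_sign()` multiplies
   edge signs (odd repressions ⇒ net inhibition), and `annotate_cycles()`
   marks which circuits each cycle traverses.

`run_pipeline()` chains all stages and writes TSV/JSON/DOT reports.

## Building-block classification

Each fiber, together with its regulators and any feedback nodes on paths
from the fiber back to them (`extract_building_block()`), is classified by
two numbers written $|n,\ell\rangle$:

* $n$, the **branching ratio**: the growth rate of the fiber's input tree,
  estimated as the ratio of the last two layer sizes at depth 40
  (`branching_ratio()`). A terminating tree gives 0 (trivial fiber); a lone
  self-loop gives 1 (feedforward fiber, FFF); $n$ intertwined loops give
  $n$; a self-loop plus a feedback loop through a regulator makes the layer
  sizes Fibonacci, so the ratio converges to the golden ratio
  $\varphi = (1+\sqrt 5)/2 \approx 1.6180$ — the Fibonacci fiber. Depth 40
  brings the Fibonacci ratio within $10^{-9}$ of $\varphi$; the default
  stability tolerance of $10^{-3}$ flags estimates still drifting between
  the last two layers, and the integer test $|n-\mathrm{round}(n)|<10^{-6}$
  separates integer from fractal classes at that depth.
* $\ell$, the number of **regulators**, counting loop-participating
  regulators too: the canonical worked example $|\varphi{=}1.6180,
  \ell{=}2\rangle$ counts both its feedback regulator and its external
  driver, and we follow that printed convention uniformly. Reports carry
  the caveat that $\ell$-counting inside feedback loops is a convention
  reconstructed from that single example.

Classes: ratio 0 ⇒ `trivial`; ratio 1 via fiber self-loop, no feedback ⇒
`fff`; integer ratio without fiber→regulator feedback ⇒ `n_ary` (we place
no upper bound on the integer: the boundary to "composite" is not
formalized, and the fall-through keeps the rule deterministic); non-integer
ratio in (1,2) with feedback ⇒ `fibonacci`; everything else ⇒ `composite`.

One representational choice deserves a note: the n=2 fiber is defined by
"two loops" through each synchronized gene. An edge multiset cannot hold
two identical (source, target, effect) self-loop rows, so the canonical
`n_ary` fixture realizes branching ratio $n$ as a fiber of $n$ genes
completely wired among themselves — each member receives $n$ fiber edges,
one of them its own self-loop. The input trees, and hence the class, are
exactly those of the two-loop picture.

## Handling of in-degree-0 nodes

Nodes without regulators have trivially isomorphic (empty) input trees, so
the strict mathematical definition merges them all. The default
`source_policy = "distinct"` instead keeps each in its own fiber: such
nodes stand for different unmodeled external inputs (sensors, constitutive
regulators), and merging them would equate unrelated regulators — and, by
refinement, could merge their downstream targets too. `"merge"` is provided
for the strict definition; both are exercised against the brute-force
input-tree oracle in the tests.

## The null model

Significance of the observed structure is empirical: `randomize()` performs
double-edge swaps *within each effect class*, rejecting swaps that would
duplicate a typed edge or create a self-loop, so per-node per-type in- and
out-degrees are preserved exactly. Pre-existing self-loops are frozen by
default — they define fiber classes and oscillator variants, and destroying
them would change the null in an unsanctioned way (`swap_self_loops` is the
sensitivity knob). Defaults are 1000 replicates and 10 attempted swaps per
edge, standard motif-analysis practice. `ensemble_stats()` re-runs the full
reduction per replicate and Z-scores each statistic with the sample
standard deviation; constant statistics (e.g. edge count) are flagged
undefined rather than scored. Per-replicate streams derive from
(seed, replicate index), so ensembles are reproducible bitwise.

## The synthetic generator

`generate_synthetic_grn()` emulates the architecture the reduction exposes
in real bacterial GRNs — a feedforward chain of SCCs, controllers feeding
them, fiber genes hanging off the core into the periphery — with the
planted truth recoverable *by construction* rather than by generate-and-
check:

* SCCs of size ≥ 4 are cycles with one chord; the chord is fixed to
  repression so that no core node's typed input set can coincide with a
  planted fiber's purely activating drive. 3-cycles get non-uniform edge
  effects; both devices make every SCC member's input history unique, so no
  accidental fibers arise inside the core.
* 2-node SCCs are the planted circuits; a pair that would be
  input-symmetric (equal reciprocal effects, no external input) is given
  unequal effects, since an unbroken symmetric pair would be an n=2 fiber,
  not a circuit.
* Each planted fiber is a set of sink genes driven (activation) by a
  distinct pair of consecutive core nodes, so distinct fibers never merge
  and no core node shares their input set.

What the generator does *not* emulate: realistic degree heterogeneity
(hubs), dual-edge-rich regulons, autoregulation in the core, overlapping
fiber regulator sets, or fibers with internal wiring. Passing the planted-
recovery tests therefore shows the pipeline is exact on networks whose
ground truth is known, not that real-data peculiarities are all covered;
the real-network comparison is a separate, data-dependent check.

## Boolean dynamics

`boolean_simulate()` updates all nodes synchronously; the default rule
switches a node on iff no active repressor targets it and it has an active
activator *or no activator inputs at all* (a gene regulated only by a
repressor is ON by default — this is what makes a two-gene negative
feedback loop run its canonical period-4 orbit). Dual edges act as
activators by default (`dual_as` switches them). Sources hold their initial
value. Any rule that depends only on the typed input multiset keeps fibers
synchronized from fiber-constant starts, and the quotient reproduces the
representative trajectories of the total graph — both properties are tested
over random graphs and random threshold rules (100 graphs × 50 steps).

## Problem sizes and numerical choices

The test suite works at desk scale by design: oracle-equivalence sweeps use
200 random graphs of ≤ 10–12 nodes (input-tree canonicalization is
exponential in depth, which is exactly why refinement is the production
algorithm), cycle-census cross-checks use ≤ 8 nodes where subset
enumeration is exhaustive, and null-ensemble tests use 60 replicates on
planted graphs of ~15–20 nodes. Layer-size recurrences use doubles, safe to
depth 40 even at ratio 2 ($2^{40} \approx 10^{12}$). Ties everywhere are
broken lexicographically (fiber representatives, color numbering, cycle
rotations, master-SCC selection), so every output is deterministic given
the input and seed.

## Known limitations

* $\ell$-counting for loop-participating regulators follows one printed
  example; alternative conventions would shift $\ell$, never the class
  kind.
* Composite blocks are a fall-through, not a constructive decomposition
  into chained primitives.
* The cycle census excludes self-loops (two-node SCCs are the shortest
  counted cycles); a census including them would differ by exactly the
  self-loop count.
* No continuous-time simulation: bistability/oscillation labels are
  structural classifications, with only the Boolean synchronization claim
  checked dynamically.
* Randomization mixes within effect classes only; cross-type swaps would
  preserve total degrees but not typed degrees and are deliberately not
  offered.
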