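---
title: "Quartet scores under hybridization: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet scores under hybridization: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetNMSC)
```

## The model

Under the multispecies coalescent (MSC), gene lineages trace their
ancestry backward through the branches of a species tree; with `k`
lineages in a population, coalescence occurs at rate `k(k-1)/2` per
coalescent unit, so two lineages fail to coalesce over time `t` with
probability `exp(-t)`.  The network multispecies coalescent (NMSC)
extends this to species networks: below a hybrid node a lineage chooses
a parental population with probability `gamma` (the inheritance
probability of that hybrid edge) and `1 - gamma` for the other.

The package works with the canonical 5-taxon, single-5-cycle network on
taxa A–E.  Its free parameters are

| parameter | units | meaning |
|---|---|---|
| `e2` | coalescent units | internal edge subtending the (C,D) side |
| `e3` | coalescent units | internal edge on the path between the cycle's two arms |
| `e4` | coalescent units | internal edge subtending the (B,C) side |
| `gamma` | probability | inheritance weight of the hybrid edge whose retention yields `T1` |

Pendant edges never affect unrooted gene-tree topology probabilities
(one sampled lineage per taxon cannot coalesce before reaching an
internal branch), so only `e2`, `e3`, `e4`, `gamma` matter analytically;
`cycleParams()` holds them and `yValues()` returns `y_i = exp(-e_i)`.

For a single-cycle network the gene-tree distribution is a
`gamma/(1-gamma)` mixture of MSC distributions on the two displayed
trees — the trees obtained by deleting one hybrid edge and suppressing
degree-2 nodes.  `fiveCycleQuartetTable()` exploits exactly this
structure: it builds the rooted network, extracts both displayed trees,
and for each of the five 4-taxon subsets mixes the MSC quartet
probabilities implied by each displayed tree's quartet split and
internal path length.  One generic code path serves all quartets; the
per-quartet closed forms (e.g. `{A,B,C,D}` reducing to a 4-cycle with
`x = e2 + e3`, `y = e4`) are kept as independent cross-checks in the
test suite rather than as the implementation, so a bug would have to
appear identically in two different derivations to go unnoticed.

## Expected quartet scores and the exact maximizer

The expected quartet score of a topology `T` is the sum over its five
induced quartet splits of those splits' gene-tree probabilities — the
large-sample limit (per gene) of the ASTRAL-type objective.
`alphaStar()` sums each quartet's maximum probability and therefore
bounds every topology's score.  Because 5 taxa admit only 15 unrooted
binary topologies, `bestTree()` maximizes exhaustively; this removes
any dependence on the constrained search heuristics of practical
ASTRAL implementations while optimizing the identical objective.
Empirically the heuristic and exact maximizers are expected to coincide
at these sizes, since constrained search spaces are built from the input
gene trees and the relevant topologies occur frequently among them.

Ties at the maximum (within `1e-12`) are all reported, with the first
topology in canonical order as the deterministic representative and a
warning raised; the star-shaped table whose probabilities are all `1/3`
ties all 15 topologies and exercises this path in the tests.

## The misleading region Theta

`theorem1Holds()` implements the two strict inequalities under which the
non-displayed tree `S = (((A,E),B),C,D)` outscores both displayed
trees, `corollary2Holds()` the mirror conditions for
`S' = (((A,E),D),C,B)`, and `inTheta()` their union.  Three numerical
choices deserve note:

* **Strict floating-point comparisons, no epsilon.**  The region
  boundary has measure zero under the sampling distribution, so an
  epsilon would only blur the region without protecting anything.
* **`gamma` endpoints.**  `cycleParams()` accepts the closed interval
  `[0, 1]` so that the degenerate pure-tree cases (`gamma = 0` gives the
  MSC on `T2`, `gamma = 1` on `T1`) are expressible — they anchor the
  consistency checks.  The region conditions themselves divide by
  `gamma` and `1 - gamma` and therefore error at the endpoints.
* **Parameter sampling.**  Scans draw `y_i ~ Uniform(0,1)` directly,
  which is the same distribution as `e_i = -log(u)` Exponential with
  mean 1; this avoids any ambiguity about log-transform sign
  conventions.  `gamma` is uniform on the requested interval, or on a
  union of intervals with mass proportional to width.

The mirror map `e2 <-> e4`, `gamma <-> 1 - gamma` corresponds to the
cycle's reflection, which on taxa swaps **both** arm pairs,
`A <-> E` and `B <-> D`.  Restricted to the single tree `S` the
`B <-> D` swap alone already yields `S'`, but the full relabeling is
needed to map all 15 scores; the tests verify the complete symmetry.

## The synthetic-data generator

`simulateMSC()` draws i.i.d. gene trees on a rooted metric species
tree: within each branch, exponential waiting times at rate `k(k-1)/2`
and uniformly chosen coalescing pairs; survivors pass rootward, and
above the root coalescence runs to completion.  The per-gene core is
compiled (Rcpp) and consumes R's RNG stream, so a single `set.seed()`
(or the `seed` argument, which is recorded in the returned sample)
makes every experiment reproducible; gene trees are stored as unrooted
topology codes by default, with full metric trees behind
`retainTrees = TRUE`.

`simulateNMSCCycle()` simulates the network case by choosing a
displayed tree per gene with its inheritance weight and delegating to
the MSC core.  This tree-level mixing is *exactly* the NMSC here
because the hybrid node subtends a single taxon: only one lineage ever
enters a hybrid edge, so lineage-level and tree-level choices coincide.
The function refuses networks where the hybrid node subtends more than
one taxon, where the shortcut would be wrong.

`buildRootedNetwork()` places the root at the midpoint of the `e3`
edge with pendant and hybrid edges of length 1 — the same construction
as the reference extended-Newick string, reproduced exactly at the
reference parameters.  Quartet probabilities are provably root-
invariant, so this choice only pins down the rooted gene trees, never
the unrooted summaries; 15-topology frequencies are compared only
against this same construction.

What the generator deliberately does **not** emulate: gene-tree
estimation error (all gene trees are "true" topologies), multiple
samples per species, sequence evolution, or continuous migration.
Passing tests therefore demonstrate the model-level claim — that a
correctly computed quartet-score maximizer is misled by the NMSC
mixture itself — and say nothing about additional error sources in
real pipelines, which could only add noise on top of the systematic
effect.

The simulator is validated against two independent oracles: the
analytic quartet table (every quartet's simulated frequencies within 3
Monte-Carlo standard errors), and an exhaustive enumeration of
coalescent histories (branch-wise lineage-count transition
probabilities from the matrix exponential of the pure-death chain,
every merge sequence enumerated with its exact probability) that yields
the exact 15-topology distribution on a fixed species tree.

## Experiments and problem sizes

`reproduceT100K()` simulates 100,000 genes from the reference network
(`e2 = 2, e3 = 0.2, e4 = 1.1, gamma = 0.5`), `reproduceTable1()` scans
Theta with 10^6 draws per `gamma` range, and `trialStudy()` runs 100
Theta-sampled parameter sets at 1,000 genes with 50,000-gene reruns of
any trial whose stage-1 inference returned a displayed tree.  These are
the sizes at which the package's acceptance checks run; the unit-test
suite uses smaller sizes (10^4–10^5 draws or genes) chosen so that
3-standard-error bands are still decisive while the whole suite runs in
about a minute.  Experiment outputs embed their configuration
(parameters, seed, package version) and identical seeds reproduce
reports byte for byte.

## Known limitations

* Only the canonical 5-taxon 5-cycle frame is supported analytically;
  relabeled networks must be mapped onto taxa A–E, and larger cycles,
  multiple hybridizations or arbitrary network levels are out of scope.
* The extended-Newick reader supports exactly one hybrid node with the
  three-field `length:support:gamma` colon syntax (support ignored).
* The score maximizer is specific to 5 taxa (15 topologies); it is
  exact there but does not scale as written, which is intentional: the
  object of study is the objective function, not search.
* Probabilities are kept in ordinary double precision; all quantities
  involved are bounded away from underflow, and the per-quartet rows
  are validated to sum to 1 within `1e-12`.
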