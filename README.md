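# quartetNMSC

Quartet scores and species-tree inference under the network multispecies
coalescent.

## The problem

Quartet-based species-tree methods in the ASTRAL family search for the
unrooted tree `T` maximizing the quartet score

    (1/m) * sum_{q in Q(T)} w_m(q, T_m)

where `Q(T)` are the quartet topologies induced by `T` and `w_m(q, T_m)`
counts the input gene trees inducing `q`.  Under the multispecies
coalescent (MSC) on a species *tree* this is statistically consistent.  A
common network-inference pipeline therefore runs ASTRAL first to get a
"backbone" tree and then adds hybridization edges to it — implicitly
assuming the ASTRAL tree is *displayed* by the true network.

This package shows, analytically and by simulation, that the assumption
can fail even for simple, non-anomalous networks.  For gene trees arising
under the network multispecies coalescent (NMSC) on a 5-taxon network
with a single 5-cycle (internal edge lengths `e2`, `e3`, `e4` in
coalescent units, hybridization parameter `gamma`), the gene-tree
distribution is a `gamma/(1-gamma)` mixture of MSC distributions on the
two displayed trees `T1 = (A,(B,C),(D,E))` and `T2 = ((A,B),(C,D),E)`.
With `y_i = exp(-e_i)`, whenever

    (1 - y2) > gamma/(1-gamma) * (1 - y3*y4)                    and
    (1 - y3) < min( gamma/(2-gamma) * (1 - y4),
                    (1-gamma)/(1+gamma) * (1 - y2) )

the *non-displayed* tree `S = (((A,E),B),C,D)` has a higher expected
quartet score than both displayed trees (and a mirror-image condition
does the same for `S' = (((A,E),D),C,B)`).  The union of the two
condition sets is the misleading region `Theta`; about 6% of the
parameter space (edge lengths Exp(1), `gamma` uniform) lies inside it.

The package provides, for this setting:

* closed-form quartet topology probabilities under the MSC and the NMSC
  (`mscQuartetProbs`, `fourCycleQuartetProbs`, `fiveCycleQuartetTable`);
* expected quartet scores, the per-quartet bound `alpha*`, and an exact
  maximizer over all 15 unrooted 5-taxon topologies (`expectedScore`,
  `alphaStar`, `bestTree`, `inferTree`) — exhaustive, so no search
  heuristic is involved;
* executable region conditions and Monte-Carlo scans of `Theta`
  (`theorem1Holds`, `corollary2Holds`, `inTheta`, `sampleTheta`);
* a coalescent gene-tree simulator for rooted metric trees and
  single-cycle networks, with extended-Newick input
  (`simulateMSC`, `simulateNMSCCycle`, `parseExtendedNewick`,
  `buildRootedNetwork`);
* end-to-end experiment drivers (`reproduceT100K`, `reproduceTable1`,
  `trialStudy`).

## Worked example

The reference network has `e2 = 2`, `e3 = 0.2`, `e4 = 1.1`,
`gamma = 0.5`, which satisfies the misleading conditions:

```r
library(quartetNMSC)

p <- cycleParams(2, 0.2, 1.1, 0.5)
theorem1Holds(p)
#> [1] TRUE

qt <- fiveCycleQuartetTable(p)
qt
#> QuartetTable on {A,B,C,D,E}
#>   ABCD:  AB|CD 0.518544  AC|BD 0.073946  AD|BC 0.407510
#>   ABCE:  AB|CE 0.282568  AC|BE 0.191934  AE|BC 0.525498
#>   ABDE:  AB|DE 0.454179  AD|BE 0.272910  AE|BD 0.272910
#>   ACDE:  AC|DE 0.249646  AD|CE 0.159011  AE|CD 0.591343
#>   BCDE:  BC|DE 0.431712  BD|CE 0.067978  BE|CD 0.500310

bestTree(qt)
#> ScoreReport (expected quartet scores over 15 topologies)
#>   alpha* = 2.589875
#>   ((C,D),(A,E),B);       2.408606 <- best
#>   ((A,B),(C,D),E);       2.346945
#>   ((B,C),(A,E),D);       2.228974
#>   ...
```

Each row of the quartet table gives the three gene-tree probabilities of
one 4-taxon subset; e.g. for `{A,B,C,D}` the displayed split `AB|CD` has
probability 0.519 and the non-displayed `AC|BD` only 0.074.  Yet the
score maximizer returns `((C,D),(A,E),B);` — the tree `S`, which the
network does **not** display — ahead of the displayed `T2`
(score 2.347).  Simulation confirms the analytic prediction:

```r
g <- simulateNMSCCycle(buildRootedNetwork(p), 100000, seed = 1)
round(head(topologyFrequencies(g), 4), 3)
#> ((A,B),(C,D),E); ((D,E),(B,C),A); ((C,D),(B,E),A); ((C,D),(A,E),B);
#>            0.215            0.174            0.131            0.129

topologyNewick(bestTopology(inferTree(g)))
#> [1] "((C,D),(A,E),B);"
isDisplayed(bestTopology(inferTree(g)), p)
#> [1] FALSE
```

The displayed trees `T2` and `T1` are the two most frequent gene-tree
topologies (the network is not anomalous), but the inferred tree is
still `S`.

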