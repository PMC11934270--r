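#' Unrooted binary tree topology, canonically encoded
#'
#' A `Topology` stores the shape of an unrooted binary tree on a fixed
#' taxon set as the set of its nontrivial splits, with no branch lengths.
#' Each split is written canonically (smaller side first, ties broken
#' lexicographically) and the split strings are sorted, so two `Topology`
#' objects are equal if and only if they describe the same unrooted shape.
#' For 5 taxa there are exactly two nontrivial splits and 15 distinct
#' topologies.
#'
#' @slot taxa sorted character vector of taxon labels.
#' @slot sides list of character vectors; for each nontrivial split, its
#'   minimal side (fewest taxa, ties broken lexicographically), sorted.
#' @slot id canonical identifier: the sorted split strings joined by `";"`.
#'
#' @seealso [topology()], [enumerateTopologies()], [unrootedTopology()],
#'   [namedTopologies()]
#' @export
setClass("Topology",
         representation(taxa = "character", sides = "list", id = "character"))

setValidity("Topology", function(object) {
  if (is.unsorted(object@taxa) || anyDuplicated(object@taxa))
    return("taxa must be sorted and unique")
  n <- length(object@taxa)
  if (n < 4) return("a Topology needs at least 4 taxa")
  if (length(object@sides) != n - 3L)
    return(sprintf("a binary topology on %d taxa has %d nontrivial splits",
                   n, n - 3L))
  for (s in object@sides) {
    if (!all(s %in% object@taxa)) return("split side contains unknown taxa")
    if (length(s) < 2 || length(s) > n - 2)
      return("split sides must be nontrivial")
  }
  TRUE
})

#' Free parameters of the canonical 5-taxon 5-cycle network
#'
#' Holds the three internal edge lengths `e2`, `e3`, `e4` (coalescent
#' units) of the canonical 5-cycle network on taxa A--E together with the
#' hybridization parameter `gamma` (the inheritance probability of the
#' hybrid edge whose retention yields the displayed tree T1).  The derived
#' quantities `y_i = exp(-e_i)` are available through [yValues()].
#'
#' `gamma` may take the boundary values 0 and 1, which degenerate the
#' network to a pure species tree (T2 and T1 respectively); the region
#' conditions [theorem1Holds()] and [corollary2Holds()] are only defined
#' for `0 < gamma < 1`.
#'
#' @slot e2,e3,e4 positive edge lengths in coalescent units.
#' @slot gamma hybridization parameter in `[0, 1]`.
#'
#' @seealso [cycleParams()], [fiveCycleQuartetTable()],
#'   [buildRootedNetwork()]
#' @export
setClass("CycleNetworkParams",
         representation(e2 = "numeric", e3 = "numeric", e4 = "numeric",
                        gamma = "numeric"))

setValidity("CycleNetworkParams", function(object) {
  for (nm in c("e2", "e3", "e4", "gamma")) {
    v <- slot(object, nm)
    if (length(v) != 1 || !is.finite(v))
      return(sprintf("%s must be a single finite number", nm))
  }
  if (object@e2 <= 0 || object@e3 <= 0 || object@e4 <= 0)
    return("edge lengths e2, e3, e4 must be positive")
  if (object@gamma < 0 || object@gamma > 1)
    return("gamma must lie in [0, 1]")
  TRUE
})

#' Rooted single-hybridization network
#'
#' A rooted, binary, single-hybrid phylogenetic network read from extended
#' Newick notation.  The hybrid node has exactly two parent (hybrid)
#' edges, each carrying an inheritance weight; the two weights sum to 1.
#' Removing either hybrid edge and suppressing the resulting degree-2
#' nodes (summing branch lengths exactly) yields a rooted displayed tree;
#' see [displayedTrees()].
#'
#' @slot taxa sorted character vector of leaf labels.
#' @slot edges data.frame with columns `parent`, `child` (node names),
#'   `length` (coalescent units) and `gamma` (inheritance weight, `NA` on
#'   non-hybrid edges; exactly two non-`NA` entries).
#' @slot root name of the root node.
#' @slot hybrid name of the hybrid node.
#' @slot newick the extended-Newick string the network was built from.
#'
#' @seealso [parseExtendedNewick()], [buildRootedNetwork()],
#'   [displayedTrees()]
#' @export
setClass("HybridNetwork",
         representation(taxa = "character", edges = "data.frame",
                        root = "character", hybrid = "character",
                        newick = "character"))

setValidity("HybridNetwork", function(object) {
  ed <- object@edges
  need <- c("parent", "child", "length", "gamma")
  if (!all(need %in% names(ed))) return("edges must have parent/child/length/gamma")
  if (any(ed$length < 0, na.rm = TRUE)) return("branch lengths must be >= 0")
  hyb <- which(!is.na(ed$gamma))
  if (length(hyb) != 2) return("exactly two hybrid edges required")
  if (!all(ed$child[hyb] == object@hybrid))
    return("both hybrid edges must point to the hybrid node")
  if (abs(sum(ed$gamma[hyb]) - 1) > 1e-9)
    return("hybrid-edge inheritance weights must sum to 1")
  TRUE
})

#' Quartet topology probabilities for all 4-taxon subsets
#'
#' For a 5-taxon set there are five 4-taxon subsets, each with three
#' resolved quartet topologies (e.g. `AB|CD`, `AC|BD`, `AD|BC`).  A
#' `QuartetTable` stores all 15 probabilities as a named vector; within
#' each quartet the three probabilities sum to 1.  Tables arise either
#' analytically from network parameters ([fiveCycleQuartetTable()]) or
#' empirically as relative quartet frequencies of a gene-tree sample
#' ([empiricalQuartetTable()]).
#'
#' @slot taxa sorted character vector of 5 taxon labels.
#' @slot probs named numeric vector of length 15; names are canonical
#'   quartet split strings such as `"AB|CD"`, grouped by 4-taxon subset.
#'
#' @seealso [quartetProbs()], [expectedScore()], [writeQuartetTable()]
#' @export
setClass("QuartetTable",
         representation(taxa = "character", probs = "numeric"))

setValidity("QuartetTable", function(object) {
  if (length(object@taxa) != 5) return("QuartetTable requires 5 taxa")
  expected <- allQuartetSplits(object@taxa)
  if (!identical(names(object@probs), expected))
    return("probs must be named by the 15 canonical quartet splits")
  if (any(object@probs < -1e-12 | object@probs > 1 + 1e-12))
    return("probabilities must lie in [0, 1]")
  sums <- rowSums(matrix(object@probs, nrow = 5, byrow = TRUE))
  if (any(abs(sums - 1) > 1e-8))
    return("each quartet's three probabilities must sum to 1")
  TRUE
})

#' Sample of simulated unrooted gene-tree topologies
#'
#' An ordered collection of gene trees simulated under the MSC or the
#' NMSC, stored as integer codes into a fixed list of unrooted topologies
#' (15 for 5 taxa, 3 for 4 taxa).  Full metric gene trees are retained as
#' `phylo` objects only when requested at simulation time.
#'
#' @slot taxa sorted character vector of taxon labels (4 or 5).
#' @slot codes integer vector; `codes[g]` indexes `levels` for gene `g`.
#' @slot levels canonical topology identifiers, in the order used by
#'   `codes` (the order of [enumerateTopologies()] for 5 taxa).
#' @slot seed integer seed used for the simulation (`NA` if none given).
#' @slot source character description of the generating model.
#' @slot trees list of `phylo` gene trees (empty unless retained).
#'
#' @seealso [simulateMSC()], [simulateNMSCCycle()],
#'   [topologyFrequencies()], [empiricalQuartetTable()]
#' @export
setClass("GeneTreeSample",
         representation(taxa = "character", codes = "integer",
                        levels = "character", seed = "integer",
                        source = "character", trees = "list"))

setValidity("GeneTreeSample", function(object) {
  if (length(object@codes) < 1) return("a sample holds at least one gene tree")
  if (anyNA(object@codes) || any(object@codes < 1) ||
      any(object@codes > length(object@levels)))
    return("codes must index levels")
  if (length(object@trees) &&
      length(object@trees) != length(object@codes))
    return("retained trees must match the number of gene trees")
  TRUE
})

#' Expected (or empirical) quartet-score report over all 15 topologies
#'
#' Scores every unrooted 5-taxon topology against a
#' [QuartetTable-class] (sum,
#' over the topology's five induced quartets, of their probabilities), and
#' records the argmax set together with the per-quartet upper bound
#' alpha*.  Every score is at most `alphaStar`; the first element of
#' `best` is the deterministic representative (canonical topology order).
#'
#' @slot scores named numeric vector of length 15 (names are canonical
#'   topology identifiers, in canonical order).
#' @slot best character vector of topology identifiers attaining the
#'   maximal score within tolerance.
#' @slot alphaStar the per-quartet maximum-probability sum.
#' @slot taxa sorted character vector of 5 taxon labels.
#'
#' @seealso [bestTree()], [inferTree()], [alphaStar()],
#'   [writeScoreReport()]
#' @export
setClass("ScoreReport",
         representation(scores = "numeric", best = "character",
                        alphaStar = "numeric", taxa = "character"))

setValidity("ScoreReport", function(object) {
  if (!length(object@best)) return("best set must be nonempty")
  if (any(object@scores > object@alphaStar + 1e-12))
    return("no score may exceed alphaStar")
  if (!all(object@best %in% names(object@scores)))
    return("best must be a subset of the scored topologies")
  TRUE
})

#' Monte-Carlo scan of the misleading parameter region Theta
#'
#' Result of drawing network parameters with `y_i = exp(-e_i)` i.i.d.
#' Uniform(0,1) (equivalently `e_i` Exponential with mean 1) and gamma
#' uniform on a given range (or union of ranges), and testing each draw
#' against the misleading-region conditions.  `proportion` is the fraction
#' of draws in Theta; `summary` holds per-parameter means over the Theta
#' members and fixed-bin histograms.
#'
#' @slot n number of draws.
#' @slot gammaRange 2-column matrix; each row one interval of the gamma
#'   sampling range.
#' @slot proportion fraction of draws in Theta.
#' @slot summary list with elements `nTheta`, `means` (named means of e2,
#'   e3, e4, gamma over Theta members; `NA` if Theta is empty) and `hist`
#'   (per-parameter 50-bin histogram counts over Theta members).
#' @slot draws data.frame of the individual draws (only if requested).
#' @slot seed integer seed (`NA` if none given).
#'
#' @seealso [sampleTheta()], [thetaSummaries()], [inTheta()]
#' @export
setClass("ThetaScan",
         representation(n = "integer", gammaRange = "matrix",
                        proportion = "numeric", summary = "list",
                        draws = "data.frame", seed = "integer"))

setValidity("ThetaScan", function(object) {
  if (object@n < 1) return("n must be >= 1")
  if (object@proportion < 0 || object@proportion > 1)
    return("proportion must lie in [0, 1]")
  TRUE
})
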