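# Expected and empirical quartet scores ------------------------------------

# Cached 15 x 15 indicator matrix: row i, column s is 1 iff topology i
# (in canonical order) induces quartet split s (canonical split order).
.scoreMatrixCache <- new.env(parent = emptyenv())

.scoreMatrix <- function(taxa) {
  key <- paste(sort(taxa), collapse = "")
  if (is.null(.scoreMatrixCache[[key]])) {
    topos <- .enumTopo(taxa)
    splitNames <- allQuartetSplits(taxa)
    ind <- matrix(0, nrow = length(topos), ncol = length(splitNames),
                  dimnames = list(vapply(topos, topologyId, character(1)),
                                  splitNames))
    for (i in seq_along(topos))
      ind[i, inducedQuartets(topos[[i]])] <- 1
    .scoreMatrixCache[[key]] <- ind
  }
  .scoreMatrixCache[[key]]
}

#' Expected quartet score of a topology
#'
#' The expected quartet score (the large-sample limit of the ASTRAL-type
#' objective, normalized per gene) of an unrooted 5-taxon topology is the
#' sum, over its five induced quartet splits, of those splits'
#' probabilities in the table.  Scores lie in `[0, 5]`.
#'
#' @param t a 5-taxon [Topology-class] object.
#' @param q a [QuartetTable-class] on the same taxa.
#' @return A single number.
#' @examples
#' qt <- fiveCycleQuartetTable(cycleParams(2, 0.2, 1.1, 0.5))
#' expectedScore(namedTopologies()$S, qt)
#' @rdname expectedScore
#' @export
setMethod("expectedScore", signature("Topology", "QuartetTable"),
          function(t, q) {
  if (!identical(t@taxa, q@taxa))
    stop("topology and quartet table are on different taxa")
  sum(q@probs[inducedQuartets(t)])
})

#' Per-quartet maximum-probability score bound alpha*
#'
#' Summing, for each 4-taxon subset, the largest of its three quartet
#' probabilities gives an upper bound on the expected quartet score of
#' *any* topology, attained only if some topology displays the most
#' probable split of every quartet.
#'
#' @param q a [QuartetTable-class] object.
#' @return A single number in `[5/3, 5]`.
#' @examples
#' alphaStar(fiveCycleQuartetTable(cycleParams(2, 0.2, 1.1, 0.5)))
#' @rdname alphaStar
#' @export
setMethod("alphaStar", "QuartetTable", function(q) {
  sum(apply(matrix(q@probs, nrow = 5, byrow = TRUE), 1, max))
})

#' Exact quartet-score maximizer over all 15 topologies
#'
#' Scores every unrooted binary topology on the table's 5 taxa and
#' returns all argmax topologies within tolerance, with the first
#' topology in canonical order as the deterministic representative.  For
#' 5 taxa the search space has only 15 trees, so the maximization is
#' exhaustive and exact (no search heuristic).  Ties are reported with a
#' warning.
#'
#' @param q a [QuartetTable-class] object.
#' @param tol tie tolerance on the score (default `1e-12`).
#' @param ... unused.
#' @return A [ScoreReport-class] object.
#' @examples
#' rep <- bestTree(fiveCycleQuartetTable(cycleParams(2, 0.2, 1.1, 0.5)))
#' topologyNewick(bestTopology(rep))
#' @rdname bestTree
#' @export
setMethod("bestTree", "QuartetTable", function(q, tol = 1e-12, ...) {
  ind <- .scoreMatrix(q@taxa)
  scores <- setNames(as.numeric(ind %*% q@probs), rownames(ind))
  best <- names(scores)[scores >= max(scores) - tol]
  if (length(best) > 1)
    warning(sprintf("tie among %d topologies at the maximal score",
                    length(best)))
  new("ScoreReport", scores = scores, best = best,
      alphaStar = alphaStar(q), taxa = q@taxa)
})

#' @describeIn bestTree the representative best [Topology-class] of a
#'   [ScoreReport-class] (first argmax in canonical order).
#' @param x a [ScoreReport-class] object.
#' @export
setMethod("bestTopology", "ScoreReport", function(x) {
  topos <- .enumTopo(x@taxa)
  topos[[match(x@best[1], vapply(topos, topologyId, character(1)))]]
})

setMethod("show", "ScoreReport", function(object) {
  cat("ScoreReport (expected quartet scores over 15 topologies)\n")
  cat(sprintf("  alpha* = %.6f\n", object@alphaStar))
  topos <- .enumTopo(object@taxa)
  nwk <- vapply(topos, topologyNewick, character(1))
  ids <- vapply(topos, topologyId, character(1))
  o <- order(object@scores, decreasing = TRUE)
  for (i in o) {
    mark <- if (ids[i] %in% object@best) " <- best" else ""
    cat(sprintf("  %-22s %.6f%s\n", nwk[match(ids[i], ids)],
                object@scores[[i]], mark))
  }
})

#' Empirical quartet table of a gene-tree sample
#'
#' For each 4-taxon subset, the relative frequency with which the sample's
#' gene trees induce each of the three quartet splits.  Frequencies
#' converge to the analytic [fiveCycleQuartetTable()] as the sample grows.
#'
#' @param g a 5-taxon [GeneTreeSample-class].
#' @return A [QuartetTable-class] object.
#' @rdname empiricalQuartetTable
#' @export
setMethod("empiricalQuartetTable", "GeneTreeSample", function(g) {
  if (length(g@taxa) != 5)
    stop("empirical quartet tables require 5-taxon samples")
  m <- length(g@codes)
  ind <- .scoreMatrix(g@taxa)
  freq <- tabulate(g@codes, nbins = nrow(ind)) / m
  quartetTable(setNames(as.numeric(freq %*% ind), colnames(ind)), g@taxa)
})

#' Infer the quartet-score-maximizing topology from gene trees
#'
#' Computes the empirical quartet table of the sample and maximizes the
#' quartet score exhaustively over all 15 unrooted topologies.  This is
#' the exact version of the ASTRAL-type objective: on 5 taxa the
#' constrained search of practical implementations coincides with the
#' global maximizer.
#'
#' @param g a 5-taxon [GeneTreeSample-class].
#' @param ... passed to [bestTree()] (e.g. `tol`).
#' @return A [ScoreReport-class] object (scores here are per-gene
#'   normalized quartet-agreement frequencies; multiply by the sample
#'   size for raw counts).
#' @rdname inferTree
#' @export
setMethod("inferTree", "GeneTreeSample", function(g, ...) {
  bestTree(empiricalQuartetTable(g), ...)
})

#' Is a topology displayed by the canonical 5-cycle network?
#'
#' The canonical 5-cycle network displays exactly the two topologies
#' `T1 = (A,(B,C),(D,E))` and `T2 = ((A,B),(C,D),E)`, whatever its
#' numerical parameters.  A quartet-score maximizer returning any of the
#' other 13 topologies (such as `S` or `Sprime`) has been misled.
#'
#' @param t a 5-taxon [Topology-class] on taxa A--E.
#' @param p a [CycleNetworkParams-class] object (the displayed topologies
#'   do not depend on its numeric values; the argument fixes the network
#'   frame).
#' @return `TRUE` or `FALSE`.
#' @examples
#' p <- cycleParams(2, 0.2, 1.1, 0.5)
#' isDisplayed(namedTopologies()$T1, p)
#' isDisplayed(namedTopologies()$S, p)
#' @rdname isDisplayed
#' @export
setMethod("isDisplayed", signature("Topology", "CycleNetworkParams"),
          function(t, p) {
  nt <- namedTopologies()
  if (!identical(t@taxa, nt$T1@taxa))
    stop("isDisplayed is defined on the canonical taxa A-E")
  t@id %in% c(nt$T1@id, nt$T2@id)
})

#' Write a score report as TSV
#'
#' Columns: `topology` (canonical Newick), `score`, `is_displayed`
#' (relative to the canonical 5-cycle; only when `params` is supplied)
#' and `is_best`.
#'
#' @param report a [ScoreReport-class] object.
#' @param file output path.
#' @param params optional [CycleNetworkParams-class]; adds the
#'   `is_displayed` column.
#' @export
writeScoreReport <- function(report, file, params = NULL) {
  topos <- .enumTopo(report@taxa)
  ids <- vapply(topos, topologyId, character(1))
  df <- data.frame(topology = vapply(topos, topologyNewick, character(1)),
                   score = as.numeric(report@scores[ids]),
                   stringsAsFactors = FALSE)
  if (!is.null(params))
    df$is_displayed <- vapply(topos, isDisplayed, logical(1), p = params)
  df$is_best <- ids %in% report@best
  write.table(df, file = file, sep = "\t", quote = FALSE, row.names = FALSE)
}
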