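# Quartet gene-tree topology probabilities --------------------------------

#' Quartet topology probabilities under the multispecies coalescent
#'
#' For a 4-taxon species tree with internal branch length `t` (coalescent
#' units), the gene-tree quartet matching the species tree has probability
#' `1 - (2/3) exp(-t)` and each of the two discordant quartets has
#' probability `(1/3) exp(-t)`.
#'
#' @param t internal branch length in coalescent units, `t >= 0`
#'   (may be `Inf`).
#' @return Numeric vector `c(major, minor, minor)` summing to 1.
#' @examples
#' mscQuartetProbs(0.2)
#' @export
mscQuartetProbs <- function(t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("t must be a single nonnegative number")
  et <- exp(-t)
  c(major = 1 - 2 / 3 * et, minor = et / 3, minor = et / 3)
}

#' Quartet probabilities for a 4-cycle network
#'
#' Closed-form gene-tree quartet probabilities under the NMSC for the
#' canonical 4-cycle network on taxa A--D, where the displayed tree
#' `AB|CD` (retained with probability `1 - gamma`) has internal length `x`
#' and the displayed tree `AD|BC` (retained with probability `gamma`) has
#' internal length `y`:
#' \deqn{P(AB|CD) = (1-\gamma)(1 - \tfrac{2}{3}e^{-x}) + \gamma\,\tfrac{1}{3}e^{-y}}
#' \deqn{P(AD|BC) = (1-\gamma)\,\tfrac{1}{3}e^{-x} + \gamma(1 - \tfrac{2}{3}e^{-y})}
#' \deqn{P(AC|BD) = (1-\gamma)\,\tfrac{1}{3}e^{-x} + \gamma\,\tfrac{1}{3}e^{-y}}
#' The non-displayed quartet `AC|BD` is never the most probable one.
#'
#' @param x,y internal branch lengths of the two displayed quartet trees,
#'   in coalescent units (`>= 0`).
#' @param gamma hybridization parameter in `[0, 1]`.
#' @return Named numeric vector `c("AB|CD", "AC|BD", "AD|BC")` summing
#'   to 1.
#' @examples
#' fourCycleQuartetProbs(2.2, 1.1, 0.5)
#' @export
fourCycleQuartetProbs <- function(x, y, gamma) {
  if (x < 0 || y < 0) stop("x and y must be nonnegative")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  ex <- exp(-x)
  ey <- exp(-y)
  c("AB|CD" = (1 - gamma) * (1 - 2 / 3 * ex) + gamma * ey / 3,
    "AC|BD" = (1 - gamma) * ex / 3 + gamma * ey / 3,
    "AD|BC" = (1 - gamma) * ex / 3 + gamma * (1 - 2 / 3 * ey))
}

#' Gap between the two displayed quartet probabilities of a 4-cycle
#'
#' The difference `P(AB|CD) - P(AD|BC)` in closed form,
#' `(1-gamma)(1 - e^-x) - gamma(1 - e^-y)`; it is positive exactly when
#' the `AB|CD` displayed quartet is the most probable.
#'
#' @inheritParams fourCycleQuartetProbs
#' @return A single number.
#' @examples
#' quartetGap(2.2, 1.1, 0.5)
#' @export
quartetGap <- function(x, y, gamma) {
  if (x < 0 || y < 0) stop("x and y must be nonnegative")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  (1 - gamma) * (1 - exp(-x)) - gamma * (1 - exp(-y))
}

# Quartet restriction of a metric tree -------------------------------------

# Internal work-horse on precomputed splits (see .treeSplits).
.quartetFromSplits <- function(splits, quartet, taxa) {
  name <- NULL
  len <- 0
  for (k in seq_along(splits$side)) {
    a <- intersect(splits$side[[k]], quartet)
    if (length(a) == 2 && length(quartet) - 2 ==
        length(setdiff(quartet, splits$side[[k]]))) {
      nm <- .splitString(a, setdiff(quartet, a))
      if (is.null(name)) {
        name <- nm
      } else if (nm != name) {
        stop("internal error: incompatible quartet restrictions")
      }
      len <- len + splits$length[k]
    }
  }
  if (is.null(name)) stop("tree is unresolved on the quartet")
  list(split = name, length = len)
}

#' Quartet topology and internal length displayed by a metric tree
#'
#' Restricts a metric tree to four taxa and reports the quartet split it
#' displays together with the length of the internal path separating the
#' two pairs (the sum of all tree edges whose split restricts to that
#' quartet split).
#'
#' @param tree a `phylo` object containing the four taxa.
#' @param quartet character vector of 4 taxon labels.
#' @return `list(split = <character>, length = <numeric>)`.
#' @examples
#' tr <- parseNewick("((C:2,B:1)G:1.1,A:1,(D:3.1,E:1.1)K:0.1);")
#' quartetInternalLength(tr, c("A", "B", "D", "E"))
#' @export
quartetInternalLength <- function(tree, quartet) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  quartet <- sort(quartet)
  if (length(quartet) != 4 || anyDuplicated(quartet))
    stop("quartet must name 4 distinct taxa")
  if (!all(quartet %in% tree$tip.label))
    stop("quartet taxa not all present in the tree")
  .quartetFromSplits(.treeSplits(tree), quartet, sort(tree$tip.label))
}

#' Mixture quartet probabilities over displayed trees
#'
#' Under the NMSC on a single-cycle network, the gene-tree distribution is
#' a mixture of MSC distributions on the displayed trees, weighted by the
#' retained hybrid-edge inheritance weights.  For one 4-taxon subset this
#' mixes the MSC quartet probabilities implied by each displayed tree's
#' quartet split and internal length.
#'
#' @param displayed a list of `list(tree = <phylo>, weight = <numeric>)`
#'   pairs as returned by [displayedTrees()]; weights must sum to 1.
#' @param quartet character vector of 4 taxon labels present in every
#'   displayed tree.
#' @return Named numeric vector of the 3 quartet probabilities, in
#'   canonical split order, summing to 1.
#' @examples
#' net <- buildRootedNetwork(cycleParams(2, 0.2, 1.1, 0.5))
#' quartetMixture(displayedTrees(net), c("A", "B", "C", "D"))
#' @export
quartetMixture <- function(displayed, quartet) {
  quartet <- sort(quartet)
  w <- vapply(displayed, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("component weights must sum to 1")
  names <- quartetSplits(quartet)
  out <- setNames(numeric(3), names)
  for (d in displayed) {
    ql <- quartetInternalLength(d$tree, quartet)
    p <- mscQuartetProbs(ql$length)
    vec <- setNames(rep(p[[2]], 3), names)
    vec[ql$split] <- p[[1]]
    out <- out + d$weight * vec
  }
  out
}

# The analytic quartet table ------------------------------------------------

#' Construct a QuartetTable from a named probability vector
#'
#' @param probs named numeric vector of 15 probabilities, named by the
#'   canonical quartet splits of `taxa` (see [allQuartetSplits()]).
#' @param taxa character vector of 5 taxon labels.
#' @return A [QuartetTable-class] object.
#' @export
quartetTable <- function(probs, taxa = c("A", "B", "C", "D", "E")) {
  taxa <- sort(taxa)
  probs <- probs[allQuartetSplits(taxa)]
  new("QuartetTable", taxa = taxa, probs = probs)
}

#' Analytic quartet table of the canonical 5-cycle network
#'
#' Builds the full table of gene-tree quartet probabilities under the
#' NMSC for the canonical 5-cycle network: the rooted network is
#' constructed with [buildRootedNetwork()], its two displayed trees are
#' extracted, and every 4-taxon subset is assigned the
#' gamma/(1-gamma)-weighted mixture of MSC quartet probabilities via
#' [quartetMixture()].  One code path serves all five quartets; the
#' hand-derived per-quartet reductions (e.g. the `{A,B,C,D}` subset being
#' a 4-cycle with `x = e2 + e3`, `y = e4`) are used as cross-checks in the
#' test suite, not as the implementation.
#'
#' @param p a [CycleNetworkParams-class] object.
#' @return A [QuartetTable-class] object.
#' @examples
#' qt <- fiveCycleQuartetTable(cycleParams(2, 0.2, 1.1, 0.5))
#' quartetProbs(qt, c("A", "B", "C", "D"))
#' @export
fiveCycleQuartetTable <- function(p) {
  stopifnot(is(p, "CycleNetworkParams"))
  validObject(p)
  net <- buildRootedNetwork(p)
  d <- displayedTrees(net)
  taxa <- net@taxa
  splits <- lapply(d, function(x) .treeSplits(x$tree))
  w <- vapply(d, `[[`, numeric(1), "weight")
  probs <- numeric(0)
  for (q in combn(taxa, 4, simplify = FALSE)) {
    names <- quartetSplits(q)
    vec <- setNames(numeric(3), names)
    for (k in seq_along(d)) {
      ql <- .quartetFromSplits(splits[[k]], q, taxa)
      pk <- mscQuartetProbs(ql$length)
      comp <- setNames(rep(pk[[2]], 3), names)
      comp[ql$split] <- pk[[1]]
      vec <- vec + w[k] * comp
    }
    probs <- c(probs, vec)
  }
  quartetTable(probs, taxa)
}

#' Probabilities of one quartet's three topologies
#'
#' @param x a [QuartetTable-class] object.
#' @param quartet character vector of 4 taxon labels (or the concatenated
#'   sorted key, e.g. `"ABCD"`).
#' @return Named numeric vector of length 3.
#' @rdname quartetProbs
#' @export
setMethod("quartetProbs", "QuartetTable", function(x, quartet) {
  if (length(quartet) == 1) quartet <- strsplit(quartet, "")[[1]]
  x@probs[quartetSplits(quartet)]
})

setMethod("show", "QuartetTable", function(object) {
  cat("QuartetTable on {", paste(object@taxa, collapse = ","), "}\n",
      sep = "")
  df <- as.data.frame(object)
  for (qq in unique(df$quartet)) {
    rows <- df[df$quartet == qq, ]
    cat(sprintf("  %s:  %s\n", qq,
                paste(sprintf("%s %.6f", rows$split, rows$probability),
                      collapse = "  ")))
  }
})

#' @export
#' @method as.data.frame QuartetTable
as.data.frame.QuartetTable <- function(x, ...) {
  quartets <- vapply(combn(x@taxa, 4, simplify = FALSE), .sideString,
                     character(1))
  data.frame(quartet = rep(quartets, each = 3),
             split = names(x@probs),
             probability = as.numeric(x@probs),
             stringsAsFactors = FALSE)
}

#' Write a quartet table as TSV
#'
#' Columns: `quartet`, `split`, `probability`.
#'
#' @param qt a [QuartetTable-class] object.
#' @param file output path.
#' @export
writeQuartetTable <- function(qt, file) {
  write.table(as.data.frame(qt), file = file, sep = "\t",
              quote = FALSE, row.names = FALSE)
}
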