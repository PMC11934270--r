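# Canonical split encoding -------------------------------------------------
#
# A nontrivial split of a taxon set is written "side1|side2" with each side
# the sorted concatenation of its labels and the lexicographically smaller
# side first.  A Topology stores, for each split, its *minimal* side (fewer
# taxa; ties broken lexicographically), which for 5-taxon topologies is
# always a 2-taxon pair.

.sideString <- function(side) paste(sort(side), collapse = "")

.splitString <- function(sideA, sideB) {
  a <- .sideString(sideA)
  b <- .sideString(sideB)
  if (a < b) paste0(a, "|", b) else paste0(b, "|", a)
}

.minimalSide <- function(side, taxa) {
  other <- setdiff(taxa, side)
  if (length(side) < length(other)) return(sort(side))
  if (length(other) < length(side)) return(sort(other))
  if (.sideString(side) <= .sideString(other)) sort(side) else sort(other)
}

#' Construct a Topology from its nontrivial splits
#'
#' @param sides list of character vectors, one side of each nontrivial
#'   split (either side may be given; the canonical minimal side is
#'   stored).
#' @param taxa character vector of taxon labels.
#' @return A [Topology-class] object.
#' @examples
#' topology(list(c("A", "B"), c("C", "D")), LETTERS[1:5])  # ((A,B),(C,D),E)
#' @export
topology <- function(sides, taxa) {
  taxa <- sort(taxa)
  sides <- lapply(sides, .minimalSide, taxa = taxa)
  splits <- vapply(sides, function(s) .splitString(s, setdiff(taxa, s)),
                   character(1))
  o <- order(splits)
  if (anyDuplicated(splits)) stop("duplicate splits")
  new("Topology", taxa = taxa, sides = sides[o],
      id = paste(splits[o], collapse = ";"))
}

#' @describeIn topology Canonical identifier of a topology (sorted split
#'   strings joined by `";"`).
#' @param t a [Topology-class] object.
#' @export
topologyId <- function(t) t@id

#' Compare topologies for equality
#'
#' Two topologies are equal iff they are on the same taxa and have equal
#' canonical split sets.
#'
#' @param e1,e2 [Topology-class] objects.
#' @name Topology-equality
#' @rdname Topology-equality
#' @aliases ==,Topology,Topology-method
#' @export
setMethod("==", signature("Topology", "Topology"), function(e1, e2) {
  identical(e1@taxa, e2@taxa) && identical(e1@id, e2@id)
})

#' @rdname Topology-equality
#' @aliases !=,Topology,Topology-method
#' @export
setMethod("!=", signature("Topology", "Topology"), function(e1, e2) {
  !(e1 == e2)
})

#' Canonical Newick string of an unrooted topology
#'
#' For 5 taxa the form is `((p,q),(r,s),free);` with the two pairs in
#' canonical order; for 4 taxa, `(p,q,(r,s));`.  No branch lengths are
#' written.
#'
#' @param t a [Topology-class] object.
#' @return A single Newick string.
#' @rdname topologyNewick
#' @export
setMethod("topologyNewick", "Topology", function(t) {
  n <- length(t@taxa)
  pair <- function(s) paste0("(", paste(s, collapse = ","), ")")
  if (n == 5) {
    free <- setdiff(t@taxa, unlist(t@sides))
    paste0("(", pair(t@sides[[1]]), ",", pair(t@sides[[2]]), ",", free, ");")
  } else if (n == 4) {
    other <- setdiff(t@taxa, t@sides[[1]])
    paste0("(", paste(t@sides[[1]], collapse = ","), ",", pair(other), ");")
  } else {
    stop("canonical Newick output supports 4 or 5 taxa")
  }
})

setMethod("show", "Topology", function(object) {
  cat("Topology on {", paste(object@taxa, collapse = ","), "}: ",
      topologyNewick(object), "  [", object@id, "]\n", sep = "")
})

#' Enumerate all unrooted binary topologies on 5 taxa
#'
#' There are (2*5-5)!! = 15 unrooted binary topologies on 5 labels.  Each
#' is determined by an unordered pair of disjoint 2-taxon subsets (the
#' fifth taxon is attached to the internal edge between them).  The list
#' is returned in deterministic canonical order (sorted by topology
#' identifier), the order used for tie-breaking throughout the package.
#'
#' @param taxa character vector of exactly 5 distinct labels.
#' @return A list of 15 [Topology-class] objects.
#' @examples
#' length(enumerateTopologies(LETTERS[1:5]))
#' @export
enumerateTopologies <- function(taxa) {
  if (length(taxa) != 5 || anyDuplicated(taxa))
    stop("exactly 5 distinct taxon labels are required")
  taxa <- sort(taxa)
  pairs <- combn(taxa, 2, simplify = FALSE)
  out <- list()
  for (i in seq_along(pairs)) {
    for (j in seq_along(pairs)) {
      if (i < j && !length(intersect(pairs[[i]], pairs[[j]]))) {
        out[[length(out) + 1L]] <- topology(list(pairs[[i]], pairs[[j]]), taxa)
      }
    }
  }
  out[order(vapply(out, topologyId, character(1)))]
}

# Memoized per-taxa enumeration (identifiers are recomputed often).
.topoCache <- new.env(parent = emptyenv())

.enumTopo <- function(taxa) {
  key <- paste(sort(taxa), collapse = "")
  if (is.null(.topoCache[[key]]))
    .topoCache[[key]] <- enumerateTopologies(taxa)
  .topoCache[[key]]
}

#' The named topologies of the canonical 5-cycle frame
#'
#' Returns the four named 5-taxon topologies used throughout: the two
#' displayed trees of the canonical 5-cycle network,
#' `T1 = (A,(B,C),(D,E))` and `T2 = ((A,B),(C,D),E)`, and the two
#' non-displayed trees `S = (((A,E),B),C,D)` and `Sprime = (((A,E),D),C,B)`
#' that can outscore them.
#'
#' @return A named list of [Topology-class] objects with elements `T1`,
#'   `T2`, `S`, `Sprime`.
#' @examples
#' topologyNewick(namedTopologies()$S)
#' @export
namedTopologies <- function() {
  taxa <- c("A", "B", "C", "D", "E")
  list(T1     = topology(list(c("B", "C"), c("D", "E")), taxa),
       T2     = topology(list(c("A", "B"), c("C", "D")), taxa),
       S      = topology(list(c("A", "E"), c("C", "D")), taxa),
       Sprime = topology(list(c("A", "E"), c("B", "C")), taxa))
}

# Quartet split names -------------------------------------------------------

#' Canonical quartet split names
#'
#' `quartetSplits()` returns the three resolved quartet topologies of one
#' 4-taxon set, in canonical order (for sorted taxa `w < x < y < z`:
#' `wx|yz`, `wy|xz`, `wz|xy`).  `allQuartetSplits()` concatenates the
#' splits of all five 4-taxon subsets of a 5-taxon set, in the row order
#' used by [QuartetTable-class].
#'
#' @param quartet character vector of 4 taxon labels.
#' @return Character vector of split strings such as `"AB|CD"`.
#' @examples
#' quartetSplits(c("A", "B", "C", "D"))
#' @export
quartetSplits <- function(quartet) {
  q <- sort(quartet)
  if (length(q) != 4 || anyDuplicated(q)) stop("need 4 distinct taxa")
  c(.splitString(q[c(1, 2)], q[c(3, 4)]),
    .splitString(q[c(1, 3)], q[c(2, 4)]),
    .splitString(q[c(1, 4)], q[c(2, 3)]))
}

#' @rdname quartetSplits
#' @param taxa character vector of 5 taxon labels.
#' @export
allQuartetSplits <- function(taxa) {
  taxa <- sort(taxa)
  if (length(taxa) != 5) stop("need 5 taxa")
  unlist(lapply(combn(taxa, 4, simplify = FALSE), quartetSplits))
}

#' Quartet splits induced by a 5-taxon topology
#'
#' Restricting an unrooted 5-taxon topology to each of its five 4-taxon
#' subsets yields one resolved quartet split per subset.
#'
#' @param t a 5-taxon [Topology-class] object.
#' @return Named character vector of 5 split strings, one per 4-taxon
#'   subset (names are the concatenated sorted subsets).
#' @examples
#' inducedQuartets(namedTopologies()$S)
#' @rdname inducedQuartets
#' @export
setMethod("inducedQuartets", "Topology", function(t) {
  if (length(t@taxa) != 5) stop("inducedQuartets requires a 5-taxon topology")
  quartets <- combn(t@taxa, 4, simplify = FALSE)
  out <- vapply(quartets, function(q) {
    for (s in t@sides) {
      if (all(s %in% q)) return(.splitString(s, setdiff(q, s)))
    }
    stop("internal error: no pair inside quartet")  # unreachable
  }, character(1))
  names(out) <- vapply(quartets, .sideString, character(1))
  out
})

#' Unrooted topology of a (rooted or unrooted) metric tree
#'
#' Extracts the canonical unrooted [Topology-class] of a `phylo` tree by
#' collecting its nontrivial splits.  The result is invariant under
#' re-rooting of the input.
#'
#' @param tree a `phylo` object with at least 4 tips, binary after
#'   unrooting.
#' @return A [Topology-class] object.
#' @examples
#' unrootedTopology(ape::read.tree(text = "(((A,E),B),(C,D));"))
#' @export
unrootedTopology <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 4) stop("at least 4 taxa are required")
  taxa <- sort(tree$tip.label)
  sides <- .treeSplits(tree)$side
  if (length(sides) != n - 3L)
    stop("tree is not binary after unrooting")
  topology(sides, taxa)
}

# Internal: nontrivial splits of a metric tree with summed lengths.
#
# Returns list(side = list of minimal-side taxon vectors,
#              length = numeric vector).
# Edges mapping to the same unrooted split (e.g. the two edges incident to
# a degree-2 root) have their lengths summed exactly.
.treeSplits <- function(tree) {
  n <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  phy <- ape::reorder.phylo(tree, "postorder")
  nNode <- n + phy$Nnode
  claden <- vector("list", nNode)
  for (i in seq_len(n)) claden[[i]] <- match(phy$tip.label[i], taxa)
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    claden[[par]] <- c(claden[[par]], claden[[ch]])
  }
  el <- phy$edge.length
  if (is.null(el)) el <- rep(0, nrow(phy$edge))
  sides <- list(); keys <- character(0); len <- numeric(0)
  for (k in seq_len(nrow(phy$edge))) {
    tipsBelow <- claden[[phy$edge[k, 2]]]
    sz <- length(tipsBelow)
    if (sz >= 2 && sz <= n - 2) {
      s <- .minimalSide(taxa[tipsBelow], taxa)
      key <- paste(s, collapse = "\r")
      hit <- match(key, keys)
      if (is.na(hit)) {
        sides[[length(sides) + 1L]] <- s
        keys <- c(keys, key)
        len <- c(len, el[k])
      } else {
        len[hit] <- len[hit] + el[k]
      }
    }
  }
  list(side = sides, length = len)
}
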