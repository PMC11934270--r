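setMethod("show", "HybridNetwork", function(object) {
  cat("HybridNetwork on {", paste(object@taxa, collapse = ","), "}\n",
      sep = "")
  hyb <- object@edges[!is.na(object@edges$gamma), ]
  cat("  hybrid node:", object@hybrid, "with inheritance weights",
      paste(sprintf("%.4g", hyb$gamma), collapse = " / "), "\n")
  cat(" ", object@newick, "\n")
})

# Internal: drop one hybrid edge, suppress degree-2 nodes (summing branch
# lengths exactly) and return the remaining rooted tree as a phylo.
.displayedTree <- function(net, dropRow) {
  ed <- net@edges[-dropRow, c("parent", "child", "length")]
  root <- net@root
  repeat {
    tab <- table(ed$parent)
    childCount <- as.integer(tab[match(ed$parent, names(tab))])
    # nodes with exactly one child and a parent edge -> splice out
    single <- names(tab)[tab == 1]
    single <- setdiff(single, net@taxa)
    spliced <- FALSE
    for (v in single) {
      up <- which(ed$child == v)
      dn <- which(ed$parent == v)
      if (length(up) == 1 && length(dn) == 1) {
        ed$length[dn] <- ed$length[dn] + ed$length[up]
        ed$parent[dn] <- ed$parent[up]
        ed <- ed[-up, ]
        spliced <- TRUE
        break
      }
    }
    if (spliced) next
    # root left with a single child: promote the child (drop the edge)
    dn <- which(ed$parent == root)
    if (length(dn) == 1) {
      root <- ed$child[dn]
      ed <- ed[-dn, ]
      next
    }
    break
  }
  ape::read.tree(text = .edgesToNewick(ed, root))
}

#' Displayed trees of a single-hybrid network
#'
#' Removing one of the two hybrid edges and suppressing the resulting
#' degree-2 nodes (adjacent branch lengths are summed exactly) yields a
#' rooted displayed tree.  Each tree is returned with the inheritance
#' weight of the hybrid edge it *retains*; the two weights sum to 1.  The
#' order follows the order of the hybrid edges in the extended-Newick
#' string.
#'
#' @param net a [HybridNetwork-class] object.
#' @return A list of two `list(tree = <phylo>, weight = <numeric>)` pairs.
#' @examples
#' net <- buildRootedNetwork(cycleParams(2, 0.2, 1.1, 0.5))
#' lapply(displayedTrees(net), function(d) ape::write.tree(d$tree))
#' @rdname displayedTrees
#' @export
setMethod("displayedTrees", "HybridNetwork", function(net) {
  hybRows <- which(!is.na(net@edges$gamma))
  lapply(hybRows, function(keep) {
    drop <- setdiff(hybRows, keep)
    list(tree = .displayedTree(net, drop),
         weight = net@edges$gamma[keep])
  })
})

# Internal: number of taxa descending from the hybrid node through tree
# (non-hybrid) edges; the displayed-tree mixture simulation shortcut is
# only valid when this is 1.
.hybridLeafCount <- function(net) {
  ed <- net@edges[is.na(net@edges$gamma), ]
  count <- 0L
  stack <- net@hybrid
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- ed$child[ed$parent == v]
    if (!length(kids) && v %in% net@taxa) count <- count + 1L
    stack <- c(stack, kids)
  }
  count
}

#' Build the canonical rooted 5-cycle network for simulation
#'
#' Constructs a rooted single-hybrid network whose unrooted (semidirected)
#' form is the canonical 5-cycle on taxa A--E with internal edge lengths
#' `e2`, `e3`, `e4` and hybridization parameter `gamma`: the hybrid node
#' sits above taxon C, the root at the midpoint of the `e3` edge, and all
#' pendant and hybrid edges default to length 1.  With
#' `cycleParams(2, 0.2, 1.1, 0.5)` this reproduces, node for node, the
#' reference network
#' `((((C:1)#H1:1::0.5,B:1)G:1.1,A:1)F:0.1,((#H1:1::0.5,D:1)J:2,E:1)K:0.1)r;`.
#'
#' Quartet gene-tree probabilities are independent of the root placement,
#' so the particular rooting affects only the simulated rooted gene trees,
#' not any unrooted summary computed from them.
#'
#' @param p a [CycleNetworkParams-class] object.
#' @param pendantLength length of the five pendant edges (default 1).
#' @param hybridLength length of the two hybrid edges (default 1).
#' @return A [HybridNetwork-class] object.
#' @examples
#' buildRootedNetwork(cycleParams(2, 0.2, 1.1, 0.5))
#' @export
buildRootedNetwork <- function(p, pendantLength = 1, hybridLength = 1) {
  stopifnot(is(p, "CycleNetworkParams"))
  validObject(p)
  if (pendantLength <= 0 || hybridLength <= 0)
    stop("pendant and hybrid edge lengths must be positive")
  f <- function(x) sprintf("%.15g", x)
  txt <- sprintf(
    "((((C:%s)#H1:%s::%s,B:%s)G:%s,A:%s)F:%s,((#H1:%s::%s,D:%s)J:%s,E:%s)K:%s)r;",
    f(pendantLength), f(hybridLength), f(p@gamma), f(pendantLength),
    f(p@e4), f(pendantLength), f(p@e3 / 2),
    f(hybridLength), f(1 - p@gamma), f(pendantLength),
    f(p@e2), f(pendantLength), f(p@e3 / 2))
  # Edge table built directly (equal to parseExtendedNewick(txt); the
  # string is kept as the network's record).  The gamma-weighted hybrid
  # edge comes first so displayed-tree order matches the string.
  pl <- pendantLength; hl <- hybridLength
  edges <- data.frame(
    parent = c("r", "r", "F", "F", "G",     "G", "K", "K", "J",         "J", "H1"),
    child  = c("F", "K", "G", "A", "H1",    "B", "J", "E", "H1",        "D", "C"),
    length = c(p@e3 / 2, p@e3 / 2, p@e4, pl, hl, pl, p@e2, pl, hl,      pl, pl),
    gamma  = c(NA, NA, NA, NA, p@gamma,     NA, NA, NA, 1 - p@gamma,    NA, NA),
    stringsAsFactors = FALSE)
  new("HybridNetwork", taxa = c("A", "B", "C", "D", "E"), edges = edges,
      root = "r", hybrid = "H1", newick = txt)
}
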