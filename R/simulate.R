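# Coalescent gene-tree simulation ------------------------------------------

# Internal: preprocess a rooted metric phylo into the post-order tables
# consumed by the C++ simulator.  Leaf ids follow the sorted taxon order
# (bit i of a clade mask corresponds to sort(tip.label)[i + 1]).
.speciesTreeTables <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  n <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  phy <- ape::reorder.phylo(tree, "postorder")
  rootNum <- n + 1L
  # map phylo node numbers -> simulator ids
  idOf <- integer(n + phy$Nnode)
  idOf[seq_len(n)] <- match(phy$tip.label, taxa) - 1L
  internalOrder <- unique(phy$edge[, 1])      # postorder parents, root last
  idOf[internalOrder] <- n + seq_along(internalOrder) - 1L
  children <- vector("list", phy$Nnode)
  blen <- numeric(phy$Nnode)
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    j <- idOf[par] - n + 1L
    children[[j]] <- c(children[[j]], idOf[ch])
    if (ch > n) blen[idOf[ch] - n + 1L] <- phy$edge.length[k]
  }
  blen[idOf[rootNum] - n + 1L] <- Inf
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth) - depth
  nodeAge <- numeric(phy$Nnode)
  nodeAge[idOf[internalOrder] - n + 1L] <- age[internalOrder]
  leafAge <- age[seq_len(n)][order(idOf[seq_len(n)])]
  list(n = n, taxa = taxa, children = children, blen = blen,
       nodeAge = nodeAge, leafAge = leafAge)
}

# Internal: popcount lookup for 5-bit masks.
.popcount5 <- local({
  pc <- integer(32)
  for (m in 1:31) pc[m + 1] <- sum(bitwAnd(m, 2^(0:4)) > 0)
  pc
})

# Internal: topology ids of the 15 five-taxon topologies as mask-pair
# codes, aligned with .enumTopo(taxa) order.
.topoMaskCodes <- function(taxa) {
  sideMask <- function(s) sum(2^(match(s, taxa) - 1))
  vapply(.enumTopo(taxa), function(t) {
    ms <- sort(vapply(t@sides, sideMask, numeric(1)))
    ms[1] * 32 + ms[2]
  }, numeric(1))
}

# Internal: unrooted topology codes from clade-mask matrices.
.topologyCodes <- function(masks, taxa) {
  n <- length(taxa)
  pc <- .popcount5[masks + 1L]
  dim(pc) <- dim(masks)
  if (n == 5) {
    side <- ifelse(pc == 2, masks, ifelse(pc == 3, 31L - masks, NA_integer_))
    lo <- do.call(pmin, c(lapply(seq_len(ncol(side)), function(j) side[, j]),
                          list(na.rm = TRUE)))
    hi <- do.call(pmax, c(lapply(seq_len(ncol(side)), function(j) side[, j]),
                          list(na.rm = TRUE)))
    codes <- match(lo * 32 + hi, .topoMaskCodes(taxa))
    levels <- vapply(.enumTopo(taxa), topologyId, character(1))
  } else if (n == 4) {
    side <- ifelse(pc == 2, pmin(masks, 15L - masks), NA_integer_)
    lo <- do.call(pmin, c(lapply(seq_len(ncol(side)), function(j) side[, j]),
                          list(na.rm = TRUE)))
    keys <- c(3L, 5L, 6L)   # {t1,t2}, {t1,t3}, {t1,t4} as minimal sides
    codes <- match(lo, keys)
    levels <- quartetSplits(taxa)
  } else {
    stop("topology coding supports 4 or 5 taxa")
  }
  if (anyNA(codes)) stop("internal error: unresolved gene tree")
  list(codes = as.integer(codes), levels = levels)
}

# Internal: rebuild metric gene trees (phylo) from clade masks and event
# ages for one species tree.
.masksToTrees <- function(masks, times, taxa, leafAge) {
  n <- length(taxa)
  lapply(seq_len(nrow(masks)), function(g) {
    lab <- taxa
    age <- leafAge
    mask <- as.integer(2^(seq_len(n) - 1))
    txt <- taxa
    for (j in seq_len(ncol(masks))) {
      mg <- masks[g, j]
      hit <- which(bitwAnd(mask, mg) == mask & mask != 0L)
      stopifnot(length(hit) == 2)
      tm <- times[g, j]
      newTxt <- sprintf("(%s:%.12g,%s:%.12g)", txt[hit[1]], tm - age[hit[1]],
                        txt[hit[2]], tm - age[hit[2]])
      mask[hit[1]] <- mg; txt[hit[1]] <- newTxt; age[hit[1]] <- tm
      mask <- mask[-hit[2]]; txt <- txt[-hit[2]]; age <- age[-hit[2]]
    }
    ape::read.tree(text = paste0(txt, ";"))
  })
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Simulates `m` i.i.d. gene trees on a rooted metric species tree with
#' one sampled lineage per taxon: within each branch, `k` lineages
#' coalesce at rate `k(k-1)/2` per coalescent unit; lineages that fail to
#' coalesce pass rootward, and coalescence above the root continues until
#' one lineage remains.  Pendant branch lengths never matter (a single
#' lineage cannot coalesce).  The simulation core is compiled and uses
#' R's RNG, so results are reproducible under `set.seed()` / `seed`.
#'
#' @param tree a rooted metric `phylo` on 4 or 5 taxa.
#' @param m number of gene trees (`>= 1`).
#' @param seed optional integer seed.
#' @param retainTrees also keep the full metric gene trees (as `phylo`
#'   objects)?  Off by default; intended for small `m`.
#' @return A [GeneTreeSample-class] of unrooted gene-tree topologies.
#' @examples
#' tr <- parseNewick("((A:1,B:1):0.2,(C:1,D:1):0.2);")
#' g <- simulateMSC(tr, 1000, seed = 1)
#' topologyFrequencies(g)
#' @export
simulateMSC <- function(tree, m, seed = NULL, retainTrees = FALSE) {
  if (m < 1) stop("m must be >= 1")
  st <- .speciesTreeTables(tree)
  if (!is.null(seed)) set.seed(seed)
  sim <- .simCoalescentClades(st$n, st$children, st$blen, st$nodeAge,
                              as.integer(m))
  tc <- .topologyCodes(sim$masks, st$taxa)
  new("GeneTreeSample", taxa = st$taxa, codes = tc$codes,
      levels = tc$levels,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      source = sprintf("MSC on %s", ape::write.tree(tree)),
      trees = if (retainTrees)
        .masksToTrees(sim$masks, sim$times, st$taxa, st$leafAge)
      else list())
}

#' Simulate gene trees under the NMSC on a single-cycle network
#'
#' For a single-hybrid network whose hybrid node subtends exactly one
#' taxon, the NMSC gene-tree distribution is exactly the mixture of the
#' MSC distributions on the two displayed trees, weighted by the
#' inheritance weights: only one lineage ever enters a hybrid edge, so
#' choosing a parental population per gene (tree-level mixing) is
#' equivalent to lineage-level tracing.  Each gene independently picks a
#' displayed tree with its weight and is then simulated with
#' [simulateMSC()]'s core.
#'
#' @param net a [HybridNetwork-class] whose hybrid node has exactly one
#'   descendant taxon (otherwise an error: the mixture shortcut would be
#'   invalid).
#' @param m number of gene trees (`>= 1`).
#' @param seed optional integer seed.
#' @param retainTrees keep full metric gene trees?
#' @return A [GeneTreeSample-class].
#' @examples
#' net <- buildRootedNetwork(cycleParams(2, 0.2, 1.1, 0.5))
#' g <- simulateNMSCCycle(net, 2000, seed = 1)
#' head(topologyFrequencies(g))
#' @export
simulateNMSCCycle <- function(net, m, seed = NULL, retainTrees = FALSE) {
  stopifnot(is(net, "HybridNetwork"))
  if (m < 1) stop("m must be >= 1")
  if (.hybridLeafCount(net) != 1)
    stop("the hybrid node must subtend exactly one taxon for the ",
         "displayed-tree mixture simulation to be exact")
  d <- displayedTrees(net)
  st <- lapply(d, function(x) .speciesTreeTables(x$tree))
  if (!identical(st[[1]]$taxa, st[[2]]$taxa))
    stop("displayed trees disagree on taxa")
  taxa <- st[[1]]$taxa
  if (!is.null(seed)) set.seed(seed)
  comp <- runif(m) < d[[1]]$weight
  counts <- c(sum(comp), m - sum(comp))
  codes <- integer(m)
  trees <- if (retainTrees) vector("list", m) else list()
  levels <- NULL
  for (k in 1:2) {
    if (counts[k] == 0) next
    sim <- .simCoalescentClades(st[[k]]$n, st[[k]]$children, st[[k]]$blen,
                                st[[k]]$nodeAge, counts[k])
    tc <- .topologyCodes(sim$masks, taxa)
    levels <- tc$levels
    sel <- if (k == 1) comp else !comp
    codes[sel] <- tc$codes
    if (retainTrees)
      trees[sel] <- .masksToTrees(sim$masks, sim$times, taxa,
                                  st[[k]]$leafAge)
  }
  new("GeneTreeSample", taxa = taxa, codes = codes, levels = levels,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      source = sprintf("NMSC mixture on %s", net@newick),
      trees = trees)
}

#' Topology frequencies of a gene-tree sample
#'
#' Relative frequencies of the unrooted topologies in the sample (all 15
#' for 5 taxa), by default sorted in decreasing order and named by the
#' canonical Newick strings.  Frequencies are exact rational counts over
#' the sample size and sum to 1.
#'
#' @param g a [GeneTreeSample-class].
#' @param sort sort decreasingly? (default `TRUE`)
#' @param ... unused.
#' @return Named numeric vector.
#' @rdname topologyFrequencies
#' @export
setMethod("topologyFrequencies", "GeneTreeSample",
          function(g, sort = TRUE, ...) {
  freq <- tabulate(g@codes, nbins = length(g@levels)) / length(g@codes)
  nm <- if (length(g@taxa) == 5) {
    vapply(.enumTopo(g@taxa), topologyNewick, character(1))
  } else {
    g@levels
  }
  names(freq) <- nm
  if (sort) freq <- base::sort(freq, decreasing = TRUE)
  freq
})

#' Accessors for gene-tree samples
#'
#' `sampleSize()` returns the number of gene trees; `topologyCodes()`
#' returns the integer topology codes (indexes into the sample's
#' topology levels).
#'
#' @param g a [GeneTreeSample-class].
#' @return An integer (count) or integer vector (codes).
#' @rdname GeneTreeSample-accessors
#' @export
setMethod("sampleSize", "GeneTreeSample", function(g) length(g@codes))

#' @rdname GeneTreeSample-accessors
#' @export
setMethod("topologyCodes", "GeneTreeSample", function(g) g@codes)

setMethod("show", "GeneTreeSample", function(object) {
  cat(sprintf("GeneTreeSample: %d gene trees on {%s}\n",
              length(object@codes), paste(object@taxa, collapse = ",")))
  cat("  source:", object@source, "\n")
  if (!is.na(object@seed)) cat("  seed:", object@seed, "\n")
  tf <- topologyFrequencies(object)
  top <- utils::head(tf[tf > 0], 4)
  cat("  top topologies:",
      paste(sprintf("%s %.4f", names(top), top), collapse = ", "), "\n")
})

#' Write a gene-tree sample as Newick, one per line
#'
#' Writes the retained metric gene trees when available, otherwise the
#' canonical (branch-length-free) Newick of each gene's unrooted
#' topology.
#'
#' @param g a [GeneTreeSample-class].
#' @param file output path.
#' @export
writeGeneTrees <- function(g, file) {
  if (length(g@trees)) {
    writeNewick(g@trees, file)
  } else {
    nwk <- vapply(.enumTopo(g@taxa), topologyNewick, character(1))
    writeLines(nwk[g@codes], file)
  }
  invisible(file)
}
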