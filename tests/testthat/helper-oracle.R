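# Exact multispecies-coalescent topology distribution on a rooted metric
# 5-taxon species tree, by exhaustive enumeration of coalescent histories.
#
# Independent of the package's simulator: branch-wise lineage-count
# transition probabilities g_{k->j}(L) come from the matrix exponential of
# the pure-death coalescent chain (rate k(k-1)/2), and every ordered merge
# sequence within a branch is enumerated with its exact probability
# (uniform pair choice at each event).  Used as the simulator's oracle.

# P[k lineages -> j lineages after time L]
.oracleReduceProbs <- function(k, L) {
  if (k == 1) return(1)
  if (!is.finite(L)) return(c(1, numeric(k - 1)))
  Q <- matrix(0, k, k)
  for (i in 2:k) {
    r <- i * (i - 1) / 2
    Q[i, i] <- -r
    Q[i, i - 1] <- r
  }
  as.numeric(Matrix::expm(Q * L)[k, ])   # index j = lineages remaining
}

.oraclePopcount <- function(m) sum(bitwAnd(m, 2^(0:4)) > 0)

# A "state" is the multiset of lineage clade masks plus the set of
# nontrivial 2-sides recorded so far; distributions over states are kept
# as named lists  key -> list(masks, sides, p).
.oracleKey <- function(masks, sides) {
  paste(c(sort(masks), "|", sort(sides)), collapse = ",")
}

.oracleAdd <- function(dist, masks, sides, p) {
  key <- .oracleKey(masks, sides)
  if (is.null(dist[[key]])) {
    dist[[key]] <- list(masks = masks, sides = sides, p = p)
  } else {
    dist[[key]]$p <- dist[[key]]$p + p
  }
  dist
}

# Evolve one state through a branch of length L (Inf for the root branch).
.oracleEvolve <- function(dist, masks, sides, p0, L) {
  k0 <- length(masks)
  gk <- .oracleReduceProbs(k0, L)
  rec <- function(masks, sides, pseq) {
    j <- length(masks)
    if (gk[j] > 0)
      dist <<- .oracleAdd(dist, masks, sides, p0 * gk[j] * pseq)
    if (j == 1) return(invisible())
    npairs <- j * (j - 1) / 2
    for (a in 1:(j - 1)) {
      for (b in (a + 1):j) {
        mg <- bitwOr(masks[a], masks[b])
        ns <- sides
        pc <- .oraclePopcount(mg)
        if (pc == 2) ns <- union(ns, mg)
        if (pc == 3) ns <- union(ns, 31L - mg)
        rec(c(masks[-c(a, b)], mg), ns, pseq / npairs)
      }
    }
  }
  rec(masks, sides, 1)
  dist
}

# Cross-product of independent child state distributions.
.oracleCombine <- function(distA, distB) {
  out <- list()
  for (sa in distA) {
    for (sb in distB) {
      out <- .oracleAdd(out, c(sa$masks, sb$masks),
                        union(sa$sides, sb$sides), sa$p * sb$p)
    }
  }
  out
}

# Exact distribution over the 15 unrooted topologies (named vector in the
# order of enumerateTopologies(sorted taxa)).
oracleTopologyDist <- function(tree) {
  n <- length(tree$tip.label)
  stopifnot(n == 5)
  taxa <- sort(tree$tip.label)
  phy <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(phy$edge[, 1])          # postorder, root last
  exitDist <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) {
    mask <- as.integer(2^(match(phy$tip.label[i], taxa) - 1))
    exitDist[[i]] <- .oracleAdd(list(), mask, integer(0), 1)
  }
  el <- phy$edge.length
  for (v in parents) {
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    entry <- exitDist[[kids[1]]]
    for (k in kids[-1]) entry <- .oracleCombine(entry, exitDist[[k]])
    isRoot <- (v == parents[length(parents)])
    L <- if (isRoot) Inf else el[which(phy$edge[, 2] == v)]
    out <- list()
    for (s in entry) out <- .oracleEvolve(out, s$masks, s$sides, s$p, L)
    exitDist[[v]] <- out
  }
  final <- exitDist[[parents[length(parents)]]]
  topos <- enumerateTopologies(taxa)
  sideMask <- function(s) sum(2^(match(s, taxa) - 1))
  codes <- vapply(topos, function(t) {
    ms <- sort(vapply(t@sides, sideMask, numeric(1)))
    ms[1] * 32 + ms[2]
  }, numeric(1))
  probs <- setNames(numeric(length(topos)),
                    vapply(topos, topologyId, character(1)))
  for (s in final) {
    stopifnot(length(s$masks) == 1, length(s$sides) == 2)
    sd <- sort(s$sides)
    probs[match(sd[1] * 32 + sd[2], codes)] <-
      probs[match(sd[1] * 32 + sd[2], codes)] + s$p
  }
  probs
}

# Quartet marginals of a 15-topology distribution (named by the canonical
# quartet splits), via the splits each topology induces.
oracleQuartetMarginals <- function(topoDist, taxa = LETTERS[1:5]) {
  topos <- enumerateTopologies(taxa)
  ids <- vapply(topos, topologyId, character(1))
  out <- setNames(numeric(15), allQuartetSplits(taxa))
  for (i in seq_along(topos)) {
    out[inducedQuartets(topos[[i]])] <-
      out[inducedQuartets(topos[[i]])] + topoDist[[ids[i]]]
  }
  out
}
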