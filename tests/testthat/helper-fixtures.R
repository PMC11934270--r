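# Shared fixtures: the reference 5-cycle network and small utilities.

refParams <- function() cycleParams(2, 0.2, 1.1, 0.5)

refNetworkString <- function() {
  "((((C:1)#H1:1::0.5,B:1)G:1.1,A:1)F:0.1,((#H1:1::0.5,D:1)J:2,E:1)K:0.1)r;"
}

# Random parameters drawn as in the Theta scans: e_i ~ Exp(1), gamma ~ U(0,1).
randomParams <- function() {
  cycleParams(-log(runif(1)), -log(runif(1)), -log(runif(1)), runif(1))
}

binomSE <- function(p, n) sqrt(p * (1 - p) / n)

# Canonical Newick of the four named topologies, for frequency lookups.
refTopoNewick <- function() {
  vapply(namedTopologies(), topologyNewick, character(1))
}

# Relabel a 5-taxon topology by a named label map (e.g. c(B = "D", D = "B")).
relabelTopology <- function(t, map) {
  swap <- function(x) ifelse(x %in% names(map), map[x], x)
  topology(lapply(t@sides, swap), swap(t@taxa))
}
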