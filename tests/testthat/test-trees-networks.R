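test_that("parseNewick handles minimal trees and round-trips random trees", {
  tr <- parseNewick("((A:1,B:1):1,C:1);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1))

  set.seed(42)
  for (i in 1:100) {
    tr <- ape::rtree(5)
    tr$tip.label <- sample(LETTERS[1:5])
    x <- writeNewick(tr)
    expect_identical(writeNewick(parseNewick(x)), x)
  }
})

test_that("malformed Newick raises position-reporting errors", {
  expect_error(parseNewick("((A:1,B);"), "position 9")
  expect_error(parseNewick("(A:1,B:1)"), "expected ';'")
  expect_error(parseNewick("(A:1,:2);"), "position")
  expect_error(parseNewick("((A:1,B:1);"), "position")
  expect_error(parseNewick("(C:1)#H1;"), "parseExtendedNewick")
})

test_that("parseExtendedNewick reads the reference network", {
  net <- parseExtendedNewick(refNetworkString())
  expect_s4_class(net, "HybridNetwork")
  expect_identical(net@taxa, LETTERS[1:5])
  expect_identical(net@hybrid, "H1")
  hyb <- net@edges[!is.na(net@edges$gamma), ]
  expect_equal(sort(hyb$gamma), c(0.5, 0.5))
  gf <- net@edges[net@edges$parent == "F" & net@edges$child == "G", ]
  expect_equal(gf$length, 1.1)
})

test_that("extended-Newick validation catches bad hybrid specifications", {
  expect_error(parseExtendedNewick("((A:1,B:1):1,C:1);"), "no hybrid")
  lopsided <- sub("::0.5,B", "::0.3,B", refNetworkString())
  lopsided <- sub("::0.5,D", "::0.7,D", lopsided)
  net <- parseExtendedNewick(lopsided)
  expect_equal(sort(net@edges$gamma[!is.na(net@edges$gamma)]), c(0.3, 0.7))
  bad <- sub("::0.5,D", "::0.6,D", refNetworkString())
  expect_error(parseExtendedNewick(bad), "sum to 1")
  nogamma <- sub(":1::0.5,D", ":1,D", refNetworkString())
  expect_error(parseExtendedNewick(nogamma), "missing inheritance weight")
})

test_that("displayed trees of the reference network have the right shape,
          lengths and weights", {
  net <- parseExtendedNewick(refNetworkString())
  d <- displayedTrees(net)
  expect_length(d, 2)
  expect_equal(d[[1]]$weight + d[[2]]$weight, 1)
  nt <- namedTopologies()

  # G-side retained: (A,(B,C),(D,E)) with BC edge 1.1 and DE edge 0.1+0.1
  expect_true(unrootedTopology(d[[1]]$tree) == nt$T1)
  q <- quartetInternalLength(d[[1]]$tree, c("A", "B", "C", "D"))
  expect_identical(q$split, "AD|BC")
  expect_equal(q$length, 1.1)
  q <- quartetInternalLength(d[[1]]$tree, c("A", "B", "D", "E"))
  expect_identical(q$split, "AB|DE")
  expect_equal(q$length, 0.2)

  # J-side retained: ((A,B),(C,D),E) with CD edge 2.0 and AB edge 0.2
  expect_true(unrootedTopology(d[[2]]$tree) == nt$T2)
  q <- quartetInternalLength(d[[2]]$tree, c("B", "C", "D", "E"))
  expect_identical(q$split, "BE|CD")
  expect_equal(q$length, 2)
  q <- quartetInternalLength(d[[2]]$tree, c("A", "B", "C", "D"))
  expect_identical(q$split, "AB|CD")
  expect_equal(q$length, 2.2)
})

test_that("buildRootedNetwork reproduces the parsed reference network", {
  net <- buildRootedNetwork(refParams())
  ref <- parseExtendedNewick(refNetworkString())
  expect_identical(net@newick, refNetworkString())
  dn <- displayedTrees(net)
  dr <- displayedTrees(ref)
  for (k in 1:2) {
    expect_equal(dn[[k]]$weight, dr[[k]]$weight)
    expect_true(unrootedTopology(dn[[k]]$tree) ==
                  unrootedTopology(dr[[k]]$tree))
    for (q in combn(LETTERS[1:5], 4, simplify = FALSE)) {
      expect_equal(quartetInternalLength(dn[[k]]$tree, q),
                   quartetInternalLength(dr[[k]]$tree, q))
    }
  }
})

test_that("unrootedTopology is invariant under re-rooting", {
  r <- unrootedTopology(parseNewick("(((A,E),B),(C,D));"))
  expect_true(r == namedTopologies()$S)

  set.seed(7)
  for (i in 1:20) {
    tr <- ape::rtree(5)
    tr$tip.label <- sample(LETTERS[1:5])
    t0 <- unrootedTopology(tr)
    for (tip in tr$tip.label) {
      rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
      expect_true(unrootedTopology(rr) == t0)
    }
  }
  expect_false(namedTopologies()$T1 == namedTopologies()$T2)
  expect_error(unrootedTopology(parseNewick("(A:1,(B:1,C:1):1);")),
               "4 taxa")
})

test_that("enumerateTopologies yields 15 distinct topologies containing the
          named ones", {
  topos <- enumerateTopologies(LETTERS[1:5])
  expect_length(topos, 15)
  ids <- vapply(topos, topologyId, character(1))
  expect_false(anyDuplicated(ids) > 0)
  nt <- namedTopologies()
  for (t in nt) expect_true(topologyId(t) %in% ids)
  expect_error(enumerateTopologies(LETTERS[1:4]), "5 distinct")
})

test_that("induced quartet sets match the displayed-quartet algebra and are
          injective", {
  nt <- namedTopologies()
  expect_setequal(unname(inducedQuartets(nt$S)),
                  c("AB|CD", "AE|CD", "BE|CD", "AE|BC", "AE|BD"))
  expect_setequal(unname(inducedQuartets(nt$T1)),
                  c("AD|BC", "AC|DE", "BC|DE", "AE|BC", "AB|DE"))
  expect_setequal(unname(inducedQuartets(nt$T2)),
                  c("AB|CD", "AE|CD", "BE|CD", "AB|CE", "AB|DE"))
  topos <- enumerateTopologies(LETTERS[1:5])
  keys <- vapply(topos, function(t)
    paste(sort(inducedQuartets(t)), collapse = ";"), character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("quartetInternalLength validates its inputs", {
  tr <- parseNewick("(((A:1,B:1):0.2,C:2):1,D:3);")
  q <- quartetInternalLength(tr, c("A", "B", "C", "D"))
  expect_identical(q$split, "AB|CD")
  expect_equal(q$length, 0.2)
  expect_error(quartetInternalLength(tr, c("A", "B", "C", "E")),
               "not all present")
  expect_error(quartetInternalLength(tr, c("A", "B", "C")), "4 distinct")
})
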