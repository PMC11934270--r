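test_that("MSC quartet probabilities match the closed form", {
  expect_equal(unname(mscQuartetProbs(0)), rep(1 / 3, 3))
  expect_equal(unname(mscQuartetProbs(Inf)), c(1, 0, 0))
  p <- mscQuartetProbs(0.2)
  expect_lt(max(abs(p - c(0.454180, 0.272910, 0.272910))), 1e-6)
  expect_equal(sum(p), 1)
  expect_error(mscQuartetProbs(-0.1), "nonnegative")
})

test_that("4-cycle quartet probabilities follow the mixture closed forms", {
  # gamma = 0 degenerates to pure MSC on the AB|CD tree
  for (x in c(0.1, 1, 3)) {
    expect_equal(unname(fourCycleQuartetProbs(x, 0.7, 0)[c(1, 2, 3)]),
                 unname(mscQuartetProbs(x)[c(1, 2, 3)]))
  }
  # x = y, gamma = 1/2: the two displayed quartets tie
  p <- fourCycleQuartetProbs(0.8, 0.8, 0.5)
  expect_equal(p[["AB|CD"]], p[["AD|BC"]])
  # frozen spot value
  p <- fourCycleQuartetProbs(2.2, 1.1, 0.5)
  expect_lt(max(abs(p - c(0.518544, 0.073946, 0.407510))), 5e-7)
  expect_equal(sum(p), 1)
  # the non-displayed quartet is never the most probable
  set.seed(11)
  for (i in 1:200) {
    p <- fourCycleQuartetProbs(-log(runif(1)), -log(runif(1)), runif(1))
    expect_lte(p[["AC|BD"]], min(p[["AB|CD"]], p[["AD|BC"]]))
    expect_equal(sum(p), 1)
  }
  expect_error(fourCycleQuartetProbs(-1, 1, 0.5), "nonnegative")
  expect_error(fourCycleQuartetProbs(1, 1, 1.5), "gamma")
})

test_that("quartetGap equals the probability difference exactly", {
  expect_equal(quartetGap(1.3, 0.4, 0), 1 - exp(-1.3))
  expect_equal(quartetGap(0.8, 0.8, 0.5), 0)
  expect_lt(abs(quartetGap(2.2, 1.1, 0.5) - 0.111034), 5e-7)
  set.seed(12)
  for (i in 1:100) {
    x <- -log(runif(1)); y <- -log(runif(1)); g <- runif(1)
    p <- fourCycleQuartetProbs(x, y, g)
    expect_lt(abs(quartetGap(x, y, g) - (p[["AB|CD"]] - p[["AD|BC"]])),
              1e-12)
  }
})

test_that("quartetMixture agrees with the closed forms and degenerates
          correctly", {
  net <- buildRootedNetwork(refParams())
  d <- displayedTrees(net)
  # {A,B,C,D} is the 4-cycle subnetwork with x = e2+e3 = 2.2, y = e4 = 1.1
  mix <- quartetMixture(d, c("A", "B", "C", "D"))
  ref <- fourCycleQuartetProbs(2.2, 1.1, 0.5)
  expect_lt(max(abs(mix[names(ref)] - ref)), 1e-12)

  # weights (0, 1): pure MSC on the second displayed tree
  d0 <- list(list(tree = d[[1]]$tree, weight = 0),
             list(tree = d[[2]]$tree, weight = 1))
  mix0 <- quartetMixture(d0, c("A", "B", "C", "D"))
  msc <- mscQuartetProbs(quartetInternalLength(d[[2]]$tree,
                                               c("A", "B", "C", "D"))$length)
  expect_equal(unname(mix0[["AB|CD"]]), unname(msc[[1]]))

  # identical components: the mixture is a single MSC
  dSame <- list(list(tree = d[[1]]$tree, weight = 0.3),
                list(tree = d[[1]]$tree, weight = 0.7))
  expect_equal(quartetMixture(dSame, c("A", "C", "D", "E")),
               quartetMixture(list(list(tree = d[[1]]$tree, weight = 1)),
                              c("A", "C", "D", "E")))
  expect_error(quartetMixture(d0[1], c("A", "B", "C", "D")), "sum to 1")
})

test_that("the analytic table matches the hand-derived per-quartet
          reductions", {
  # Reductions from the displayed-tree algebra of the canonical 5-cycle:
  # {A,B,C,D}: 4-cycle with x = e2+e3, y = e4
  # {A,B,C,E}: displayed splits AB|CE (e3, w 1-g) vs AE|BC (e4, w g)
  # {A,B,D,E}: pure tree AB|DE with internal e3
  # {A,C,D,E}: displayed splits AE|CD (e2, w 1-g) vs AC|DE (e3, w g)
  # {B,C,D,E}: displayed splits BE|CD (e2, w 1-g) vs BC|DE (e3+e4, w g)
  set.seed(13)
  paramSets <- c(list(refParams()), replicate(40, randomParams()))
  for (p in paramSets) {
    qt <- fiveCycleQuartetTable(p)
    v <- paramVector(p); g <- v[["gamma"]]
    y <- yValues(p)
    mixRow <- function(lenMajor1, w1, split1, lenMajor2, split2, names) {
      p1 <- mscQuartetProbs(lenMajor1); p2 <- mscQuartetProbs(lenMajor2)
      out <- setNames(rep(w1 * p1[[2]] + (1 - w1) * p2[[2]], 3), names)
      out[split1] <- out[split1] + w1 * (p1[[1]] - p1[[2]])
      out[split2] <- out[split2] + (1 - w1) * (p2[[1]] - p2[[2]])
      out
    }
    abcd <- fourCycleQuartetProbs(v[["e2"]] + v[["e3"]], v[["e4"]], g)
    expect_lt(max(abs(quartetProbs(qt, "ABCD")[names(abcd)] - abcd)), 1e-12)

    abce <- mixRow(v[["e4"]], g, "AE|BC", v[["e3"]], "AB|CE",
                   quartetSplits(c("A", "B", "C", "E")))
    expect_lt(max(abs(quartetProbs(qt, "ABCE") - abce)), 1e-12)

    abde <- mscQuartetProbs(v[["e3"]])
    row <- quartetProbs(qt, "ABDE")
    expect_lt(abs(row[["AB|DE"]] - abde[[1]]), 1e-12)
    expect_lt(abs(row[["AD|BE"]] - row[["AE|BD"]]), 1e-12)

    acde <- quartetProbs(qt, "ACDE")
    expect_lt(abs((acde[["AE|CD"]] - acde[["AC|DE"]]) -
                    ((1 - g) * (1 - y[["y2"]]) - g * (1 - y[["y3"]]))),
              1e-12)

    bcde <- mixRow(v[["e2"]], 1 - g, "BE|CD", v[["e3"]] + v[["e4"]],
                   "BC|DE", quartetSplits(c("B", "C", "D", "E")))
    expect_lt(max(abs(quartetProbs(qt, "BCDE") - bcde)), 1e-12)
  }
})

test_that("every quartet row sums to one across random parameter draws", {
  set.seed(14)
  for (i in 1:150) {
    qt <- fiveCycleQuartetTable(randomParams())
    sums <- rowSums(matrix(qt@probs, nrow = 5, byrow = TRUE))
    expect_lt(max(abs(sums - 1)), 1e-12)
  }
})

test_that("gamma = 0 and gamma = 1 degenerate to pure MSC on one displayed
          tree", {
  p0 <- cycleParams(1.4, 0.3, 0.9, 0)
  qt0 <- fiveCycleQuartetTable(p0)
  d <- displayedTrees(buildRootedNetwork(p0))
  for (q in combn(LETTERS[1:5], 4, simplify = FALSE)) {
    ql <- quartetInternalLength(d[[2]]$tree, q)  # T2 side retained
    expect_lt(abs(quartetProbs(qt0, q)[[ql$split]] -
                    mscQuartetProbs(ql$length)[[1]]), 1e-12)
  }
  p1 <- cycleParams(1.4, 0.3, 0.9, 1)
  qt1 <- fiveCycleQuartetTable(p1)
  d1 <- displayedTrees(buildRootedNetwork(p1))
  for (q in combn(LETTERS[1:5], 4, simplify = FALSE)) {
    ql <- quartetInternalLength(d1[[1]]$tree, q)  # T1 side retained
    expect_lt(abs(quartetProbs(qt1, q)[[ql$split]] -
                    mscQuartetProbs(ql$length)[[1]]), 1e-12)
  }
})

test_that("displayed-split probabilities are nondecreasing in their own
          internal branch", {
  grid <- seq(0.05, 3, length.out = 15)
  # e3 drives the AB|DE probability of {A,B,D,E}
  probs <- vapply(grid, function(e3)
    quartetProbs(fiveCycleQuartetTable(cycleParams(1.5, e3, 0.8, 0.4)),
                 "ABDE")[["AB|DE"]], numeric(1))
  expect_true(all(diff(probs) >= 0))
  # e2 drives the AE|CD probability of {A,C,D,E}
  probs <- vapply(grid, function(e2)
    quartetProbs(fiveCycleQuartetTable(cycleParams(e2, 0.3, 0.8, 0.4)),
                 "ACDE")[["AE|CD"]], numeric(1))
  expect_true(all(diff(probs) >= 0))
})

test_that("quartet tables serialize as TSV", {
  qt <- fiveCycleQuartetTable(refParams())
  f <- tempfile(fileext = ".tsv")
  writeQuartetTable(qt, f)
  back <- read.delim(f)
  expect_identical(names(back), c("quartet", "split", "probability"))
  expect_equal(nrow(back), 15)
  expect_equal(back$probability, unname(qt@probs))
})
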