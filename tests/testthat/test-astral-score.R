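starTable <- function() {
  quartetTable(setNames(rep(1 / 3, 15), allQuartetSplits(LETTERS[1:5])))
}

test_that("expected scores, alpha* and the frozen reference differences", {
  qt <- starTable()
  topos <- enumerateTopologies(LETTERS[1:5])
  for (t in topos) expect_equal(expectedScore(t, qt), 5 / 3)
  expect_equal(alphaStar(qt), 5 / 3)

  nt <- namedTopologies()
  qtRef <- fiveCycleQuartetTable(refParams())
  dS <- expectedScore(nt$S, qtRef) - expectedScore(nt$T2, qtRef)
  expect_lt(abs(dS - 0.061661), 5e-7)
  expect_error(expectedScore(nt$S, quartetTable(
    setNames(rep(1 / 3, 15), allQuartetSplits(c("A", "B", "C", "D", "Z"))),
    taxa = c("A", "B", "C", "D", "Z"))), "different taxa")
})

test_that("summed scores match the proof identities on random draws", {
  set.seed(21)
  nt <- namedTopologies()
  for (i in 1:100) {
    p <- randomParams()
    v <- paramVector(p); g <- v[["gamma"]]; y <- yValues(p)
    qt <- fiveCycleQuartetTable(p)
    a <- alphaStar(qt)
    # definitional bound over all 15 topologies
    expect_lt(max(bestTree(qt)@scores), a + 1e-12)
    # A(T2) and A(S) by direct summation vs the per-quartet differences:
    # alpha* - A(T2) = P(AE|BC) - P(AB|CE); alpha* - A(S) = P(AB|DE) - P(AE|BD)
    abce <- quartetProbs(qt, "ABCE")
    abde <- quartetProbs(qt, "ABDE")
    dT2 <- abce[["AE|BC"]] - abce[["AB|CE"]]
    dSd <- abde[["AB|DE"]] - abde[["AE|BD"]]
    expect_lt(abs(dT2 - (g * (1 - y[["y4"]]) - (1 - g) * (1 - y[["y3"]]))),
              1e-12)
    expect_lt(abs(dSd - (1 - y[["y3"]])), 1e-12)
    # A(T1) by independent per-quartet summation from the closed forms
    abcd <- fourCycleQuartetProbs(v[["e2"]] + v[["e3"]], v[["e4"]], g)
    acde <- quartetProbs(qt, "ACDE")
    bcde <- quartetProbs(qt, "BCDE")
    aT1 <- abcd[["AD|BC"]] + acde[["AC|DE"]] + bcde[["BC|DE"]] +
      abce[["AE|BC"]] + abde[["AB|DE"]]
    expect_lt(abs(expectedScore(nt$T1, qt) - aT1), 1e-12)
  }
})

test_that("the exact maximizer is consistent under the MSC and misled on
          the reference network", {
  nt <- namedTopologies()
  # pure MSC on T2 (gamma = 0): unique best tree is T2
  rep0 <- bestTree(fiveCycleQuartetTable(cycleParams(1.5, 0.4, 0.9, 0)))
  expect_identical(rep0@best, topologyId(nt$T2))
  # reference parameters: best is S, not T1/T2
  repRef <- bestTree(fiveCycleQuartetTable(refParams()))
  expect_identical(repRef@best, topologyId(nt$S))
  expect_true(bestTopology(repRef) == nt$S)
  expect_false(isDisplayed(bestTopology(repRef), refParams()))
  # Corollary-2 region: S' outscores both displayed trees
  pm <- mirrorParams(refParams())
  qtm <- fiveCycleQuartetTable(pm)
  expect_gt(expectedScore(nt$Sprime, qtm), expectedScore(nt$T1, qtm))
  expect_gt(expectedScore(nt$Sprime, qtm), expectedScore(nt$T2, qtm))
})

test_that("ties are detected and reported", {
  expect_warning(rep <- bestTree(starTable()), "tie")
  expect_length(rep@best, 15)
  expect_equal(unname(rep@scores[rep@best[1]]), 5 / 3)
})

test_that("empirical quartet tables behave on degenerate and large
          samples", {
  nt <- namedTopologies()
  # all-identical T1 gene trees via a no-ILS species tree
  tr <- parseNewick("((A:1,(B:1,C:1):50):50,(D:1,E:1):50);")
  g <- simulateMSC(tr, 50, seed = 3)
  qt <- empiricalQuartetTable(g)
  for (s in inducedQuartets(nt$T1)) expect_equal(qt@probs[[s]], 1)
  expect_true(bestTopology(inferTree(g)) == nt$T1)

  # m = 1: each quartet row is a unit vector
  g1 <- simulateMSC(tr, 1, seed = 4)
  qt1 <- empiricalQuartetTable(g1)
  expect_true(all(qt1@probs %in% c(0, 1)))

  # law of large numbers against the analytic table
  p <- refParams()
  big <- simulateNMSCCycle(buildRootedNetwork(p), 1e5, seed = 5)
  emp <- empiricalQuartetTable(big)
  ana <- fiveCycleQuartetTable(p)
  se <- binomSE(ana@probs, 1e5)
  expect_true(all(abs(emp@probs - ana@probs) <= 3 * se + 1e-9))
  # expected score of any topology is the large-sample limit of the
  # empirical score
  for (t in namedTopologies()) {
    expect_lt(abs(expectedScore(t, emp) - expectedScore(t, ana)),
              3 * sqrt(sum(se^2)))
  }
})

test_that("mirror symmetry maps scores through the cycle reflection", {
  # the 5-cycle's reflection swaps both arm pairs: A<->E together with
  # B<->D (on parameters: e2<->e4, gamma<->1-gamma); it carries S to S'
  set.seed(22)
  nt <- namedTopologies()
  map <- c(A = "E", E = "A", B = "D", D = "B")
  expect_true(relabelTopology(nt$S, map) == nt$Sprime)
  for (i in 1:30) {
    p <- randomParams()
    qt <- fiveCycleQuartetTable(p)
    qtm <- fiveCycleQuartetTable(mirrorParams(p))
    expect_lt(abs(expectedScore(nt$S, qt) -
                    expectedScore(nt$Sprime, qtm)), 1e-12)
    for (t in enumerateTopologies(LETTERS[1:5])) {
      expect_lt(abs(expectedScore(t, qt) -
                      expectedScore(relabelTopology(t, map), qtm)), 1e-12)
    }
  }
})

test_that("isDisplayed recognizes exactly the displayed topologies", {
  p <- refParams()
  nt <- namedTopologies()
  expect_true(isDisplayed(nt$T1, p))
  expect_true(isDisplayed(nt$T2, p))
  expect_false(isDisplayed(nt$S, p))
  expect_false(isDisplayed(nt$Sprime, p))
  expect_equal(sum(vapply(enumerateTopologies(LETTERS[1:5]), isDisplayed,
                          logical(1), p = p)), 2)
})

test_that("score reports serialize as TSV", {
  repRef <- bestTree(fiveCycleQuartetTable(refParams()))
  f <- tempfile(fileext = ".tsv")
  writeScoreReport(repRef, f, params = refParams())
  back <- read.delim(f)
  expect_identical(names(back),
                   c("topology", "score", "is_displayed", "is_best"))
  expect_equal(nrow(back), 15)
  expect_equal(sum(back$is_best), 1)
  expect_equal(sum(back$is_displayed), 2)
  expect_identical(back$topology[back$is_best],
                   topologyNewick(namedTopologies()$S))
})
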