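# End-to-end experiment drivers --------------------------------------------

.pkgVersionString <- function() {
  as.character(utils::packageVersion("quartetNMSC"))
}

#' Simulate a large gene-tree sample from the reference network and infer
#'
#' Builds the reference rooted 5-cycle network (parameters
#' `e2 = 2, e3 = 0.2, e4 = 1.1, gamma = 0.5`, all other edges 1),
#' simulates `m` gene trees under the NMSC mixture, tabulates the 15
#' unrooted topology frequencies, and runs the exact quartet-score
#' maximizer on the sample.  At these parameters the two displayed trees
#' are the two most frequent gene-tree topologies (so the network is far
#' from anomalous), yet the maximizer returns the non-displayed tree
#' `S = (((A,E),B),C,D)`.
#'
#' @param seed optional integer seed.
#' @param m number of gene trees (default 100,000).
#' @return A list with elements `config`, `frequencies` (named, sorted
#'   decreasingly), `report` (the [ScoreReport-class]), `inferred`
#'   (canonical Newick of the representative best topology) and
#'   `isDisplayed`.
#' @examples
#' res <- reproduceT100K(seed = 1, m = 2000)
#' res$inferred
#' @export
reproduceT100K <- function(seed = NULL, m = 100000) {
  p <- cycleParams(2, 0.2, 1.1, 0.5)
  net <- buildRootedNetwork(p)
  g <- simulateNMSCCycle(net, m, seed = seed)
  report <- inferTree(g)
  best <- bestTopology(report)
  list(config = list(params = paramVector(p), m = m, seed = seed,
                     network = net@newick,
                     version = .pkgVersionString()),
       frequencies = topologyFrequencies(g),
       report = report,
       inferred = topologyNewick(best),
       isDisplayed = isDisplayed(best, p))
}

#' Theta proportions across hybridization levels
#'
#' Runs [sampleTheta()] with `nPerRange` draws for the four gamma ranges
#' `(0,1)`, `(0.2,0.8)`, `(0.4,0.6)` and `(0,0.1) u (0.9,1)` and collects
#' the fraction of draws in the misleading region Theta for each.  The
#' fractions increase as the gamma range concentrates around 0.5 (strong
#' hybridization signal) and drop sharply for near-tree gamma.
#'
#' @param nPerRange draws per gamma range (default 10^6).
#' @param seed optional integer seed.
#' @return A list with elements `config`, `proportions` (named numeric of
#'   length 4) and `summaries` (per-range [thetaSummaries()] lists).
#' @examples
#' reproduceTable1(nPerRange = 20000, seed = 1)$proportions
#' @export
reproduceTable1 <- function(nPerRange = 1e6, seed = NULL) {
  ranges <- list("(0,1)" = c(0, 1),
                 "(0.2,0.8)" = c(0.2, 0.8),
                 "(0.4,0.6)" = c(0.4, 0.6),
                 "(0,0.1)u(0.9,1)" = rbind(c(0, 0.1), c(0.9, 1)))
  if (!is.null(seed)) set.seed(seed)
  scans <- lapply(ranges, function(r) sampleTheta(nPerRange, r))
  list(config = list(nPerRange = nPerRange, seed = seed,
                     version = .pkgVersionString()),
       proportions = vapply(scans, thetaProportion, numeric(1)),
       summaries = lapply(scans, thetaSummaries))
}

#' Misleading-region trial study
#'
#' Rejection-samples `nTrials` parameter sets from the misleading region
#' Theta (gamma uniform on (0, 1)), simulates `mGenes` gene trees from
#' the corresponding rooted 5-cycle network for each, infers the
#' quartet-score-maximizing topology exhaustively, and counts the trials
#' whose inferred tree is *not* displayed by the network.  Trials whose
#' stage-1 inference returned a displayed tree are then rerun with
#' `mGenesFollowup` gene trees (same parameter sets), mirroring the
#' two-stage design in which apparent stage-1 successes are revealed as
#' finite-sample artifacts.  Set `mGenesFollowup = 0` to skip stage 2.
#'
#' @param nTrials number of Theta parameter sets (default 100).
#' @param mGenes gene trees per stage-1 trial (default 1,000).
#' @param mGenesFollowup gene trees per stage-2 rerun (default 50,000).
#' @param seed optional integer seed.
#' @return A list with elements `config`, `trials` (data.frame with one
#'   row per trial: parameters, inferred topology, `displayed` flag,
#'   `m`), `followup` (same shape, only the rerun trials) and `counts`
#'   (list with `nonDisplayed`, `displayed`,
#'   `followupNonDisplayed`).
#' @examples
#' ts <- trialStudy(nTrials = 4, mGenes = 300, mGenesFollowup = 0, seed = 2)
#' ts$counts
#' @export
trialStudy <- function(nTrials = 100, mGenes = 1000,
                       mGenesFollowup = 50000, seed = NULL) {
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  params <- sampleThetaParams(nTrials)

  runStage <- function(paramList, m) {
    rows <- lapply(paramList, function(p) {
      net <- buildRootedNetwork(p)
      g <- simulateNMSCCycle(net, m)
      best <- bestTopology(suppressWarnings(inferTree(g)))
      cbind(as.data.frame(as.list(paramVector(p))),
            data.frame(inferred = topologyNewick(best),
                       displayed = isDisplayed(best, p),
                       m = m, stringsAsFactors = FALSE))
    })
    do.call(rbind, rows)
  }

  trials <- runStage(params, mGenes)
  redo <- which(trials$displayed)
  followup <- if (mGenesFollowup > 0 && length(redo)) {
    runStage(params[redo], mGenesFollowup)
  } else {
    trials[integer(0), ]
  }
  list(config = list(nTrials = nTrials, mGenes = mGenes,
                     mGenesFollowup = mGenesFollowup, seed = seed,
                     version = .pkgVersionString()),
       trials = trials,
       followup = followup,
       counts = list(nonDisplayed = sum(!trials$displayed),
                     displayed = sum(trials$displayed),
                     followupNonDisplayed = sum(!followup$displayed)))
}
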