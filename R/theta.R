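# The misleading parameter region Theta ------------------------------------
#
# Vectorized internals work on y2, y3, y4, gamma; strict inequalities are
# compared in plain floating point (the boundary has measure zero under
# the sampling distribution).

.thm1Vec <- function(y2, y3, y4, g) {
  (1 - y2) > g / (1 - g) * (1 - y3 * y4) &
    (1 - y3) < pmin(g / (2 - g) * (1 - y4),
                    (1 - g) / (1 + g) * (1 - y2))
}

.cor2Vec <- function(y2, y3, y4, g) {
  (1 - y4) > (1 - g) / g * (1 - y3 * y2) &
    (1 - y3) < pmin(g / (2 - g) * (1 - y4),
                    (1 - g) / (1 + g) * (1 - y2))
}

.checkOpenGamma <- function(p) {
  if (p@gamma <= 0 || p@gamma >= 1)
    stop("the region conditions require 0 < gamma < 1")
}

#' Conditions for a non-displayed tree to outscore both displayed trees
#'
#' With `y_i = exp(-e_i)`, `theorem1Holds()` tests the pair of strict
#' inequalities
#' \deqn{(1-y_2) > \frac{\gamma}{1-\gamma}(1-y_3 y_4)}
#' \deqn{(1-y_3) < \min\Big(\frac{\gamma}{2-\gamma}(1-y_4),\;
#'   \frac{1-\gamma}{1+\gamma}(1-y_2)\Big)}
#' under which the non-displayed tree `S = (((A,E),B),C,D)` has a higher
#' expected quartet score than both displayed trees `T1` and `T2`.
#' `corollary2Holds()` tests the mirror-image conditions (first inequality
#' `(1-y_4) > \frac{1-\gamma}{\gamma}(1-y_3 y_2)`, same second condition)
#' under which `Sprime = (((A,E),D),C,B)` outscores both displayed trees.
#' `inTheta()` is their union: the misleading region Theta.
#'
#' All inequalities are strict and compared in plain floating point.
#' `gamma` must lie strictly in (0, 1).
#'
#' @param p a [CycleNetworkParams-class] object.
#' @return `TRUE` or `FALSE`.
#' @examples
#' p <- cycleParams(2, 0.2, 1.1, 0.5)
#' theorem1Holds(p)
#' corollary2Holds(mirrorParams(p))
#' inTheta(p)
#' @name theoremRegion
NULL

#' @rdname theoremRegion
#' @export
setMethod("theorem1Holds", "CycleNetworkParams", function(p) {
  .checkOpenGamma(p)
  y <- yValues(p)
  .thm1Vec(y[["y2"]], y[["y3"]], y[["y4"]], p@gamma)
})

#' @rdname theoremRegion
#' @export
setMethod("corollary2Holds", "CycleNetworkParams", function(p) {
  .checkOpenGamma(p)
  y <- yValues(p)
  .cor2Vec(y[["y2"]], y[["y3"]], y[["y4"]], p@gamma)
})

#' @rdname theoremRegion
#' @export
setMethod("inTheta", "CycleNetworkParams", function(p) {
  theorem1Holds(p) || corollary2Holds(p)
})

# Internal: normalize a gamma range specification into a 2-column matrix
# of disjoint intervals within [0, 1].
.gammaRangeMatrix <- function(gammaRange) {
  if (is.list(gammaRange)) gammaRange <- do.call(rbind, gammaRange)
  if (is.numeric(gammaRange) && is.null(dim(gammaRange)))
    gammaRange <- matrix(gammaRange, ncol = 2, byrow = TRUE)
  if (!is.matrix(gammaRange) || ncol(gammaRange) != 2 ||
      nrow(gammaRange) < 1)
    stop("gammaRange must be an interval c(lo, hi) or a list/matrix of them")
  if (any(gammaRange < 0) || any(gammaRange > 1) ||
      any(gammaRange[, 2] <= gammaRange[, 1]))
    stop("gamma intervals must be nonempty subsets of [0, 1]")
  gammaRange
}

# Internal: one batch of raw draws; returns a data.frame.
.drawBatch <- function(n, gr) {
  y2 <- runif(n); y3 <- runif(n); y4 <- runif(n)
  widths <- gr[, 2] - gr[, 1]
  if (nrow(gr) == 1) {
    g <- runif(n, gr[1, 1], gr[1, 2])
  } else {
    piece <- sample.int(nrow(gr), n, replace = TRUE,
                        prob = widths / sum(widths))
    g <- gr[piece, 1] + runif(n) * widths[piece]
  }
  thm1 <- .thm1Vec(y2, y3, y4, g)
  cor2 <- .cor2Vec(y2, y3, y4, g)
  data.frame(e2 = -log(y2), e3 = -log(y3), e4 = -log(y4), gamma = g,
             y2 = y2, y3 = y3, y4 = y4,
             theorem1 = thm1, corollary2 = cor2,
             inTheta = thm1 | cor2)
}

# Internal: 50 equal-width bins on [0, max(x)] (breaks + counts).
.fixedHist <- function(x, nbins = 50L) {
  if (!length(x)) return(list(breaks = numeric(0), counts = integer(0)))
  breaks <- seq(0, max(x), length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                          nbins), nbins)
  list(breaks = breaks, counts = counts)
}

.summarizeTheta <- function(draws) {
  members <- draws[draws$inTheta, c("e2", "e3", "e4", "gamma")]
  if (nrow(members)) {
    means <- colMeans(members)
    hist <- lapply(members, .fixedHist)
  } else {
    means <- setNames(rep(NA_real_, 4), c("e2", "e3", "e4", "gamma"))
    hist <- NULL
  }
  list(nTheta = sum(draws$inTheta), means = means, hist = hist)
}

#' Monte-Carlo scan of the misleading region Theta
#'
#' Draws `n` parameter sets with `y_i = exp(-e_i)` i.i.d. Uniform(0, 1)
#' for `i = 2, 3, 4` -- equivalently, edge lengths `e_i` i.i.d.
#' Exponential with mean 1 -- and the hybridization parameter gamma
#' uniform on `gammaRange` (an interval `c(lo, hi)` or a list/matrix of
#' disjoint intervals, sampled with mass proportional to width).  Each
#' draw is tested against the misleading-region conditions
#' ([theoremRegion]); the returned scan records the fraction of draws in
#' Theta and per-parameter summaries over the Theta members.
#'
#' @param n number of draws (`>= 1`).
#' @param gammaRange gamma sampling range within `[0, 1]`; default the
#'   full interval.
#' @param seed optional integer seed (recorded in the result).
#' @param keepDraws keep the per-draw data.frame in the result?  (For
#'   large `n` this costs ~80 bytes per draw.)
#' @return A [ThetaScan-class] object.
#' @examples
#' scan <- sampleTheta(10000, seed = 1)
#' thetaProportion(scan)
#' thetaSummaries(scan)$means
#' @export
sampleTheta <- function(n, gammaRange = c(0, 1), seed = NULL,
                        keepDraws = FALSE) {
  if (n < 1) stop("n must be >= 1")
  gr <- .gammaRangeMatrix(gammaRange)
  if (!is.null(seed)) set.seed(seed)
  draws <- .drawBatch(as.integer(n), gr)
  new("ThetaScan", n = as.integer(n), gammaRange = gr,
      proportion = mean(draws$inTheta),
      summary = .summarizeTheta(draws),
      draws = if (keepDraws) draws else data.frame(),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @describeIn sampleTheta fraction of draws in Theta.
#' @param x a [ThetaScan-class] object.
#' @export
setMethod("thetaProportion", "ThetaScan", function(x) x@proportion)

#' Per-parameter summaries over the Theta members of a scan
#'
#' Returns `nTheta` (number of draws in Theta), `means` (means of `e2`,
#' `e3`, `e4`, `gamma` over the Theta members; `NA` when Theta is empty)
#' and `hist` (fixed 50-equal-width-bin histogram counts on `[0, max]`
#' per parameter).
#'
#' @param x a [ThetaScan-class] object or a draw data.frame with columns
#'   `e2`, `e3`, `e4`, `gamma`, `inTheta`.
#' @return A list; see Details.
#' @rdname thetaSummaries
#' @export
setMethod("thetaSummaries", "ThetaScan", function(x) x@summary)

#' @rdname thetaSummaries
#' @export
setMethod("thetaSummaries", "data.frame", function(x) .summarizeTheta(x))

setMethod("show", "ThetaScan", function(object) {
  rng <- paste(apply(object@gammaRange, 1, function(r)
    sprintf("(%g,%g)", r[1], r[2])), collapse = " u ")
  cat(sprintf(
    "ThetaScan: %d draws, gamma in %s -> proportion in Theta = %.4f\n",
    object@n, rng, object@proportion))
  m <- object@summary$means
  if (!anyNA(m))
    cat(sprintf(
      "  Theta-member means: e2 = %.3f, e3 = %.3f, e4 = %.3f, gamma = %.3f\n",
      m[["e2"]], m[["e3"]], m[["e4"]], m[["gamma"]]))
})

#' Rejection-sample parameter sets from Theta
#'
#' Draws parameters as in [sampleTheta()] (gamma uniform on
#' `gammaRange`) and keeps only draws inside Theta, until `n` members are
#' found.  Used by [trialStudy()] to pick empirically problematic
#' parameter sets.
#'
#' @param n number of Theta members required.
#' @param gammaRange as in [sampleTheta()].
#' @param seed optional integer seed.
#' @param maxBatches cap on the number of 10,000-draw batches (error if
#'   exceeded; Theta has roughly 6% prior mass, so the default is ample).
#' @return A list of `n` [CycleNetworkParams-class] objects.
#' @examples
#' sampleThetaParams(2, seed = 7)
#' @export
sampleThetaParams <- function(n, gammaRange = c(0, 1), seed = NULL,
                              maxBatches = 1000L) {
  gr <- .gammaRangeMatrix(gammaRange)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  found <- 0L
  for (b in seq_len(maxBatches)) {
    draws <- .drawBatch(10000L, gr)
    hits <- which(draws$inTheta)
    for (h in hits) {
      if (found == n) break
      found <- found + 1L
      out[[found]] <- cycleParams(draws$e2[h], draws$e3[h],
                                  draws$e4[h], draws$gamma[h])
    }
    if (found == n) return(out)
  }
  stop("rejection sampling exceeded the iteration cap")
}
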