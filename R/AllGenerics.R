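#' @rdname displayedTrees
#' @export
setGeneric("displayedTrees", function(net) standardGeneric("displayedTrees"))

#' @rdname inducedQuartets
#' @export
setGeneric("inducedQuartets", function(t) standardGeneric("inducedQuartets"))

#' @rdname topologyNewick
#' @export
setGeneric("topologyNewick", function(t) standardGeneric("topologyNewick"))

#' @rdname quartetProbs
#' @export
setGeneric("quartetProbs", function(x, quartet) standardGeneric("quartetProbs"))

#' @rdname expectedScore
#' @export
setGeneric("expectedScore", function(t, q) standardGeneric("expectedScore"))

#' @rdname alphaStar
#' @export
setGeneric("alphaStar", function(q) standardGeneric("alphaStar"))

#' @rdname bestTree
#' @export
setGeneric("bestTree", function(q, ...) standardGeneric("bestTree"))

#' @rdname empiricalQuartetTable
#' @export
setGeneric("empiricalQuartetTable",
           function(g) standardGeneric("empiricalQuartetTable"))

#' @rdname inferTree
#' @export
setGeneric("inferTree", function(g, ...) standardGeneric("inferTree"))

#' @rdname isDisplayed
#' @export
setGeneric("isDisplayed", function(t, p) standardGeneric("isDisplayed"))

#' @rdname theoremRegion
#' @export
setGeneric("theorem1Holds", function(p) standardGeneric("theorem1Holds"))

#' @rdname theoremRegion
#' @export
setGeneric("corollary2Holds", function(p) standardGeneric("corollary2Holds"))

#' @rdname theoremRegion
#' @export
setGeneric("inTheta", function(p) standardGeneric("inTheta"))

#' @rdname thetaSummaries
#' @export
setGeneric("thetaSummaries", function(x) standardGeneric("thetaSummaries"))

#' @rdname topologyFrequencies
#' @export
setGeneric("topologyFrequencies",
           function(g, ...) standardGeneric("topologyFrequencies"))

#' @rdname GeneTreeSample-accessors
#' @export
setGeneric("sampleSize", function(g) standardGeneric("sampleSize"))

#' @rdname GeneTreeSample-accessors
#' @export
setGeneric("topologyCodes", function(g) standardGeneric("topologyCodes"))

#' @rdname cycleParams
#' @export
setGeneric("yValues", function(p) standardGeneric("yValues"))

#' @rdname cycleParams
#' @export
setGeneric("paramVector", function(p) standardGeneric("paramVector"))

#' @rdname bestTree
#' @export
setGeneric("bestTopology", function(x) standardGeneric("bestTopology"))

#' @rdname sampleTheta
#' @export
setGeneric("thetaProportion", function(x) standardGeneric("thetaProportion"))
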