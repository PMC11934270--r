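#' Create parameters of the canonical 5-cycle network
#'
#' @param e2,e3,e4 positive internal edge lengths in coalescent units
#'   (see [CycleNetworkParams-class] for the edge roles).
#' @param gamma hybridization parameter in `[0, 1]`: the inheritance
#'   weight of the hybrid edge whose retention yields the displayed tree
#'   `T1 = (A,(B,C),(D,E))`; the other edge (yielding
#'   `T2 = ((A,B),(C,D),E)`) has weight `1 - gamma`.
#' @return A [CycleNetworkParams-class] object.
#' @examples
#' p <- cycleParams(2, 0.2, 1.1, 0.5)
#' yValues(p)
#' @rdname cycleParams
#' @export
cycleParams <- function(e2, e3, e4, gamma) {
  new("CycleNetworkParams", e2 = as.numeric(e2), e3 = as.numeric(e3),
      e4 = as.numeric(e4), gamma = as.numeric(gamma))
}

#' @describeIn cycleParams the derived quantities `y_i = exp(-e_i)` as a
#'   named vector `c(y2, y3, y4)`.
#' @param p a [CycleNetworkParams-class] object.
#' @export
setMethod("yValues", "CycleNetworkParams", function(p) {
  c(y2 = exp(-p@e2), y3 = exp(-p@e3), y4 = exp(-p@e4))
})

#' @describeIn cycleParams the raw parameters as a named vector
#'   `c(e2, e3, e4, gamma)`.
#' @export
setMethod("paramVector", "CycleNetworkParams", function(p) {
  c(e2 = p@e2, e3 = p@e3, e4 = p@e4, gamma = p@gamma)
})

setMethod("show", "CycleNetworkParams", function(object) {
  cat(sprintf(
    "CycleNetworkParams: e2 = %.6g, e3 = %.6g, e4 = %.6g, gamma = %.6g\n",
    object@e2, object@e3, object@e4, object@gamma))
})

#' Mirror image of 5-cycle parameters
#'
#' The canonical 5-cycle has a reflection symmetry exchanging taxa B and D
#' and the two hybrid edges; on parameters it swaps `e2` with `e4` and
#' `gamma` with `1 - gamma`.  The mirror map carries instances of the
#' first misleading condition ([theorem1Holds()]) onto instances of the
#' second ([corollary2Holds()]) and the outscoring tree `S` onto `Sprime`.
#'
#' @param p a [CycleNetworkParams-class] object.
#' @return The mirrored [CycleNetworkParams-class].
#' @examples
#' mirrorParams(cycleParams(2, 0.2, 1.1, 0.5))
#' @export
mirrorParams <- function(p) {
  stopifnot(is(p, "CycleNetworkParams"))
  cycleParams(p@e4, p@e3, p@e2, 1 - p@gamma)
}
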