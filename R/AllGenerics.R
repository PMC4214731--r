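#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @export
setGeneric("boundedDistance", function(net, a, b, maxLen = 2L)
  standardGeneric("boundedDistance"))

#' @export
setGeneric("nodeNeighborhood", function(net, seeds, v)
  standardGeneric("nodeNeighborhood"))

#' @export
setGeneric("medianDegree", function(net) standardGeneric("medianDegree"))

#' @export
setGeneric("edgeTable", function(net) standardGeneric("edgeTable"))

#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @export
setGeneric("nodeSets", function(x) standardGeneric("nodeSets"))

#' @export
setGeneric("knownDrugs", function(assoc, disease) standardGeneric("knownDrugs"))

#' @export
setGeneric("knownDiseases", function(assoc, drug)
  standardGeneric("knownDiseases"))

#' @export
setGeneric("associationPairs", function(assoc)
  standardGeneric("associationPairs"))

#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))

#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))

#' @export
setGeneric("repeatAUCs", function(x) standardGeneric("repeatAUCs"))
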