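#' @import methods
NULL

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("edgeKeys", function(x) standardGeneric("edgeKeys"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("activePlayers", function(x) standardGeneric("activePlayers"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("nActive", function(x) standardGeneric("nActive"))

#' @rdname geneStar
#' @export
setGeneric("geneStar", function(x, gene) standardGeneric("geneStar"))

#' @rdname geneStar
#' @export
setGeneric("geneDegree", function(x, gene) standardGeneric("geneDegree"))

#' @rdname gameValue
#' @export
setGeneric("gameValue", function(game, links) standardGeneric("gameValue"))

#' @rdname MicroarrayNetworkGame-class
#' @export
setGeneric("baseNetwork", function(x) standardGeneric("baseNetwork"))

#' @rdname lriScores
#' @export
setGeneric("lriClosed", function(x, ...) standardGeneric("lriClosed"))

#' @rdname lriScores
#' @export
setGeneric("lriSum", function(x, ...) standardGeneric("lriSum"))

#' @rdname positionValueOracle
#' @export
setGeneric("positionValueOracle", function(x, ...)
  standardGeneric("positionValueOracle"))

#' @rdname LRIScoreTable-class
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname LRIScoreTable-class
#' @export
setGeneric("lriScores", function(x) standardGeneric("lriScores"))

#' @rdname MicroarrayExperimentSituation-class
#' @export
setGeneric("caseMatrix", function(x) standardGeneric("caseMatrix"))

#' @rdname MicroarrayExperimentSituation-class
#' @export
setGeneric("controlMatrix", function(x) standardGeneric("controlMatrix"))

#' @rdname MicroarrayExperimentSituation-class
#' @export
setGeneric("caseSamples", function(x) standardGeneric("caseSamples"))

#' @rdname MicroarrayExperimentSituation-class
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
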