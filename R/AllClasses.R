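#' CoexpressionNetwork: an undirected gene co-expression network
#'
#' Holds the gene set \eqn{N} and the link set \eqn{g^E} of a co-expression
#' network. Links are unordered pairs of distinct genes, stored with the two
#' ids in lexicographic order; genes may be present without any link
#' (isolated genes), so the active-player set \eqn{N(g^E)} can be a strict
#' subset of the node set.
#'
#' @slot nodes character vector of gene identifiers (the set \eqn{N}).
#' @slot edges two-column character matrix of links, one row per link,
#'   columns already in lexicographic order within each row.
#'
#' @param x a \code{CoexpressionNetwork} (or, for \code{edgeKeys}, any object
#'   with edges).
#' @return \code{networkNodes}: the gene ids; \code{networkEdges}: the
#'   two-column link matrix; \code{edgeKeys}: links as \code{"a|b"} strings;
#'   \code{activePlayers}: genes with at least one link (\eqn{N(g^E)});
#'   \code{nActive}: the count \eqn{n(g^E)}.
#' @seealso [coexpressionNetwork()] to construct one, [geneStar()],
#'   [lriClosed()].
#' @export
setClass("CoexpressionNetwork",
         representation(nodes = "character", edges = "matrix"))

setValidity("CoexpressionNetwork", function(object) {
  e <- object@edges
  n <- object@nodes
  msgs <- character()
  if (anyDuplicated(n)) msgs <- c(msgs, "duplicate gene ids in nodes")
  if (ncol(e) != 2L) msgs <- c(msgs, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (!all(e %in% n)) msgs <- c(msgs, "edge endpoint not among nodes")
    if (any(e[, 1L] == e[, 2L])) msgs <- c(msgs, "self-loop edge")
    if (any(e[, 1L] > e[, 2L]))
      msgs <- c(msgs, "edge endpoints not in lexicographic order")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "|")))
      msgs <- c(msgs, "duplicate edges")
  }
  if (length(msgs)) msgs else TRUE
})

#' MicroarrayNetworkGame: the cooperative link game of a network
#'
#' Wraps a \code{CoexpressionNetwork} as a cooperative game on link subsets.
#' The characteristic function averages, over the active genes, the unanimity
#' games anchored at each gene's star: a link set \eqn{g} is worth
#' \eqn{v(g) = \frac{1}{n(g^E)} \sum_{i \in N(g^E)} u_{g_i^E}(g)}, where the
#' unanimity game \eqn{u_{g_i^E}} pays 1 exactly when \eqn{g} contains the
#' whole star of gene \eqn{i}. Consequently \eqn{v(\emptyset) = 0},
#' \eqn{v(g^E) = 1}, and \eqn{v} is monotone under link-set inclusion.
#'
#' @slot network the underlying \code{CoexpressionNetwork} (\eqn{g^E}).
#' @param x a \code{MicroarrayNetworkGame}.
#' @return \code{baseNetwork}: the underlying network.
#' @seealso [microarrayNetworkGame()], [gameValue()], [positionValueOracle()].
#' @export
setClass("MicroarrayNetworkGame",
         representation(network = "CoexpressionNetwork"))

setValidity("MicroarrayNetworkGame", function(object) {
  if (nActive(object@network) < 1L)
    "degenerate game: base network has no linked gene"
  else TRUE
})

#' LRIScoreTable: per-gene Link Relevance Index allocation
#'
#' The result of an LRI computation: one row per gene carrying the exact
#' rational score (numerator/denominator), its floating-point view, the gene
#' degree, and a dense rank (descending by score; tied scores share a rank and
#' are ordered by gene id). For a network with at least one link the scores of
#' the active genes sum exactly to 1 (efficiency); isolated genes score 0.
#'
#' @slot table data.frame with columns \code{gene}, \code{num}, \code{den},
#'   \code{lri}, \code{degree}, \code{rank}, sorted descending by score then
#'   lexicographically by gene.
#' @slot method character, which implementation produced it
#'   (\code{"closed"}, \code{"sum"} or \code{"oracle"}).
#'
#' @param x an \code{LRIScoreTable}.
#' @return \code{scoreTable}: the underlying data.frame; \code{lriScores}:
#'   named numeric vector of scores in table order.
#' @seealso [lriClosed()], [selectSalient()], [writeScoreTable()].
#' @export
setClass("LRIScoreTable",
         representation(table = "data.frame", method = "character"))

setValidity("LRIScoreTable", function(object) {
  need <- c("gene", "num", "den", "lri", "degree", "rank")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  tb <- object@table
  if (any(tb$num < 0) || any(tb$den <= 0)) return("scores must be >= 0")
  if (any((tb$degree >= 1L) != (tb$num > 0)))
    return("score positive exactly for linked genes")
  TRUE
})

#' MicroarrayExperimentSituation: case/control expression experiment
#'
#' The tuple of a two-group expression study: a gene panel, disjoint diseased
#' (case) and reference (control) sample sets, and their log2-scale
#' expression matrices. Implemented as a \code{SummarizedExperiment} whose
#' \code{colData} carries a \code{group} column with values \code{"case"} or
#' \code{"control"}; the single assay \code{"log2"} holds genes in rows and
#' samples in columns.
#'
#' @param x a \code{MicroarrayExperimentSituation}.
#' @return \code{caseMatrix}/\code{controlMatrix}: the genes-by-samples log2
#'   submatrices of each group; \code{caseSamples}/\code{controlSamples}:
#'   the sample ids.
#' @seealso [microarrayExperimentSituation()], [buildNetwork()],
#'   [computeDeg()].
#' @import SummarizedExperiment
#' @export
setClass("MicroarrayExperimentSituation",
         contains = "SummarizedExperiment")

setValidity("MicroarrayExperimentSituation", function(object) {
  msgs <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd))
    return("colData must contain a 'group' column")
  grp <- as.character(cd$group)
  if (!all(grp %in% c("case", "control")))
    msgs <- c(msgs, "group values must be 'case' or 'control'")
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'log2' is required")
  else {
    a <- SummarizedExperiment::assay(object, "log2")
    if (!is.numeric(a) || !all(is.finite(a)))
      msgs <- c(msgs, "expression values must all be finite numbers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "unique gene ids required as rownames")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "unique sample ids required as colnames")
  if (length(msgs)) msgs else TRUE
})

#' GeneSetCollection: named gene sets over a background universe
#'
#' Named gene sets (as parsed from a GMT file) together with the background
#' universe used for enrichment testing. Stands in for marker-gene lists and
#' ontology annotation collections; the universe is always caller-supplied
#' because enrichment p-values depend on it.
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot descriptions character vector, one per set.
#' @slot universe character vector of background gene ids.
#' @param x a \code{GeneSetCollection}.
#' @return \code{geneSets}: the named list of sets; \code{geneUniverse}:
#'   the background ids.
#' @seealso [readGmt()], [hypergeomEnrichment()].
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character",
                        universe = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  if (length(object@sets) == 0L) msgs <- c(msgs, "no gene sets")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msgs <- c(msgs, "sets must have unique names")
  if (any(vapply(object@sets, length, 1L) == 0L))
    msgs <- c(msgs, "empty gene set")
  if (any(vapply(object@sets, anyDuplicated, 1L) > 0L))
    msgs <- c(msgs, "duplicate member within a set")
  if (length(object@descriptions) != length(object@sets))
    msgs <- c(msgs, "one description per set required")
  if (anyDuplicated(object@universe))
    msgs <- c(msgs, "duplicate ids in universe")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticTruth: planted structure of a simulated experiment
#'
#' Records what the simulator planted, for recovery scoring: the gene ids of
#' each co-expressed module, designated hub genes (genes loading on more than
#' one module), the shifted (DEG) genes, and the population within-module
#' correlation \eqn{\lambda^2 / (\lambda^2 + \sigma^2)} implied by the
#' single-factor model.
#'
#' @slot moduleMembers named list of character vectors, genes per module.
#' @slot hubGenes character vector of designated hub genes.
#' @slot degGenes character vector of mean-shifted genes.
#' @slot moduleCorrelation numeric, population pairwise correlation per module.
#' @seealso [simulateExperiment()], [recoveryReport()].
#' @export
setClass("SyntheticTruth",
         representation(moduleMembers = "list", hubGenes = "character",
                        degGenes = "character",
                        moduleCorrelation = "numeric"))
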