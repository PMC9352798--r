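#' Construct a gene co-expression network
#'
#' Builds a \linkS4class{CoexpressionNetwork} from an explicit link list.
#' Links are canonicalised (endpoints sorted lexicographically, duplicates
#' rejected); genes mentioned only in \code{nodes} but in no link are kept as
#' isolated genes.
#'
#' @param edges links, as a two-column character matrix/data.frame (one row
#'   per link) or a character vector of \code{"a|b"} keys. May be empty.
#' @param nodes optional character vector of gene ids; defaults to the genes
#'   appearing in \code{edges}. Must contain every edge endpoint.
#' @return a \code{CoexpressionNetwork}.
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' activePlayers(net)
#' geneStar(net, "1")
#' @export
coexpressionNetwork <- function(edges, nodes = NULL) {
  if (is.character(edges) && is.null(dim(edges))) {
    parts <- strsplit(edges, "|", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("malformed edge key(s): ",
                       paste(edges[bad], collapse = ", "))
    edges <- do.call(rbind, parts)
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), 0L, 2L)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  mode(edges) <- "character"
  ## canonical order within each link
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L)]
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop edge(s) not allowed")
  key <- paste(edges[, 1L], edges[, 2L], sep = "|")
  if (anyDuplicated(key))
    stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]),
                                      collapse = ", "))
  edges <- edges[order(key), , drop = FALSE]
  if (is.null(nodes)) {
    nodes <- sort(unique(as.vector(edges)))
  } else {
    nodes <- as.character(nodes)
    missing <- setdiff(as.vector(edges), nodes)
    if (length(missing))
      stop("edge endpoint(s) not in nodes: ", paste(missing, collapse = ", "))
  }
  new("CoexpressionNetwork", nodes = nodes, edges = edges)
}

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("edgeKeys", "CoexpressionNetwork", function(x) {
  e <- x@edges
  if (nrow(e) == 0L) character() else paste(e[, 1L], e[, 2L], sep = "|")
})

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("activePlayers", "CoexpressionNetwork", function(x) {
  x@nodes[x@nodes %in% as.vector(x@edges)]
})

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("nActive", "CoexpressionNetwork",
          function(x) length(activePlayers(x)))

#' Star and degree of a gene
#'
#' \code{geneStar} returns the star \eqn{g_i^E} of a gene: the set of links of
#' the network incident to it, as \code{"a|b"} keys (empty for an isolated
#' gene). \code{geneDegree} returns the star size \eqn{d_i(g^E)}; with no
#' \code{gene} argument, the named degree vector of all nodes.
#'
#' @param x a \code{CoexpressionNetwork}.
#' @param gene a gene id present in the network's nodes.
#' @return character vector of edge keys, or integer degree(s).
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3")))
#' geneStar(net, "1")
#' geneDegree(net)
#' @export
setMethod("geneStar", "CoexpressionNetwork", function(x, gene) {
  if (length(gene) != 1L || !gene %in% x@nodes)
    stop("unknown gene id: ", gene)
  e <- x@edges
  hit <- e[, 1L] == gene | e[, 2L] == gene
  if (!any(hit)) return(character())
  paste(e[hit, 1L], e[hit, 2L], sep = "|")
})

#' @rdname geneStar
#' @export
setMethod("geneDegree", "CoexpressionNetwork", function(x, gene) {
  counts <- table(factor(as.vector(x@edges), levels = x@nodes))
  deg <- as.integer(counts)
  names(deg) <- x@nodes
  if (missing(gene)) return(deg)
  if (!all(gene %in% x@nodes))
    stop("unknown gene id: ", paste(setdiff(gene, x@nodes), collapse = ", "))
  deg[gene]
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork with", length(object@nodes), "genes and",
      nrow(object@edges), "links;", nActive(object), "active\n")
})

#' Summarise a co-expression network
#'
#' @param network a \code{CoexpressionNetwork}.
#' @return a list with \code{n_nodes}, \code{n_active}, \code{n_edges},
#'   \code{degree_histogram} (table of positive degrees) and
#'   \code{component_sizes} (sizes of connected components among active
#'   genes, decreasing).
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' networkSummary(net)
#' @export
networkSummary <- function(network) {
  stopifnot(is(network, "CoexpressionNetwork"))
  deg <- geneDegree(network)
  act <- deg[deg > 0L]
  comp_sizes <- integer()
  if (nrow(network@edges) > 0L) {
    g <- igraph::graph_from_edgelist(network@edges, directed = FALSE)
    comp_sizes <- sort(igraph::components(g)$csize, decreasing = TRUE)
  }
  list(n_nodes = length(network@nodes),
       n_active = nActive(network),
       n_edges = nrow(network@edges),
       degree_histogram = table(act),
       component_sizes = as.integer(comp_sizes))
}
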