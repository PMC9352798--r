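#' Build the microarray network game of a co-expression network
#'
#' @param network a \code{CoexpressionNetwork} with at least one linked gene.
#' @return a \linkS4class{MicroarrayNetworkGame}.
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' game <- microarrayNetworkGame(net)
#' gameValue(game, c("1|2", "1|3", "1|4"))
#' @export
microarrayNetworkGame <- function(network) {
  stopifnot(is(network, "CoexpressionNetwork"))
  if (nActive(network) < 1L)
    stop("degenerate game: network has no links")
  new("MicroarrayNetworkGame", network = network)
}

#' @rdname MicroarrayNetworkGame-class
#' @export
setMethod("baseNetwork", "MicroarrayNetworkGame", function(x) x@network)

setMethod("show", "MicroarrayNetworkGame", function(object) {
  net <- object@network
  cat("MicroarrayNetworkGame on", nActive(net), "active genes /",
      nrow(net@edges), "links\n")
})

#' Unanimity game of a star
#'
#' The unanimity game anchored at a link set \eqn{T} pays 1 on any link set
#' containing \eqn{T} and 0 otherwise; the empty anchor pays 1 everywhere.
#'
#' @param starLinks anchor link set (character keys \code{"a|b"}).
#' @param g evaluated link set (character keys).
#' @return 1 if \code{starLinks} is a subset of \code{g}, else 0.
#' @examples
#' unanimityValue("1|4", "1|4")             # 1
#' unanimityValue(c("1|2","1|3"), "1|2")    # 0
#' @export
unanimityValue <- function(starLinks, g) {
  if (all(starLinks %in% g)) 1L else 0L
}

.normalizeLinks <- function(links) {
  if (is.matrix(links) || is.data.frame(links)) {
    links <- as.matrix(links)
    mode(links) <- "character"
    swap <- links[, 1L] > links[, 2L]
    links[swap, ] <- links[swap, c(2L, 1L)]
    links <- paste(links[, 1L], links[, 2L], sep = "|")
  }
  unique(as.character(links))
}

#' Characteristic function of a microarray network game
#'
#' Evaluates \eqn{v(g) = \frac{1}{n(g^E)} \sum_{i \in N(g^E)} u_{g_i^E}(g)}:
#' the fraction of active genes whose whole star is contained in the link
#' set \code{links}. Returned as an exact rational.
#'
#' @param game a \code{MicroarrayNetworkGame}.
#' @param links a link set: character vector of \code{"a|b"} keys or a
#'   two-column matrix; may be empty.
#' @return an object of class \code{"rational"} (fields \code{num},
#'   \code{den}); convert with \code{as.numeric(gameValue(...)$num /
#'   gameValue(...)$den)} or compare exactly.
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' game <- microarrayNetworkGame(net)
#' gameValue(game, c("1|2", "1|3", "1|4"))   # 1/2
#' gameValue(game, edgeKeys(net))            # 1
#' @export
setMethod("gameValue", "MicroarrayNetworkGame", function(game, links) {
  net <- game@network
  if (nActive(net) < 1L) stop("degenerate game: network has no links")
  links <- .normalizeLinks(links)
  players <- activePlayers(net)
  hits <- sum(vapply(players,
                     function(i) unanimityValue(geneStar(net, i), links),
                     integer(1)))
  rational(hits, length(players))
})
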