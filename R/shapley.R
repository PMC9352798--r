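## Brute-force Shapley machinery for the link game. The oracle enumerates all
## 2^m coalitions of links; with m capped at 16 the factorial weights and
## accumulated numerators stay below 2^53, so plain doubles hold them exactly.

.popcount <- function(x, m) {
  out <- integer(length(x))
  for (b in seq_len(m) - 1L)
    out <- out + as.integer(bitwAnd(x, bitwShiftL(1L, b)) != 0L)
  out
}

## Shapley value of each of the m links for a characteristic function given
## as exact rationals over all 2^m coalitions (index = mask + 1).
## Used for the additivity axiom check, where the summed game is no longer an
## integer-count game. Returns a rational vector of length m.
.shapleyFromValues <- function(num, den, m) {
  S <- 0:(2^m - 1L)
  sizes <- .popcount(S, m)
  w <- factorial(0:(m - 1L)) * factorial((m - 1L):0)   # w[s+1] = s!(m-s-1)!
  outNum <- numeric(m); outDen <- numeric(m)
  for (b in seq_len(m)) {
    bit <- bitwShiftL(1L, b - 1L)
    without <- S[bitwAnd(S, bit) == 0L]
    acc <- rational(0, 1)
    for (s in without) {
      d <- ratAdd(rational(num[s + bit + 1L], den[s + bit + 1L]),
                  rational(-num[s + 1L], den[s + 1L]))
      acc <- ratAdd(acc, ratMul(rational(w[sizes[s + 1L] + 1L], 1), d))
    }
    sh <- ratMul(acc, rational(1, factorial(m)))
    outNum[b] <- sh$num; outDen[b] <- sh$den
  }
  list(num = outNum, den = outDen)
}

## Exact Shapley value of every link of the network's microarray game.
.linkShapley <- function(net, cap) {
  keys <- edgeKeys(net)
  m <- length(keys)
  if (m > cap)
    stop("link count ", m, " exceeds the enumeration cap (", cap,
         "); use lriClosed() for large networks")
  n <- nActive(net)
  players <- activePlayers(net)
  masks <- vapply(players, function(i) {
    sum(bitwShiftL(1L, which(keys %in% geneStar(net, i)) - 1L))
  }, numeric(1))

  ## counts[mask+1] = number of stars contained in coalition `mask`; v = counts/n
  S <- 0:(2^m - 1L)
  counts <- integer(2^m)
  for (mk in masks) counts <- counts + as.integer(bitwAnd(S, mk) == mk)

  sizes <- .popcount(S, m)
  w <- factorial(0:(m - 1L)) * factorial((m - 1L):0)
  mfact <- factorial(m)
  shNum <- numeric(m); shDen <- numeric(m)
  for (b in seq_len(m)) {
    bit <- bitwShiftL(1L, b - 1L)
    without <- S[bitwAnd(S, bit) == 0L]
    delta <- counts[without + bit + 1L] - counts[without + 1L]
    cl <- sum(w[sizes[without + 1L] + 1L] * delta)
    sh <- rational(cl, mfact * n)
    shNum[b] <- sh$num; shDen[b] <- sh$den
  }
  list(keys = keys, num = shNum, den = shDen)
}

#' Exact Shapley values of the links of a microarray network game
#'
#' @param game a \code{MicroarrayNetworkGame}.
#' @param cap maximum link count to enumerate (default 16).
#' @return data.frame with columns \code{link}, \code{num}, \code{den},
#'   \code{shapley} (float view); the Shapley values sum to
#'   \eqn{v(g^E) = 1}.
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' linkShapleyValues(microarrayNetworkGame(net))
#' @export
linkShapleyValues <- function(game, cap = 16L) {
  stopifnot(is(game, "MicroarrayNetworkGame"))
  sh <- .linkShapley(game@network, cap)
  data.frame(link = sh$keys, num = sh$num, den = sh$den,
             shapley = sh$num / sh$den, stringsAsFactors = FALSE)
}

#' Brute-force position value of a microarray network game
#'
#' Independent oracle for the LRI: enumerates every coalition of links,
#' computes the exact Shapley value of each link in the link game by
#' factorial-weighted marginal contributions, and assigns each gene half the
#' Shapley value of each incident link. Exponential in the link count, hence
#' the cap; agrees exactly (rational arithmetic) with [lriClosed()] and
#' [lriSum()].
#'
#' @param x a \code{MicroarrayNetworkGame} or a \code{CoexpressionNetwork}
#'   (wrapped automatically).
#' @param cap maximum link count to enumerate (default 16, i.e. at most
#'   \code{2^16} coalitions).
#' @param includeIsolated keep isolated genes with score 0 (default TRUE).
#' @param ... unused.
#' @return an \linkS4class{LRIScoreTable} (method \code{"oracle"}).
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' scoreTable(positionValueOracle(net))
#' @export
setMethod("positionValueOracle", "MicroarrayNetworkGame",
          function(x, cap = 16L, includeIsolated = TRUE, ...) {
  net <- x@network
  sh <- .linkShapley(net, cap)
  genes <- networkNodes(net)
  deg <- geneDegree(net)
  num <- numeric(length(genes)); den <- rep(1, length(genes))
  names(num) <- names(den) <- genes
  for (i in activePlayers(net)) {
    idx <- which(sh$keys %in% geneStar(net, i))
    acc <- rational(0, 1)
    for (b in idx)
      acc <- ratAdd(acc, rational(sh$num[b], 2 * sh$den[b]))
    num[i] <- acc$num; den[i] <- acc$den
  }
  .makeScoreTable(genes, num, den, deg, "oracle", includeIsolated)
})

#' @rdname positionValueOracle
#' @export
setMethod("positionValueOracle", "CoexpressionNetwork",
          function(x, cap = 16L, includeIsolated = TRUE, ...) {
  positionValueOracle(microarrayNetworkGame(x), cap = cap,
                      includeIsolated = includeIsolated)
})
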