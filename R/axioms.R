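## Axiom checks for the LRI allocation: efficiency, superfluous-link
## invariance, anonymity (permutation equivariance) and additivity of the
## Shapley oracle. Failures are reported, never raised.

## General allocation F(g, v, g^E) evaluated on a supernetwork g >= g^E:
## only subsets g' of g that coincide with some star of g^E carry unanimity
## weight, each contributing |g'_i| / (2|g'|) to every incident gene i.
.allocationOnLinks <- function(net, evalKeys) {
  genes <- networkNodes(net)
  n <- nActive(net)
  num <- numeric(length(genes)); den <- rep(1, length(genes))
  names(num) <- names(den) <- genes
  acc <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) acc[[g]] <- rational(0, 1)
  for (j in activePlayers(net)) {
    starJ <- geneStar(net, j)
    if (!all(starJ %in% evalKeys)) next
    ends <- strsplit(starJ, "|", fixed = TRUE)
    touching <- unique(unlist(ends))
    for (i in touching) {
      inc <- sum(vapply(ends, function(p) i %in% p, logical(1)))
      acc[[i]] <- ratAdd(acc[[i]], rational(inc, 2 * length(starJ) * n))
    }
  }
  for (g in genes) { num[g] <- acc[[g]]$num; den[g] <- acc[[g]]$den }
  list(num = num, den = den)
}

.scoresAsRationalMap <- function(tab) {
  tb <- scoreTable(tab)
  list(num = stats::setNames(tb$num, tb$gene),
       den = stats::setNames(tb$den, tb$gene))
}

#' Check the four LRI axioms on a network
#'
#' Verifies, in exact rational arithmetic, the four properties that
#' characterise the LRI allocation:
#' \describe{
#'   \item{efficiency}{the scores of all genes sum to the value of the whole
#'     network, \eqn{\sum_i F_i = v(g^E) = 1};}
#'   \item{superfluous link property}{evaluating the allocation on a
#'     supernetwork containing extra links absent from every star leaves all
#'     scores unchanged;}
#'   \item{anonymity}{relabeling genes by a permutation permutes the scores
#'     identically;}
#'   \item{additivity}{the Shapley oracle allocation of the sum of two
#'     unanimity-built link games equals the sum of the separate
#'     allocations.}
#' }
#' Random permutations, superfluous-link draws and partner games are
#' generated from \code{seed}; the additivity check enumerates coalitions and
#' therefore requires a small link count.
#'
#' @param network a \code{CoexpressionNetwork} with at least one link.
#' @param trials number of random repetitions per randomised axiom.
#' @param seed integer RNG seed.
#' @param cap enumeration cap passed to the oracle for the additivity check.
#' @return list with logical fields \code{efficiency}, \code{superfluous},
#'   \code{anonymity}, \code{additivity} and an \code{all_pass} flag.
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' checkAxioms(net, trials = 5, seed = 1)$all_pass
#' @export
checkAxioms <- function(network, trials = 10L, seed = 1L, cap = 16L) {
  stopifnot(is(network, "CoexpressionNetwork"), nrow(networkEdges(network)) > 0L)
  set.seed(seed)
  ref <- lriClosed(network)
  refMap <- .scoresAsRationalMap(ref)
  genes <- networkNodes(network)
  keys <- edgeKeys(network)

  ## efficiency: exact rational sum equals 1
  tot <- ratSum(rational(scoreTable(ref)$num, scoreTable(ref)$den))
  efficiency <- tot$num == 1 && tot$den == 1

  ## superfluous links: add absent links to the evaluation network only
  allPairs <- utils::combn(sort(genes), 2L)
  allKeys <- paste(allPairs[1L, ], allPairs[2L, ], sep = "|")
  spare <- setdiff(allKeys, keys)
  superfluous <- TRUE
  for (k in seq_len(trials)) {
    extra <- if (length(spare))
      sample(spare, sample.int(length(spare), 1L)) else character()
    al <- .allocationOnLinks(network, c(keys, extra))
    ok <- all(al$num[genes] == refMap$num[genes] &
              al$den[genes] == refMap$den[genes])
    if (!ok) { superfluous <- FALSE; break }
  }

  ## anonymity: relabel genes, recompute, map back
  anonymity <- TRUE
  for (k in seq_len(trials)) {
    perm <- sample(genes)
    names(perm) <- genes                      # gene -> new label
    e <- networkEdges(network)
    relabeled <- coexpressionNetwork(cbind(perm[e[, 1L]], perm[e[, 2L]]),
                                     nodes = unname(perm))
    pm <- .scoresAsRationalMap(lriClosed(relabeled))
    ok <- all(pm$num[perm[genes]] == refMap$num[genes] &
              pm$den[perm[genes]] == refMap$den[genes])
    if (!ok) { anonymity <- FALSE; break }
  }

  ## additivity of the Shapley oracle on a sum of two unanimity-built games
  additivity <- TRUE
  if (length(keys) <= cap) {
    for (k in seq_len(trials)) {
      partner <- randomNetwork(length(genes), min(length(keys), 4L),
                               connected = FALSE, nodes = genes)
      union_keys <- sort(union(keys, edgeKeys(partner)))
      m <- length(union_keys)
      if (m > cap) next
      v1 <- .characteristicArray(network, union_keys)
      v2 <- .characteristicArray(partner, union_keys)
      sumNum <- numeric(2^m); sumDen <- numeric(2^m)
      for (s in seq_len(2^m)) {
        r <- ratAdd(rational(v1$num[s], v1$den[s]),
                    rational(v2$num[s], v2$den[s]))
        sumNum[s] <- r$num; sumDen[s] <- r$den
      }
      sh1 <- .shapleyFromValues(v1$num, v1$den, m)
      sh2 <- .shapleyFromValues(v2$num, v2$den, m)
      shS <- .shapleyFromValues(sumNum, sumDen, m)
      ok <- TRUE
      for (b in seq_len(m)) {
        r <- ratAdd(rational(sh1$num[b], sh1$den[b]),
                    rational(sh2$num[b], sh2$den[b]))
        if (r$num != shS$num[b] || r$den != shS$den[b]) { ok <- FALSE; break }
      }
      if (!ok) { additivity <- FALSE; break }
    }
  }

  out <- list(efficiency = efficiency, superfluous = superfluous,
              anonymity = anonymity, additivity = additivity)
  out$all_pass <- all(unlist(out))
  out
}

## Characteristic function of a network's game over subsets of `linkKeys`
## (a superset of the network's links), as exact rationals indexed mask+1.
.characteristicArray <- function(net, linkKeys) {
  m <- length(linkKeys)
  players <- activePlayers(net)
  n <- length(players)
  masks <- vapply(players, function(i) {
    sum(bitwShiftL(1L, which(linkKeys %in% geneStar(net, i)) - 1L))
  }, numeric(1))
  S <- 0:(2^m - 1L)
  counts <- integer(2^m)
  for (mk in masks) counts <- counts + as.integer(bitwAnd(S, mk) == mk)
  red <- rational(counts, rep(n, 2^m))
  list(num = red$num, den = red$den)
}

#' Generate a random co-expression network
#'
#' Utility for property-based testing and the axiom battery: draws a random
#' network with the requested gene and link counts, optionally guaranteed
#' connected (random spanning tree first, then extra links). Uses the current
#' RNG state; call \code{set.seed} for reproducibility.
#'
#' @param nGenes number of genes.
#' @param nLinks number of links; when \code{connected}, at least
#'   \code{nGenes - 1} and at most \code{choose(nGenes, 2)}.
#' @param connected logical; force a connected network (default TRUE).
#' @param nodes optional gene ids (length \code{nGenes}).
#' @return a \code{CoexpressionNetwork}.
#' @examples
#' set.seed(7)
#' randomNetwork(5, 6)
#' @export
randomNetwork <- function(nGenes, nLinks, connected = TRUE, nodes = NULL) {
  if (is.null(nodes)) nodes <- sprintf("g%02d", seq_len(nGenes))
  stopifnot(length(nodes) == nGenes, nLinks <= choose(nGenes, 2L))
  edges <- matrix(character(), 0L, 2L)
  if (connected) {
    stopifnot(nLinks >= nGenes - 1L)
    ord <- sample(nodes)
    for (k in seq_len(nGenes - 1L)) {
      j <- if (k == 1L) 1L else sample.int(k, 1L)
      edges <- rbind(edges, c(ord[k + 1L], ord[j]))
    }
  }
  have <- function(e) paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]),
                            sep = "|")
  pairs <- utils::combn(sort(nodes), 2L)
  allKeys <- paste(pairs[1L, ], pairs[2L, ], sep = "|")
  spare <- setdiff(allKeys, if (nrow(edges)) have(edges) else character())
  extraN <- nLinks - nrow(edges)
  if (extraN > 0L) {
    pick <- sample(spare, extraN)
    edges <- rbind(edges, do.call(rbind, strsplit(pick, "|", fixed = TRUE)))
  }
  coexpressionNetwork(edges, nodes = nodes)
}
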