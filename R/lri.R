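## Assemble an LRIScoreTable from per-gene rational scores.
## Rows sort descending by score then lexicographically by gene; tied scores
## (exact rational equality) share a min-rank.
.makeScoreTable <- function(genes, num, den, degree, method,
                            includeIsolated = TRUE) {
  stopifnot(length(genes) == length(num), length(num) == length(den))
  keep <- if (includeIsolated) rep(TRUE, length(genes)) else degree > 0L
  genes <- genes[keep]; num <- num[keep]; den <- den[keep]
  degree <- degree[keep]
  val <- num / den
  ord <- order(-val, genes)
  genes <- genes[ord]; num <- num[ord]; den <- den[ord]
  degree <- degree[ord]; val <- val[ord]
  if (length(genes)) {
    same <- c(FALSE, num[-1L] == num[-length(num)] &
                     den[-1L] == den[-length(den)])
    rk <- integer(length(genes))
    for (k in seq_along(genes)) rk[k] <- if (same[k]) rk[k - 1L] else k
  } else rk <- integer()
  tb <- data.frame(gene = genes, num = num, den = den, lri = val,
                   degree = as.integer(degree), rank = rk,
                   stringsAsFactors = FALSE, row.names = NULL)
  new("LRIScoreTable", table = tb, method = method)
}

.emptyScoreTable <- function(network, method, includeIsolated) {
  warning("network has no links; all LRI scores are zero")
  genes <- if (includeIsolated) networkNodes(network) else character()
  n <- length(genes)
  .makeScoreTable(genes, rep(0, n), rep(1, n), rep(0L, n), method)
}

#' Link Relevance Index (LRI) of every gene
#'
#' The LRI is the position value of the microarray network game: each gene
#' receives half of the Shapley value of each of its links. Two equivalent
#' direct implementations are provided, both in exact rational arithmetic.
#'
#' \code{lriClosed} uses the closed form
#' \deqn{F_i = \frac{1}{2\,n(g^E)}\Big(1 + \sum_{j \in N_i(g^E)}
#'   \frac{1}{n_j(g^E)}\Big),}
#' where \eqn{N_i(g^E)} are the neighbours of gene \eqn{i} and
#' \eqn{n_j(g^E)} is the neighbour count (degree) of gene \eqn{j}.
#'
#' \code{lriSum} evaluates the star-sum form: the allocation restricted to
#' the unanimity decomposition, summing over every gene \eqn{j} whose star
#' touches \eqn{i} the ratio of \eqn{i}'s incidences within \eqn{j}'s star to
#' twice the star size, scaled by \eqn{1/n(g^E)}. Here the index set
#' \eqn{N(g_i^E)} is read as the genes incident to \eqn{i}'s star
#' \emph{including \eqn{i} itself}, which is what makes the two forms agree.
#'
#' Isolated genes score exactly 0; every linked gene scores at least
#' \eqn{1/(2 n(g^E))}; for a network with at least one link the scores sum
#' exactly to 1 (efficiency).
#'
#' @param x a \code{CoexpressionNetwork}.
#' @param includeIsolated logical; keep genes without links in the table
#'   with score 0 (default \code{TRUE}) or drop them.
#' @param ... unused.
#' @return an \linkS4class{LRIScoreTable}.
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' scoreTable(lriClosed(net))   # scores 3/8, 11/48, 11/48, 1/6
#' @export
setMethod("lriClosed", "CoexpressionNetwork",
          function(x, includeIsolated = TRUE, ...) {
  genes <- networkNodes(x)
  deg <- geneDegree(x)
  n <- nActive(x)
  if (n == 0L) return(.emptyScoreTable(x, "closed", includeIsolated))
  e <- networkEdges(x)
  num <- numeric(length(genes)); den <- rep(1, length(genes))
  names(num) <- names(den) <- genes
  for (i in genes[deg > 0L]) {
    nbr <- c(e[e[, 1L] == i, 2L], e[e[, 2L] == i, 1L])
    s <- ratSum(rational(rep(1, length(nbr)), deg[nbr]))
    f <- ratMul(ratAdd(rational(1, 1), s), rational(1, 2 * n))
    num[i] <- f$num; den[i] <- f$den
  }
  .makeScoreTable(genes, num, den, deg, "closed", includeIsolated)
})

#' @rdname lriScores
#' @export
setMethod("lriSum", "CoexpressionNetwork",
          function(x, includeIsolated = TRUE, ...) {
  genes <- networkNodes(x)
  deg <- geneDegree(x)
  n <- nActive(x)
  if (n == 0L) return(.emptyScoreTable(x, "sum", includeIsolated))
  stars <- lapply(genes, function(g) geneStar(x, g))
  names(stars) <- genes
  num <- numeric(length(genes)); den <- rep(1, length(genes))
  names(num) <- names(den) <- genes
  for (i in genes[deg > 0L]) {
    ## genes incident to i's star, including i itself
    touching <- unique(unlist(strsplit(stars[[i]], "|", fixed = TRUE)))
    terms <- rational(0, 1)
    acc <- rational(0, 1)
    for (j in touching) {
      starJ <- stars[[j]]
      ## incidences of i within star(j)
      ends <- strsplit(starJ, "|", fixed = TRUE)
      inc <- sum(vapply(ends, function(p) i %in% p, logical(1)))
      acc <- ratAdd(acc, rational(inc, 2 * length(starJ)))
    }
    f <- ratMul(acc, rational(1, n))
    num[i] <- f$num; den[i] <- f$den
  }
  .makeScoreTable(genes, num, den, deg, "sum", includeIsolated)
})

#' @rdname LRIScoreTable-class
#' @export
setMethod("scoreTable", "LRIScoreTable", function(x) x@table)

#' @rdname LRIScoreTable-class
#' @export
setMethod("lriScores", "LRIScoreTable", function(x) {
  out <- x@table$lri
  names(out) <- x@table$gene
  out
})

#' Exact fraction strings of an LRI score table
#'
#' @param x an \code{LRIScoreTable}.
#' @return named character vector like \code{"11/48"}, in table order.
#' @export
lriFractions <- function(x) {
  stopifnot(is(x, "LRIScoreTable"))
  out <- ratFormat(list(num = x@table$num, den = x@table$den))
  names(out) <- x@table$gene
  out
}

setMethod("show", "LRIScoreTable", function(object) {
  tb <- object@table
  cat("LRIScoreTable (", object@method, " form): ", nrow(tb), " genes, ",
      sum(tb$lri > 0), " with positive score\n", sep = "")
  if (nrow(tb)) {
    head_tb <- utils::head(tb, 6L)
    head_tb$exact <- ratFormat(list(num = head_tb$num, den = head_tb$den))
    print(head_tb[, c("gene", "exact", "lri", "degree", "rank")],
          row.names = FALSE)
    if (nrow(tb) > 6L) cat("...\n")
  }
})
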