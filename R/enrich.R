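#' Right-sided hypergeometric gene-set enrichment
#'
#' For each set in the collection, the right-tail hypergeometric probability
#' of observing at least the seen overlap between the query list and the set,
#' given the universe size: \eqn{P(X \ge k)} with \eqn{X \sim
#' \mathrm{Hypergeom}(K, N - K, n)} for term size \eqn{K}, universe
#' \eqn{N} and query size \eqn{n}. P-values are Benjamini-Hochberg adjusted
#' across all tested terms; terms whose overlap falls below \code{minGenes}
#' are dropped from the result.
#'
#' @param query character vector of gene ids; must all lie in the
#'   collection's universe.
#' @param sets a \code{GeneSetCollection}.
#' @param alpha significance cutoff recorded in the result (default 0.05);
#'   rows are returned regardless so the caller can inspect near-misses.
#' @param minGenes minimum overlap per reported term, default 3.
#' @return data.frame with columns \code{term}, \code{overlap},
#'   \code{term_size}, \code{query_size}, \code{universe_size},
#'   \code{pvalue}, \code{adj_pvalue}, \code{significant}, \code{genes}
#'   (comma-joined overlap), sorted by adjusted p.
#' @examples
#' uni <- paste0("g", 1:20)
#' gsc <- geneSetCollection(list(T1 = uni[1:5]), universe = uni)
#' hypergeomEnrichment(uni[c(1:4, 20)], gsc, minGenes = 3)
#' @export
hypergeomEnrichment <- function(query, sets, alpha = 0.05, minGenes = 3L) {
  stopifnot(is(sets, "GeneSetCollection"))
  if (minGenes < 1L) stop("minGenes must be >= 1")
  query <- unique(trimws(query))
  uni <- geneUniverse(sets)
  offenders <- setdiff(query, uni)
  if (length(offenders))
    stop("query gene(s) absent from universe: ",
         paste(offenders, collapse = ", "))
  N <- length(uni)
  n <- length(query)
  rows <- lapply(names(geneSets(sets)), function(nm) {
    members <- intersect(geneSets(sets)[[nm]], uni)
    K <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, overlap = k, term_size = K, query_size = n,
               universe_size = N, pvalue = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_pvalue <- bhAdjust(out$pvalue)
  out <- out[out$overlap >= minGenes, , drop = FALSE]
  out$significant <- out$adj_pvalue <= alpha
  out <- out[order(out$adj_pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "overlap", "term_size", "query_size", "universe_size",
          "pvalue", "adj_pvalue", "significant", "genes")]
}

#' Cohen's kappa between two terms' gene memberships
#'
#' Agreement between the indicator vectors of two gene sets over a common
#' universe: \eqn{\kappa = (P_o - P_e) / (1 - P_e)} with observed agreement
#' \eqn{P_o} and chance agreement \eqn{P_e} from the 2x2 membership table.
#' Identical terms give 1 (including the degenerate case of both terms equal
#' to the whole universe, where \eqn{P_e = 1}).
#'
#' @param termA,termB character vectors of gene ids, subsets of
#'   \code{universe}.
#' @param universe background gene ids.
#' @return numeric kappa in \eqn{[-1, 1]}.
#' @examples
#' uni <- paste0("g", 1:100)
#' termKappa(uni[1:5], uni[6:10], uni)   # about -0.053
#' @export
termKappa <- function(termA, termB, universe) {
  termA <- unique(termA); termB <- unique(termB)
  universe <- unique(universe)
  bad <- c(setdiff(termA, universe), setdiff(termB, universe))
  if (length(bad))
    stop("term gene(s) outside universe: ", paste(bad, collapse = ", "))
  inA <- universe %in% termA
  inB <- universe %in% termB
  if (setequal(termA, termB)) return(1)
  N <- length(universe)
  po <- sum(inA == inB) / N
  pe <- (sum(inA) * sum(inB) + sum(!inA) * sum(!inB)) / N^2
  if (pe == 1) stop("degenerate kappa: chance agreement is 1 for non-identical terms")
  (po - pe) / (1 - pe)
}

#' Group enriched terms by kappa agreement
#'
#' Single-linkage grouping of terms whose pairwise membership kappa reaches
#' the threshold (the term-network grouping rule, default 0.4): terms joined
#' by any chain of pairs with \eqn{\kappa \ge} \code{kappa} share a group.
#'
#' @param termNames character vector of set names to group.
#' @param sets a \code{GeneSetCollection} containing them.
#' @param kappa agreement threshold, default 0.4.
#' @return integer vector of group ids, named by term.
#' @export
groupTermsByKappa <- function(termNames, sets, kappa = 0.4) {
  stopifnot(is(sets, "GeneSetCollection"))
  missing <- setdiff(termNames, names(geneSets(sets)))
  if (length(missing))
    stop("unknown term(s): ", paste(missing, collapse = ", "))
  uni <- geneUniverse(sets)
  k <- length(termNames)
  group <- seq_len(k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      kp <- termKappa(geneSets(sets)[[termNames[i]]],
                      geneSets(sets)[[termNames[j]]], uni)
      if (kp >= kappa) group[group == group[j]] <- group[i]
    }
  }
  group <- match(group, unique(group))
  names(group) <- termNames
  group
}
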