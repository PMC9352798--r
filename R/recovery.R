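#' Recovery of planted module structure by LRI rank
#'
#' Rank-based scoring of how well the LRI recovered the simulator's planted
#' module genes: the area under the ROC curve of module membership against
#' LRI score (Mann-Whitney form, ties averaged), precision among the top-k
#' genes for k equal to the number of planted module genes, and whether
#' every designated hub gene ranks within the top decile.
#'
#' @param scores an \code{LRIScoreTable} computed on a network built from
#'   the simulated matrices.
#' @param truth the matching \code{SyntheticTruth}.
#' @return list with \code{auc}, \code{top_k_precision}, \code{k},
#'   \code{hubs_in_top_decile} (NA when no hubs were planted).
#' @examples
#' sim <- simulateExperiment(simulationConfig(nGenes = 60, nCase = 30,
#'   nControl = 30, modules = list(list(size = 5, lambda = 3,
#'   activeIn = "case")), nDeg = 0, seed = 7))
#' net <- buildNetwork(sim$mes, threshold = 0.9)
#' recoveryReport(lriClosed(net), sim$truth)
#' @export
recoveryReport <- function(scores, truth) {
  stopifnot(is(scores, "LRIScoreTable"), is(truth, "SyntheticTruth"))
  planted <- unique(unlist(truth@moduleMembers))
  if (!length(planted)) stop("empty truth: no planted module genes")
  tb <- scoreTable(scores)
  pos <- tb$gene %in% planted
  if (!any(pos)) stop("no planted gene appears in the score table")
  npos <- sum(pos); nneg <- sum(!pos)
  if (nneg == 0L) stop("score table contains only planted genes")
  r <- rank(tb$lri)
  auc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  topk <- tb$gene[order(-tb$lri, tb$gene)][seq_len(npos)]
  prec <- mean(topk %in% planted)
  hubFlag <- NA
  if (length(truth@hubGenes)) {
    cutoff <- ceiling(nrow(tb) / 10)
    topDecile <- tb$gene[order(-tb$lri, tb$gene)][seq_len(cutoff)]
    hubFlag <- all(truth@hubGenes %in% topDecile)
  }
  list(auc = auc, top_k_precision = prec, k = npos,
       hubs_in_top_decile = hubFlag)
}
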