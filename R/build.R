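#' Build a co-expression network from a case/control experiment
#'
#' Construction of the link set \eqn{g^E} from expression data. Two
#' deterministic rules are provided:
#' \describe{
#'   \item{case-correlation}{link genes \eqn{i,j} when the absolute pairwise
#'     correlation of their rows over the \emph{case} samples reaches the
#'     threshold, \eqn{|r_{ij}| \ge \tau};}
#'   \item{differential-correlation}{link when the absolute difference
#'     between the case and control correlations reaches the threshold,
#'     \eqn{|r^{case}_{ij} - r^{control}_{ij}| \ge \tau}.}
#' }
#' Genes whose variance (in every matrix the rule uses) falls below
#' \code{minVariance}, and zero-variance genes (correlation undefined), are
#' left isolated and reported with a warning. Raising \eqn{\tau} can only
#' remove links (monotonicity), and identical inputs give identical link
#' lists.
#'
#' @param mes a \code{MicroarrayExperimentSituation}.
#' @param method \code{"case-correlation"} (default) or
#'   \code{"differential-correlation"}.
#' @param correlation \code{"pearson"} (default) or \code{"spearman"}.
#' @param threshold absolute-correlation cutoff \eqn{\tau} in (0, 1],
#'   default 0.9.
#' @param minVariance per-gene variance floor, default 0.
#' @param geneSubset optional gene ids to restrict the construction to;
#'   other genes stay isolated.
#' @return a \code{CoexpressionNetwork} over all genes of \code{mes}
#'   (non-passing genes isolated).
#' @examples
#' cs <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),
#'             g3 = c(1, -1, -1, 1))
#' colnames(cs) <- paste0("d", 1:4)
#' ct <- cs; colnames(ct) <- paste0("r", 1:4)
#' mes <- microarrayExperimentSituation(cs, ct)
#' buildNetwork(mes, threshold = 0.9)   # one link: g1--g2
#' @export
buildNetwork <- function(mes,
                         method = c("case-correlation",
                                    "differential-correlation"),
                         correlation = c("pearson", "spearman"),
                         threshold = 0.9, minVariance = 0,
                         geneSubset = NULL) {
  stopifnot(is(mes, "MicroarrayExperimentSituation"))
  method <- match.arg(method)
  correlation <- match.arg(correlation)
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]")
  if (minVariance < 0) stop("minVariance must be >= 0")
  genes <- rownames(mes)
  cse <- caseMatrix(mes)
  if (ncol(cse) < 3L)
    stop("insufficient data: need >= 3 case samples for correlation")
  mats <- list(cse)
  if (method == "differential-correlation") {
    ctl <- controlMatrix(mes)
    if (ncol(ctl) < 3L)
      stop("insufficient data: need >= 3 control samples for correlation")
    mats <- c(mats, list(ctl))
  }

  use <- rep(TRUE, length(genes))
  names(use) <- genes
  if (!is.null(geneSubset)) {
    unknown <- setdiff(geneSubset, genes)
    if (length(unknown))
      stop("geneSubset gene(s) not in experiment: ",
           paste(unknown, collapse = ", "))
    use <- use & genes %in% geneSubset
  }
  vars <- lapply(mats, function(m) apply(m, 1L, stats::var))
  lowVar <- Reduce(`|`, lapply(vars, function(v) v < minVariance | v == 0))
  if (any(lowVar & use))
    warning(sum(lowVar & use),
            " gene(s) below the variance floor or constant; left isolated")
  use <- use & !lowVar

  keep <- genes[use]
  if (length(keep) < 2L)
    return(coexpressionNetwork(matrix(character(), 0L, 2L), nodes = genes))

  cors <- lapply(mats, function(m)
    stats::cor(t(m[keep, , drop = FALSE]), method = correlation))
  score <- if (method == "case-correlation") abs(cors[[1L]])
           else abs(cors[[1L]] - cors[[2L]])
  score[lower.tri(score, diag = TRUE)] <- NA_real_
  hit <- which(score >= threshold, arr.ind = TRUE)
  edges <- cbind(keep[hit[, 1L]], keep[hit[, 2L]])
  coexpressionNetwork(edges, nodes = genes)
}
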