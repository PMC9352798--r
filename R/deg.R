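#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper over the step-up false-discovery-rate procedure
#' (\code{stats::p.adjust(method = "BH")}): sort ascending, scale the k-th
#' smallest p by m/k, enforce monotonicity from the largest down, cap at 1,
#' return in input order.
#'
#' @param pvalues numeric vector of p-values in \eqn{[0, 1]}.
#' @return adjusted p-values, same order and length.
#' @examples
#' bhAdjust(c(0.01, 0.04, 0.03, 0.02))   # all 0.04
#' @export
bhAdjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numbers in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential expression by per-gene Welch test
#'
#' The conventional comparison arm: for each gene, a two-sided Welch
#' two-sample t-test of case versus control log2 values (unequal variances,
#' Welch-Satterthwaite degrees of freedom), the log2 fold change as the
#' difference of group means (case minus control), Benjamini-Hochberg
#' adjustment across all genes, and the dual DEG filter: adjusted
#' p \eqn{\le} \code{alpha} and \eqn{|LFC| \ge} \code{lfcMin}. Genes with
#' zero variance in both groups and zero fold change get p = 1 with a
#' warning (no evidence either way).
#'
#' @param mes a \code{MicroarrayExperimentSituation} with at least 2 samples
#'   per group.
#' @param alpha adjusted-p cutoff, default 0.05.
#' @param lfcMin absolute log2-fold-change cutoff, default 2.
#' @return data.frame with columns \code{gene}, \code{lfc}, \code{t},
#'   \code{pvalue}, \code{adj_pvalue}, \code{is_deg}, in the gene order of
#'   \code{mes}.
#' @examples
#' set.seed(1)
#' cs <- matrix(rnorm(40, 8), 2, 20,
#'              dimnames = list(c("flat","up"), paste0("d", 1:20)))
#' ct <- matrix(rnorm(40, 8), 2, 20,
#'              dimnames = list(c("flat","up"), paste0("r", 1:20)))
#' cs["up", ] <- cs["up", ] + 3
#' computeDeg(microarrayExperimentSituation(cs, ct))
#' @export
computeDeg <- function(mes, alpha = 0.05, lfcMin = 2) {
  stopifnot(is(mes, "MicroarrayExperimentSituation"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (lfcMin < 0) stop("lfcMin must be >= 0")
  a <- caseMatrix(mes); b <- controlMatrix(mes)
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L)
    stop("insufficient data: need >= 2 samples per group")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    if (any(degenerate & lfc == 0)) {
      warning(sum(degenerate & lfc == 0),
              " gene(s) with zero variance and zero fold change; p set to 1")
      p[degenerate & lfc == 0] <- 1
      tstat[degenerate & lfc == 0] <- 0
    }
    ## zero variance but nonzero shift: infinitely strong evidence
    p[degenerate & lfc != 0] <- 0
  }
  adj <- bhAdjust(p)
  data.frame(gene = rownames(mes), lfc = lfc, t = tstat, pvalue = p,
             adj_pvalue = adj,
             is_deg = adj <= alpha & abs(lfc) >= lfcMin,
             stringsAsFactors = FALSE, row.names = NULL)
}
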