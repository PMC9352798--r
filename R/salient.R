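#' Select salient genes from an LRI score table
#'
#' Salient genes are those with LRI strictly above the threshold (default 0,
#' so every gene incident to at least one co-expression link qualifies).
#' Ordered descending by score, ties by gene id.
#'
#' @param scores an \code{LRIScoreTable}.
#' @param threshold minimum score, strict inequality; default 0.
#' @return character vector of gene ids.
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' selectSalient(lriClosed(net))            # all four genes
#' selectSalient(lriClosed(net), 0.3)       # gene "1" only
#' @export
selectSalient <- function(scores, threshold = 0) {
  stopifnot(is(scores, "LRIScoreTable"))
  if (threshold < 0) stop("threshold must be >= 0")
  tb <- scoreTable(scores)
  tb$gene[tb$lri > threshold]
}

#' Distribution summary of positive LRI scores
#'
#' Order statistics of the salient (positive) scores; zero scores are
#' excluded by contract since they mark genes outside the network.
#'
#' @param scores an \code{LRIScoreTable}.
#' @return list with \code{count}, \code{mean}, \code{median}, \code{q1},
#'   \code{q3}, \code{min}, \code{max} of the positive scores (empty list
#'   fields \code{count = 0} with a warning when none are positive).
#' @examples
#' net <- coexpressionNetwork(rbind(c("1","2"), c("1","3"),
#'                                  c("1","4"), c("2","3")))
#' scoreDistribution(lriClosed(net))
#' @export
scoreDistribution <- function(scores) {
  stopifnot(is(scores, "LRIScoreTable"))
  v <- scoreTable(scores)$lri
  v <- v[v > 0]
  if (!length(v)) {
    warning("no positive LRI scores; empty distribution summary")
    return(list(count = 0L, mean = NA_real_, median = NA_real_,
                q1 = NA_real_, q3 = NA_real_, min = NA_real_,
                max = NA_real_))
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(count = length(v), mean = mean(v), median = q[2L],
       q1 = q[1L], q3 = q[3L], min = min(v), max = max(v))
}

#' Plot the distribution of positive LRI scores
#'
#' Violin, normal Q-Q and histogram views of the positive scores, as a
#' patchable list of ggplot objects (requires ggplot2).
#'
#' @param scores an \code{LRIScoreTable}.
#' @return named list of ggplot objects (\code{violin}, \code{qq},
#'   \code{histogram}).
#' @export
plotScoreDistribution <- function(scores) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  stopifnot(is(scores, "LRIScoreTable"))
  v <- scoreTable(scores)$lri
  df <- data.frame(lri = v[v > 0])
  if (!nrow(df)) stop("no positive LRI scores to plot")
  list(
    violin = ggplot2::ggplot(df, ggplot2::aes(x = "", y = lri)) +
      ggplot2::geom_violin() + ggplot2::geom_jitter(width = 0.05, size = 0.6) +
      ggplot2::labs(x = NULL, y = "LRI"),
    qq = ggplot2::ggplot(df, ggplot2::aes(sample = lri)) +
      ggplot2::stat_qq() + ggplot2::stat_qq_line(),
    histogram = ggplot2::ggplot(df, ggplot2::aes(x = lri)) +
      ggplot2::geom_histogram(bins = 30) + ggplot2::labs(x = "LRI"))
}

#' Overlap between two gene lists
#'
#' Set comparison after id normalisation (whitespace trim; optional case
#' folding). Intended for comparing salient genes against marker lists or
#' DEG lists.
#'
#' @param a,b character vectors of gene ids.
#' @param caseFold lower-case ids before comparing (default FALSE).
#' @return list with \code{n_common}, \code{n_a_only}, \code{n_b_only} and
#'   the sorted \code{common} members.
#' @examples
#' setOverlap(c("ITGA5", "MCAM", "TOP2A"), c("ITGA5", "MCAM", "KRAS"))
#' @export
setOverlap <- function(a, b, caseFold = FALSE) {
  norm <- function(x) {
    x <- trimws(as.character(x))
    if (caseFold) x <- tolower(x)
    unique(x[nzchar(x)])
  }
  a <- norm(a); b <- norm(b)
  common <- sort(intersect(a, b))
  list(n_common = length(common), n_a_only = length(setdiff(a, b)),
       n_b_only = length(setdiff(b, a)), common = common)
}
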