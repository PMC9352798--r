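#' Construct a MicroarrayExperimentSituation
#'
#' Assembles the case/control expression tuple from two genes-by-samples
#' log2 matrices with matching row (gene) order, or from a single matrix plus
#' a group factor.
#'
#' @param caseMatrix genes x case-samples numeric matrix (log2 scale), with
#'   rownames (genes) and colnames (sample ids).
#' @param controlMatrix genes x control-samples numeric matrix, same genes in
#'   the same order.
#' @return a \linkS4class{MicroarrayExperimentSituation}.
#' @examples
#' set.seed(1)
#' cs <- matrix(rnorm(12, 8), 3, 4,
#'              dimnames = list(c("a","b","c"), paste0("d", 1:4)))
#' ct <- matrix(rnorm(12, 8), 3, 4,
#'              dimnames = list(c("a","b","c"), paste0("r", 1:4)))
#' mes <- microarrayExperimentSituation(cs, ct)
#' caseSamples(mes)
#' @export
microarrayExperimentSituation <- function(caseMatrix, controlMatrix) {
  caseMatrix <- as.matrix(caseMatrix)
  controlMatrix <- as.matrix(controlMatrix)
  if (is.null(rownames(caseMatrix)) || is.null(rownames(controlMatrix)))
    stop("matrices must carry gene ids as rownames")
  if (!identical(rownames(caseMatrix), rownames(controlMatrix)))
    stop("case and control matrices must have identical gene rows")
  if (is.null(colnames(caseMatrix)) || is.null(colnames(controlMatrix)))
    stop("matrices must carry sample ids as colnames")
  shared <- intersect(colnames(caseMatrix), colnames(controlMatrix))
  if (length(shared))
    stop("case and control sample sets overlap: ",
         paste(shared, collapse = ", "))
  a <- cbind(caseMatrix, controlMatrix)
  if (!all(is.finite(a)))
    stop("expression values must all be finite (no NA/NaN/Inf)")
  grp <- c(rep("case", ncol(caseMatrix)), rep("control", ncol(controlMatrix)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = a),
    colData = S4Vectors::DataFrame(group = grp, row.names = colnames(a)))
  new("MicroarrayExperimentSituation", se)
}

#' @rdname MicroarrayExperimentSituation-class
#' @export
setMethod("caseSamples", "MicroarrayExperimentSituation", function(x) {
  colnames(x)[SummarizedExperiment::colData(x)$group == "case"]
})

#' @rdname MicroarrayExperimentSituation-class
#' @export
setMethod("controlSamples", "MicroarrayExperimentSituation", function(x) {
  colnames(x)[SummarizedExperiment::colData(x)$group == "control"]
})

#' @rdname MicroarrayExperimentSituation-class
#' @export
setMethod("caseMatrix", "MicroarrayExperimentSituation", function(x) {
  SummarizedExperiment::assay(x, "log2")[, caseSamples(x), drop = FALSE]
})

#' @rdname MicroarrayExperimentSituation-class
#' @export
setMethod("controlMatrix", "MicroarrayExperimentSituation", function(x) {
  SummarizedExperiment::assay(x, "log2")[, controlSamples(x), drop = FALSE]
})

setMethod("show", "MicroarrayExperimentSituation", function(object) {
  cat("MicroarrayExperimentSituation:", nrow(object), "genes;",
      length(caseSamples(object)), "case /",
      length(controlSamples(object)), "control samples\n")
})
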