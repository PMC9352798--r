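## Interchange formats. All tables are TSV, UTF-8, LF endings, '#' comments,
## with a header row; gene identifiers are opaque strings (any symbol/Entrez
## mapping is the caller's responsibility).

.checkRagged <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row in ", path, " at (non-comment) line ", bad + 1L)
  }
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column \code{gene} (unique ids), remaining columns one per sample
#' (unique ids in the header); genes in rows and samples in columns. Lines
#' starting with \code{#} are comments.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpression <- function(path) {
  .checkRagged(path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression file needs a gene column and >= 1 sample")
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at gene ", genes[bad[1L]],
         ", sample ", samples[bad[2L]])
  }
  vals
}

#' Write a genes-by-samples expression matrix to TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(mat, path) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns \code{sample} and \code{group}, with group values \code{case} or
#' \code{control}.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{sample}, \code{group}.
#' @export
readMetadata <- function(path) {
  .checkRagged(path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (!all(c("sample", "group") %in% colnames(df)))
    stop("metadata must have columns 'sample' and 'group'")
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s) in metadata")
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad))
    stop("group values must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  df[, c("sample", "group")]
}

#' Assemble an experiment situation from expression + metadata files
#'
#' @param exprPath expression TSV (see [readExpression()]).
#' @param metaPath metadata TSV (see [readMetadata()]).
#' @return a \code{MicroarrayExperimentSituation} restricted to the samples
#'   listed in the metadata.
#' @export
readExperiment <- function(exprPath, metaPath) {
  mat <- readExpression(exprPath)
  meta <- readMetadata(metaPath)
  missing <- setdiff(meta$sample, colnames(mat))
  if (length(missing))
    stop("metadata sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  caseIds <- meta$sample[meta$group == "case"]
  ctlIds <- meta$sample[meta$group == "control"]
  microarrayExperimentSituation(mat[, caseIds, drop = FALSE],
                                mat[, ctlIds, drop = FALSE])
}

#' Read an edge list from TSV
#'
#' Two columns \code{gene_a}, \code{gene_b} (header optional); \code{#}
#' comments allowed; pairs are canonicalised to lexicographic order.
#'
#' @param path TSV file path.
#' @param nodes optional node set passed to [coexpressionNetwork()].
#' @return a \code{CoexpressionNetwork}.
#' @export
readEdgeList <- function(path, nodes = NULL) {
  .checkRagged(path)
  first <- utils::read.delim(path, header = FALSE, sep = "\t", nrows = 1L,
                             comment.char = "#", colClasses = "character",
                             quote = "")
  header <- identical(tolower(unlist(first, use.names = FALSE)),
                      c("gene_a", "gene_b"))
  df <- utils::read.delim(path, header = header, sep = "\t",
                          comment.char = "#", colClasses = "character",
                          quote = "")
  if (ncol(df) != 2L) stop("edge list must have exactly two columns")
  coexpressionNetwork(as.matrix(df), nodes = nodes)
}

#' Write a network's edge list to TSV
#'
#' @param network a \code{CoexpressionNetwork}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(network, path) {
  stopifnot(is(network, "CoexpressionNetwork"))
  e <- networkEdges(network)
  df <- data.frame(gene_a = e[, 1L], gene_b = e[, 2L],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write an LRI score table to TSV
#'
#' Columns \code{gene}, \code{lri_exact} (fraction string),
#' \code{lri_float} (rounded to \code{precision} decimals), \code{degree},
#' \code{rank}, sorted descending by score.
#'
#' @param scores an \code{LRIScoreTable}.
#' @param path output path.
#' @param precision decimals for the float view, default 6.
#' @return invisibly, \code{path}.
#' @export
writeScoreTable <- function(scores, path, precision = 6L) {
  stopifnot(is(scores, "LRIScoreTable"))
  tb <- scoreTable(scores)
  df <- data.frame(gene = tb$gene,
                   lri_exact = ratFormat(list(num = tb$num, den = tb$den)),
                   lri_float = formatC(tb$lri, digits = precision,
                                       format = "f"),
                   degree = tb$degree, rank = tb$rank,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read an LRI score table written by [writeScoreTable()]
#'
#' Reconstructs the exact rational scores from the fraction strings.
#'
#' @param path TSV file path.
#' @return an \code{LRIScoreTable} (method \code{"file"}).
#' @export
readScoreTable <- function(path) {
  .checkRagged(path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", quote = "")
  need <- c("gene", "lri_exact", "lri_float", "degree", "rank")
  if (!all(need %in% colnames(df)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  frac <- strsplit(df$lri_exact, "/", fixed = TRUE)
  num <- vapply(frac, function(p) as.numeric(p[1L]), 1)
  den <- vapply(frac, function(p)
    if (length(p) > 1L) as.numeric(p[2L]) else 1, 1)
  .makeScoreTable(df$gene, num, den, as.integer(df$degree), "file")
}

#' Write simulation truth to JSON
#'
#' @param truth a \code{SyntheticTruth}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  jsonlite::write_json(
    list(module_members = truth@moduleMembers,
         hub_genes = truth@hubGenes, deg_genes = truth@degGenes,
         module_correlation = truth@moduleCorrelation),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read simulation truth written by [writeTruth()]
#'
#' @param path JSON file path.
#' @return a \code{SyntheticTruth}.
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mm <- as.list(x$module_members)
  mm <- lapply(mm, as.character)
  new("SyntheticTruth", moduleMembers = mm,
      hubGenes = as.character(x$hub_genes),
      degGenes = as.character(x$deg_genes),
      moduleCorrelation = as.numeric(x$module_correlation))
}
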