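#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (gene ids per set).
#' @param universe character vector of background gene ids.
#' @param descriptions optional character vector, one per set (defaults to
#'   the set names).
#' @return a \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- geneSetCollection(list(A = c("g1", "g2")), universe = paste0("g", 1:5))
#' geneSets(gsc)
#' @export
geneSetCollection <- function(sets, universe, descriptions = names(sets)) {
  new("GeneSetCollection", sets = sets,
      descriptions = as.character(descriptions),
      universe = as.character(universe))
}

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over a universe of",
      length(object@universe), "genes\n")
})

#' Read gene sets from a GMT file
#'
#' Standard tab-separated gene-set format: one set per line, fields
#' \code{name}, \code{description}, then the member gene ids. Member ids are
#' whitespace-trimmed; empty trailing fields are dropped.
#'
#' @param path GMT file path.
#' @param universe background gene ids for the resulting collection.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, universe) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "))
  nm <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) {
    members <- trimws(p[-(1:2)])
    unique(members[nzchar(members)])
  })
  names(sets) <- nm
  geneSetCollection(sets, universe = universe, descriptions = desc)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a \code{GeneSetCollection}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  lines <- mapply(function(nm, desc, members)
    paste(c(nm, desc, members), collapse = "\t"),
    names(gsc@sets), gsc@descriptions, gsc@sets)
  writeLines(lines, path)
  invisible(path)
}
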