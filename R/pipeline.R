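#' Run the full salient-gene analysis pipeline
#'
#' End-to-end driver: read expression + metadata, build the co-expression
#' network, score genes by LRI (closed form), select salient genes, run the
#' Welch/BH DEG arm, compare the salient list against the DEG list and any
#' supplied marker list, optionally run hypergeometric enrichment against a
#' GMT collection, and write every stage output plus a machine-readable run
#' manifest into \code{outDir}.
#'
#' @param exprPath expression TSV path.
#' @param metaPath metadata TSV path.
#' @param outDir output directory (created if absent).
#' @param network list of [buildNetwork()] settings: \code{method},
#'   \code{correlation}, \code{threshold}, \code{minVariance}.
#' @param deg list of [computeDeg()] settings: \code{alpha}, \code{lfcMin}.
#' @param salientThreshold strict LRI cutoff for salient genes, default 0.
#' @param markersPath optional file of marker gene ids (one per line) to
#'   overlap against.
#' @param enrichment optional list with \code{gmtPath}, \code{universePath}
#'   (one gene id per line), \code{alpha}, \code{minGenes}.
#' @param precision float decimals in the score TSV, default 6.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{network}, \code{scores}, \code{salient}, \code{deg},
#'   \code{overlap_deg}, \code{overlap_markers}, \code{enrichment},
#'   \code{manifest}).
#' @export
runPipeline <- function(exprPath, metaPath, outDir,
                        network = list(), deg = list(),
                        salientThreshold = 0, markersPath = NULL,
                        enrichment = NULL, precision = 6L) {
  for (p in c(exprPath, metaPath, markersPath,
              enrichment$gmtPath, enrichment$universePath))
    if (!is.null(p) && !file.exists(p))
      stop("input file does not exist: ", p)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  mes <- tick("read", readExperiment(exprPath, metaPath))
  net <- tick("build", do.call(buildNetwork, c(list(mes = mes), network)))
  writeEdgeList(net, file.path(outDir, "edges.tsv"))
  scores <- tick("score", lriClosed(net))
  writeScoreTable(scores, file.path(outDir, "scores.tsv"),
                  precision = precision)
  salient <- tick("salient", selectSalient(scores, salientThreshold))
  writeLines(salient, file.path(outDir, "salient.txt"))
  degTab <- tick("deg", do.call(computeDeg, c(list(mes = mes), deg)))
  utils::write.table(degTab, file.path(outDir, "deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  ovDeg <- setOverlap(salient, degTab$gene[degTab$is_deg])
  jsonlite::write_json(ovDeg, file.path(outDir, "overlap_deg.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ovMark <- NULL
  if (!is.null(markersPath)) {
    markers <- trimws(readLines(markersPath, warn = FALSE))
    ovMark <- setOverlap(salient, markers[nzchar(markers)])
    jsonlite::write_json(ovMark, file.path(outDir, "overlap_markers.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  enr <- NULL
  if (!is.null(enrichment)) {
    uniLines <- trimws(readLines(enrichment$universePath, warn = FALSE))
    gsc <- readGmt(enrichment$gmtPath, universe = uniLines[nzchar(uniLines)])
    enr <- tick("enrich", hypergeomEnrichment(
      intersect(salient, geneUniverse(gsc)), gsc,
      alpha = enrichment$alpha %||% 0.05,
      minGenes = enrichment$minGenes %||% 3L))
    utils::write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
  }

  cfg <- list(exprPath = exprPath, metaPath = metaPath, network = network,
              deg = deg, salientThreshold = salientThreshold,
              precision = precision)
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfgJson), tmp)
  manifest <- list(
    package = "lriNet",
    version = as.character(utils::packageVersion("lriNet")),
    config = cfg,
    config_hash = unname(tools::md5sum(tmp)),
    counts = list(genes = nrow(mes),
                  case_samples = length(caseSamples(mes)),
                  control_samples = length(controlSamples(mes)),
                  edges = nrow(networkEdges(net)),
                  salient = length(salient),
                  deg = sum(degTab$is_deg)),
    timings_sec = timings)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(network = net, scores = scores, salient = salient,
                 deg = degTab, overlap_deg = ovDeg, overlap_markers = ovMark,
                 enrichment = enr, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
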