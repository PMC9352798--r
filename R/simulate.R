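#' Simulation configuration for synthetic case/control experiments
#'
#' Validates and assembles the generator settings. The defaults describe the
#' reference simulation used throughout the package's validation: a
#' 1000-gene panel with one 10-gene co-expressed module active in the case
#' group (single latent factor, loading 3 against noise 0.5, giving a
#' population within-module correlation of 36/37), ten background genes
#' carrying a +3 log2 mean shift in cases, and 100 case / 100 control
#' samples on a log2 baseline drawn uniformly from [4, 12].
#'
#' @param nGenes total number of genes.
#' @param nCase,nControl sample counts per group.
#' @param modules list of module descriptors, each a list with \code{size},
#'   \code{lambda} (factor loading, log2 units) and \code{activeIn}
#'   (\code{"case"} or \code{"both"}).
#' @param nDeg number of mean-shifted genes (disjoint from modules).
#' @param shift log2 shift added to case means of DEG genes.
#' @param sigma residual noise SD, log2 units; must be positive.
#' @param baselineRange length-2 range the per-gene baseline means are drawn
#'   from.
#' @param hub logical; when TRUE and at least two modules are configured,
#'   the first gene of the second module also loads on the first module,
#'   making it a designated high-degree hub.
#' @param seed integer RNG seed (mandatory: the generator is fully
#'   reproducible from it).
#' @return validated config (class \code{"lriSimConfig"}).
#' @examples
#' cfg <- simulationConfig(nGenes = 100, nCase = 20, nControl = 20,
#'                         modules = list(list(size = 5, lambda = 3,
#'                                             activeIn = "case")),
#'                         nDeg = 3, seed = 1)
#' @export
simulationConfig <- function(nGenes = 1000L, nCase = 100L, nControl = 100L,
                             modules = list(list(size = 10L, lambda = 3,
                                                 activeIn = "case")),
                             nDeg = 10L, shift = 3, sigma = 0.5,
                             baselineRange = c(4, 12), hub = FALSE,
                             seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  stopifnot(nGenes >= 1L, nCase >= 1L, nControl >= 1L, nDeg >= 0L)
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(baselineRange) != 2L || diff(baselineRange) < 0)
    stop("baselineRange must be an increasing length-2 range")
  for (m in modules) {
    if (!all(c("size", "lambda", "activeIn") %in% names(m)))
      stop("each module needs size, lambda and activeIn")
    if (m$size < 2L) stop("module size must be >= 2")
    if (m$lambda < 0) stop("module lambda must be >= 0")
    if (!m$activeIn %in% c("case", "both"))
      stop("module activeIn must be 'case' or 'both'")
  }
  msize <- sum(vapply(modules, function(m) m$size, 1))
  if (msize + nDeg > nGenes)
    stop("module sizes plus nDeg exceed nGenes")
  structure(list(nGenes = as.integer(nGenes), nCase = as.integer(nCase),
                 nControl = as.integer(nControl), modules = modules,
                 nDeg = as.integer(nDeg), shift = shift, sigma = sigma,
                 baselineRange = baselineRange, hub = isTRUE(hub),
                 seed = as.integer(seed)),
            class = "lriSimConfig")
}

#' Simulate a case/control expression experiment with planted structure
#'
#' Single-factor Gaussian generator. Background gene \eqn{g}, sample
#' \eqn{s}: \eqn{x = \mu_g + \varepsilon} with \eqn{\varepsilon \sim
#' N(0, \sigma^2)} and \eqn{\mu_g} drawn once per gene from the baseline
#' range. A module gene in a group where its module is active gains a shared
#' latent term \eqn{\lambda f_s}, \eqn{f_s \sim N(0, 1)} per sample per
#' module, so any two members correlate at \eqn{\lambda^2 / (\lambda^2 +
#' \sigma^2)} in the population. DEG genes gain \eqn{+\delta} on their case
#' means. The RNG is seeded once from \code{config$seed} and consumed in a
#' fixed order (baselines, factors, noise, shift assignment), so identical
#' configs give byte-identical matrices.
#'
#' @param config an \code{lriSimConfig} from [simulationConfig()].
#' @return list with \code{mes}, a
#'   \linkS4class{MicroarrayExperimentSituation}, and \code{truth}, a
#'   \linkS4class{SyntheticTruth}.
#' @examples
#' sim <- simulateExperiment(simulationConfig(nGenes = 50, nCase = 10,
#'   nControl = 10, modules = list(list(size = 4, lambda = 3,
#'   activeIn = "case")), nDeg = 2, seed = 42))
#' sim$truth@moduleMembers
#' @export
simulateExperiment <- function(config) {
  if (!inherits(config, "lriSimConfig"))
    config <- do.call(simulationConfig, config)
  set.seed(config$seed)
  genes <- sprintf("gene%04d", seq_len(config$nGenes))
  caseIds <- sprintf("case%03d", seq_len(config$nCase))
  ctlIds <- sprintf("ctrl%03d", seq_len(config$nControl))

  ## planted gene assignment: modules from the front, then DEG genes
  cursor <- 0L
  moduleMembers <- list()
  for (k in seq_along(config$modules)) {
    sz <- config$modules[[k]]$size
    moduleMembers[[paste0("module", k)]] <- genes[cursor + seq_len(sz)]
    cursor <- cursor + sz
  }
  hubGenes <- character()
  if (config$hub && length(moduleMembers) >= 2L) {
    hub <- moduleMembers[[2L]][1L]
    moduleMembers[[1L]] <- c(moduleMembers[[1L]], hub)
    hubGenes <- hub
  }
  degGenes <- if (config$nDeg > 0L) genes[cursor + seq_len(config$nDeg)]
              else character()

  mu <- stats::runif(config$nGenes, config$baselineRange[1L],
                     config$baselineRange[2L])
  names(mu) <- genes

  nAll <- config$nCase + config$nControl
  signal <- matrix(0, config$nGenes, nAll,
                   dimnames = list(genes, c(caseIds, ctlIds)))
  for (k in seq_along(config$modules)) {
    mod <- config$modules[[k]]
    f <- stats::rnorm(nAll)                       # one factor per sample
    active <- if (mod$activeIn == "both") rep(TRUE, nAll)
              else c(rep(TRUE, config$nCase), rep(FALSE, config$nControl))
    members <- moduleMembers[[k]]
    signal[members, active] <- signal[members, active] +
      mod$lambda * rep(f[active], each = length(members))
  }
  eps <- matrix(stats::rnorm(config$nGenes * nAll, sd = config$sigma),
                config$nGenes, nAll)
  x <- mu + signal + eps
  if (length(degGenes))
    x[degGenes, seq_len(config$nCase)] <-
      x[degGenes, seq_len(config$nCase)] + config$shift

  mes <- microarrayExperimentSituation(
    x[, caseIds, drop = FALSE], x[, ctlIds, drop = FALSE])
  lam <- vapply(config$modules, function(m) m$lambda, 1)
  truth <- new("SyntheticTruth", moduleMembers = moduleMembers,
               hubGenes = hubGenes, degGenes = degGenes,
               moduleCorrelation = lam^2 / (lam^2 + config$sigma^2))
  list(mes = mes, truth = truth)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@moduleMembers), "module(s),",
      length(unique(unlist(object@moduleMembers))), "module genes,",
      length(object@degGenes), "DEG genes,",
      length(object@hubGenes), "hub(s)\n")
})
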