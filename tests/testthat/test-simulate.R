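smallConfig <- function(seed = 1L, ...) {
  defaults <- list(nGenes = 60L, nCase = 30L, nControl = 30L,
                   modules = list(list(size = 5, lambda = 3,
                                       activeIn = "case")),
                   nDeg = 3L, shift = 3, sigma = 0.5, seed = seed)
  do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

test_that("the generator is byte-identical under a fixed seed", {
  a <- simulateExperiment(smallConfig(seed = 42L))
  b <- simulateExperiment(smallConfig(seed = 42L))
  expect_identical(caseMatrix(a$mes), caseMatrix(b$mes))
  expect_identical(controlMatrix(a$mes), controlMatrix(b$mes))
  expect_identical(a$truth@moduleMembers, b$truth@moduleMembers)
  c <- simulateExperiment(smallConfig(seed = 43L))
  expect_false(identical(caseMatrix(a$mes), caseMatrix(c$mes)))
})

test_that("within-module sample correlation approaches lambda^2/(lambda^2+sigma^2)", {
  cfg <- simulationConfig(nGenes = 20L, nCase = 200L, nControl = 5L,
                          modules = list(list(size = 6, lambda = 3,
                                              activeIn = "case")),
                          nDeg = 0L, sigma = 0.5, seed = 7L)
  sim <- simulateExperiment(cfg)
  expect_equal(sim$truth@moduleCorrelation, 9 / 9.25, tolerance = 1e-12)
  members <- sim$truth@moduleMembers[[1]]
  cm <- cor(t(caseMatrix(sim$mes)[members, ]))
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off - 9 / 9.25) < 0.03))
})

test_that("a structureless simulation yields an edgeless network at tau 0.9", {
  clean <- 0L
  for (s in 1:100) {
    cfg <- simulationConfig(nGenes = 50L, nCase = 50L, nControl = 5L,
                            modules = list(), nDeg = 0L, sigma = 0.5,
                            seed = 1000L + s)
    sim <- simulateExperiment(cfg)
    net <- buildNetwork(sim$mes, threshold = 0.9)
    if (nrow(networkEdges(net)) == 0L) clean <- clean + 1L
  }
  expect_gte(clean, 95L)
})

test_that("planted module edges are recovered and background stays clean", {
  hits <- 0L; falseEdges <- 0L; possible <- 0L
  for (s in 1:5) {
    sim <- simulateExperiment(smallConfig(seed = 500L + s, nCase = 100L))
    net <- buildNetwork(sim$mes, threshold = 0.9)
    members <- sim$truth@moduleMembers[[1]]
    keys <- edgeKeys(net)
    ends <- strsplit(keys, "|", fixed = TRUE)
    inModule <- vapply(ends, function(p) all(p %in% members), logical(1))
    hits <- hits + sum(inModule)
    falseEdges <- falseEdges + sum(!inModule)
    possible <- possible + choose(length(members), 2)
  }
  expect_gte(hits / possible, 0.9)
  expect_identical(falseEdges, 0L)
})

test_that("a designated hub gene joins two modules and tops the ranking", {
  cfg <- simulationConfig(nGenes = 100L, nCase = 100L, nControl = 10L,
                          modules = list(list(size = 5, lambda = 3,
                                              activeIn = "case"),
                                         list(size = 5, lambda = 3,
                                              activeIn = "case")),
                          nDeg = 0L, sigma = 0.5, hub = TRUE, seed = 11L)
  sim <- simulateExperiment(cfg)
  hub <- sim$truth@hubGenes
  expect_length(hub, 1L)
  expect_true(hub %in% sim$truth@moduleMembers[[1]])
  expect_true(hub %in% sim$truth@moduleMembers[[2]])
  # hub correlation with plain members is lambda^2 / sqrt((2*lambda^2 +
  # sigma^2) * (lambda^2 + sigma^2)) ~ 0.69, so a 0.6 threshold keeps both
  # its within-module edges while background pairs stay far below
  net <- buildNetwork(sim$mes, threshold = 0.6)
  # hub links to the 5 + 4 other members of its two modules; plain
  # members only within their own module
  plain <- setdiff(unlist(sim$truth@moduleMembers), hub)
  expect_identical(unname(geneDegree(net)[hub]), 9L)
  expect_gt(geneDegree(net)[hub], max(geneDegree(net)[plain]))
  rep <- recoveryReport(lriClosed(net), sim$truth)
  expect_true(isTRUE(rep$hubs_in_top_decile))
})

test_that("recovery metrics behave at the extremes", {
  truth <- new("SyntheticTruth",
               moduleMembers = list(m1 = c("a", "b")), hubGenes = character(),
               degGenes = character(), moduleCorrelation = 0.9)
  perfect <- lriNet:::.makeScoreTable(c("a", "b", "c", "d"),
                                      c(2, 1, 0, 0), c(4, 4, 1, 1),
                                      c(1L, 1L, 0L, 0L), "closed")
  rep <- recoveryReport(perfect, truth)
  expect_identical(rep$auc, 1)
  expect_identical(rep$top_k_precision, 1)

  set.seed(77)
  n <- 2000L
  genes <- sprintf("g%04d", 1:n)
  rnd <- sample(1:10000, n)
  random <- lriNet:::.makeScoreTable(genes, rnd, rep(10000, n),
                                     rep(1L, n), "closed")
  truth2 <- new("SyntheticTruth",
                moduleMembers = list(m1 = sample(genes, 200)),
                hubGenes = character(), degGenes = character(),
                moduleCorrelation = 0.5)
  rep2 <- recoveryReport(random, truth2)
  expect_true(abs(rep2$auc - 0.5) < 0.05)

  expect_error(recoveryReport(perfect, new("SyntheticTruth",
    moduleMembers = list(), hubGenes = character(), degGenes = character(),
    moduleCorrelation = numeric())), "empty truth")
})

test_that("planted DEGs are recovered with controlled false discoveries", {
  flagged <- character(); planted <- character(); total_flags <- 0L
  for (s in 1:5) {
    cfg <- simulationConfig(nGenes = 200L, nCase = 20L, nControl = 20L,
                            modules = list(), nDeg = 5L, shift = 3,
                            sigma = 0.2, seed = 900L + s)
    sim <- simulateExperiment(cfg)
    tab <- computeDeg(sim$mes)
    expect_true(all(sim$truth@degGenes %in% tab$gene[tab$is_deg]),
                info = paste("seed", 900L + s))
    total_flags <- total_flags + sum(tab$is_deg)
    flagged <- c(flagged, tab$gene[tab$is_deg])
    planted <- c(planted, sim$truth@degGenes)
  }
  fdr <- 1 - sum(flagged %in% planted) / total_flags
  expect_lte(fdr, 0.1)
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(simulationConfig(seed = NULL), "seed")
  expect_error(simulationConfig(nGenes = 5, nDeg = 0, seed = 1,
    modules = list(list(size = 10, lambda = 1, activeIn = "case"))),
    "exceed")
  expect_error(simulationConfig(sigma = 0, seed = 1), "sigma")
  expect_error(simulationConfig(seed = 1,
    modules = list(list(size = 5, lambda = -1, activeIn = "case"))),
    "lambda")
  expect_error(simulationConfig(seed = 1,
    modules = list(list(size = 5, lambda = 1, activeIn = "never"))),
    "activeIn")
})
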