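test_that("salient selection is strict and follows the ranking", {
  scores <- lriClosed(workedExampleNetwork())
  expect_identical(selectSalient(scores), c("1", "2", "3", "4"))
  expect_identical(selectSalient(scores, 0.3), "1")    # only 18/48 = 0.375

  withIso <- lriClosed(workedExampleNetwork(extraNodes = "5"))
  expect_false("5" %in% selectSalient(withIso))
  # salient at threshold 0 == active players of the scored network
  set.seed(61)
  net <- randomConnectedNetwork()
  expect_setequal(selectSalient(lriClosed(net)), activePlayers(net))
})

test_that("score distribution summarises positive scores only", {
  d <- scoreDistribution(lriClosed(workedExampleNetwork(extraNodes = "z")))
  expect_identical(d$count, 4L)
  expect_identical(d$max, 3 / 8)
  expect_identical(d$min, 1 / 6)
  expect_identical(d$median, 11 / 48)
  expect_gt(d$min, 0)

  k4 <- coexpressionNetwork(t(combn(c("a", "b", "c", "d"), 2)))
  dk <- scoreDistribution(lriClosed(k4))
  expect_identical(dk$q3 - dk$q1, 0)      # complete graph: constant scores

  lonely <- coexpressionNetwork(matrix(character(), 0, 2), nodes = "a")
  suppressWarnings(z <- lriClosed(lonely))
  expect_warning(dz <- scoreDistribution(z), "no positive")
  expect_identical(dz$count, 0L)
})

test_that("gene-list overlaps match the marker and DEG comparisons", {
  salient <- c("MIR143HG", "AMOTL1", "ITGA5", "MCAM", "MT1M", "SI")
  markers <- c("ITGA5", "MCAM", "KRAS", "EGFR")
  ov <- setOverlap(salient, markers)
  expect_identical(ov$common, c("ITGA5", "MCAM"))
  expect_identical(ov$n_common, 2L)

  degs <- c("MT1M", "SI", "GCG", "FOXQ1")
  ov2 <- setOverlap(salient, degs)
  expect_identical(ov2$common, c("MT1M", "SI"))

  expect_identical(setOverlap(c("a", "b"), c("c"))$n_common, 0L)
  expect_identical(setOverlap(" x ", "X", caseFold = TRUE)$n_common, 1L)
})

test_that("hypergeometric enrichment p is the exact right tail", {
  uni <- paste0("g", 1:20)
  gsc <- geneSetCollection(list(T1 = uni[1:5]), universe = uni)
  res <- hypergeomEnrichment(c(uni[1:4], uni[20]), gsc, minGenes = 3)
  # C(5,4)C(15,1) + C(5,5)C(15,0) over C(20,5) = 76/15504
  expect_equal(res$pvalue, 76 / 15504, tolerance = 1e-14)
  expect_identical(res$overlap, 4L)

  # independent oracle: exact tail sum over the 2x2 tables
  tailOracle <- function(k, K, N, n)
    sum(choose(K, k:min(K, n)) * choose(N - K, n - k:min(K, n))) / choose(N, n)
  expect_equal(res$pvalue, tailOracle(4, 5, 20, 5), tolerance = 1e-14)

  # the minimum-overlap filter drops sparse terms
  gsc2 <- geneSetCollection(list(T1 = uni[1:5], T2 = uni[6:10]), universe = uni)
  res2 <- hypergeomEnrichment(c(uni[1:2], uni[19:20]), gsc2, minGenes = 3)
  expect_identical(nrow(res2), 0L)
  res3 <- hypergeomEnrichment(c(uni[1:2], uni[19:20]), gsc2, minGenes = 1)
  expect_identical(res3$term[res3$overlap == 2L], "T1")

  expect_error(hypergeomEnrichment(c("nope"), gsc), "nope")
})

test_that("enrichment p falls as the universe grows around fixed sets", {
  sizes <- c(30, 50, 100, 500, 1000)
  ps <- vapply(sizes, function(N) {
    uni <- paste0("g", seq_len(N))
    gsc <- geneSetCollection(list(T1 = uni[1:10]), universe = uni)
    hypergeomEnrichment(uni[1:10], gsc)$pvalue
  }, 1)
  expect_true(all(diff(ps) < 0))
})

test_that("term kappa matches contingency-table computation and is symmetric", {
  uni <- paste0("g", 1:100)
  expect_identical(termKappa(uni[1:5], uni[1:5], uni), 1)
  # disjoint 5 vs 5 in 100: Po = 0.90, Pe = 0.905 -> kappa = -1/19
  expect_equal(termKappa(uni[1:5], uni[6:10], uni), -1 / 19, tolerance = 1e-14)

  # brute-force 2x2 agreement oracle on term vs term-minus-one
  a <- uni[1:5]; b <- uni[1:4]
  tab <- table(factor(uni %in% a, c(FALSE, TRUE)),
               factor(uni %in% b, c(FALSE, TRUE)))
  po <- sum(diag(tab)) / 100
  pe <- sum(rowSums(tab) * colSums(tab)) / 100^2
  expect_equal(termKappa(a, b, uni), (po - pe) / (1 - pe), tolerance = 1e-14)
  expect_equal(termKappa(a, b, uni), termKappa(b, a, uni))

  expect_error(termKappa(c("g1", "zz"), c("g2"), uni), "zz")
  # both terms equal to the whole universe: identical, kappa 1 by definition
  expect_identical(termKappa(uni, uni, uni), 1)
})

test_that("kappa grouping chains terms that share enough genes", {
  uni <- paste0("g", 1:50)
  gsc <- geneSetCollection(list(A = uni[1:10], B = uni[2:11],
                                C = uni[40:45]), universe = uni)
  grp <- groupTermsByKappa(c("A", "B", "C"), gsc, kappa = 0.4)
  expect_identical(grp[["A"]], grp[["B"]])
  expect_false(grp[["A"]] == grp[["C"]])
})
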