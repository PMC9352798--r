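test_that("stars collect exactly the incident links", {
  net <- workedExampleNetwork(extraNodes = "5")
  expect_setequal(geneStar(net, "1"), c("1|2", "1|3", "1|4"))
  expect_identical(geneStar(net, "4"), "1|4")
  expect_identical(geneStar(net, "5"), character())
  expect_error(geneStar(net, "99"), "99")
  expect_identical(geneDegree(net),
                   c(`1` = 3L, `2` = 2L, `3` = 2L, `4` = 1L, `5` = 0L))
})

test_that("network invariants: canonical edges, degree sum, active set", {
  net <- coexpressionNetwork(rbind(c("b", "a"), c("c", "a")), nodes = letters[1:4])
  e <- networkEdges(net)
  expect_true(all(e[, 1L] < e[, 2L]))
  expect_identical(sum(geneDegree(net)), 2L * nrow(e))
  expect_setequal(activePlayers(net), c("a", "b", "c"))
  expect_identical(nActive(net), 3L)
  expect_error(coexpressionNetwork(rbind(c("a", "a"))), "self-loop")
  expect_error(coexpressionNetwork(rbind(c("a", "b"), c("b", "a"))),
               "duplicate")
  expect_error(coexpressionNetwork(rbind(c("a", "z")), nodes = c("a", "b")),
               "z")
})

test_that("unanimity games pay 1 exactly on supersets of their anchor", {
  expect_identical(unanimityValue("1|4", "1|4"), 1L)
  expect_identical(unanimityValue(c("1|2", "1|3", "1|4"), c("1|2", "1|3")), 0L)
  expect_identical(unanimityValue(character(), character()), 1L)
})

test_that("characteristic function reproduces the full 16-row value table", {
  net <- workedExampleNetwork()
  game <- microarrayNetworkGame(net)
  keys <- c("1|2", "1|3", "1|4", "2|3")
  expected <- list(
    `0` = list(character()),
    `0b` = list("1|2", "1|3", "2|3", c("1|2", "1|3")),
    `1/4` = list("1|4", c("1|2", "1|4"), c("1|2", "2|3"), c("1|3", "1|4"),
                 c("1|3", "2|3"), c("1|4", "2|3")),
    `1/2` = list(c("1|2", "1|3", "1|4"), c("1|2", "1|3", "2|3"),
                 c("1|2", "1|4", "2|3"), c("1|3", "1|4", "2|3")),
    `1` = list(keys))
  vals <- list(`0` = c(0, 1), `0b` = c(0, 1), `1/4` = c(1, 4),
               `1/2` = c(1, 2), `1` = c(1, 1))
  nChecked <- 0L
  for (grp in names(expected)) for (g in expected[[grp]]) {
    v <- gameValue(game, g)
    expect_identical(c(v$num, v$den), vals[[grp]],
                     info = paste("subset", paste(g, collapse = ",")))
    nChecked <- nChecked + 1L
  }
  expect_identical(nChecked, 16L)
})

test_that("value function is monotone and normalised at the endpoints", {
  set.seed(31)
  for (rep in 1:20) {
    net <- randomConnectedNetwork()
    game <- microarrayNetworkGame(net)
    keys <- edgeKeys(net)
    v0 <- gameValue(game, character())
    expect_identical(v0$num, 0)
    vfull <- gameValue(game, keys)
    expect_identical(c(vfull$num, vfull$den), c(1, 1))
    sub <- sample(keys, sample.int(length(keys), 1L))
    sup <- union(sub, sample(keys, 1L))
    expect_lte(ratAsNumericHelper(gameValue(game, sub)),
               ratAsNumericHelper(gameValue(game, sup)))
  }
})

test_that("a network without links cannot form a game", {
  lonely <- coexpressionNetwork(matrix(character(), 0, 2), nodes = c("a", "b"))
  expect_error(microarrayNetworkGame(lonely), "degenerate")
})

test_that("closed-form LRI matches hand-computed allocations", {
  expectFractions(lriClosed(workedExampleNetwork()), workedExampleFractions)

  pairNet <- coexpressionNetwork(rbind(c("A", "B")))
  expectFractions(lriClosed(pairNet), c(A = "1/2", B = "1/2"))

  starNet <- coexpressionNetwork(rbind(c("H", "L1"), c("H", "L2"), c("H", "L3")))
  expectFractions(lriClosed(starNet),
                  c(H = "1/2", L1 = "1/6", L2 = "1/6", L3 = "1/6"))

  k3 <- coexpressionNetwork(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  expectFractions(lriClosed(k3), c(a = "1/3", b = "1/3", c = "1/3"))
})

test_that("star-sum form equals the closed form and the single-edge value", {
  expectFractions(lriSum(workedExampleNetwork()), workedExampleFractions)
  expectFractions(lriSum(coexpressionNetwork(rbind(c("A", "B")))),
                  c(A = "1/2", B = "1/2"))
  set.seed(11)
  for (rep in 1:25) {
    net <- randomConnectedNetwork()
    a <- scoreTable(lriClosed(net)); b <- scoreTable(lriSum(net))
    expect_identical(a[c("gene", "num", "den")], b[c("gene", "num", "den")])
  }
})

test_that("regular networks share the score 1/n and linked genes score >= 1/(2n)", {
  # C5 cycle is 2-regular on 5 genes
  c5 <- coexpressionNetwork(rbind(c("a","b"), c("b","c"), c("c","d"),
                                  c("d","e"), c("a","e")))
  expectFractions(lriClosed(c5), c(a = "1/5", b = "1/5", c = "1/5",
                                   d = "1/5", e = "1/5"))
  set.seed(17)
  for (rep in 1:15) {
    net <- randomConnectedNetwork()
    tb <- scoreTable(lriClosed(net))
    n <- nActive(net)
    expect_true(all(tb$lri[tb$degree > 0] >= 1 / (2 * n) - 1e-12))
  }
})

test_that("isolated genes score zero and an edgeless network warns", {
  net <- workedExampleNetwork(extraNodes = "5")
  tb <- scoreTable(lriClosed(net))
  expect_identical(tb$lri[tb$gene == "5"], 0)
  tb2 <- scoreTable(lriClosed(net, includeIsolated = FALSE))
  expect_false("5" %in% tb2$gene)

  lonely <- coexpressionNetwork(matrix(character(), 0, 2), nodes = c("a", "b"))
  expect_warning(empty <- lriClosed(lonely), "no links")
  expect_true(all(scoreTable(empty)$lri == 0))
})

test_that("brute-force Shapley oracle agrees with both direct forms", {
  net <- workedExampleNetwork()
  expectFractions(positionValueOracle(net), workedExampleFractions)

  sh <- linkShapleyValues(microarrayNetworkGame(net))
  expect_identical(c(sh$num[sh$link == "1|4"], sh$den[sh$link == "1|4"]),
                   c(1, 3))
  tot <- sum(sh$shapley)
  expect_equal(tot, 1, tolerance = 1e-12)

  set.seed(5)
  net2 <- randomNetwork(5, 6)
  a <- scoreTable(lriClosed(net2))
  b <- scoreTable(positionValueOracle(net2))
  expect_identical(a[c("gene", "num", "den")], b[c("gene", "num", "den")])

  big <- randomNetwork(8, 20, connected = FALSE)
  expect_error(positionValueOracle(big, cap = 16L), "cap")
})

test_that("rank assignment: descending scores, ties shared, gene-id order", {
  net <- workedExampleNetwork()
  tb <- scoreTable(lriClosed(net))
  expect_identical(tb$gene, c("1", "2", "3", "4"))
  expect_identical(tb$rank, c(1L, 2L, 2L, 4L))
})
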