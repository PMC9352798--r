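# Shared fixtures. The 4-gene network with links {12,13,14,23} is the
# canonical hand-checkable example: its LRI allocation is
# (18/48, 11/48, 11/48, 8/48).

workedExampleNetwork <- function(extraNodes = character()) {
  coexpressionNetwork(rbind(c("1", "2"), c("1", "3"),
                            c("1", "4"), c("2", "3")),
                      nodes = c(c("1", "2", "3", "4"), extraNodes))
}

workedExampleFractions <- c(`1` = "3/8", `2` = "11/48",
                            `3` = "11/48", `4` = "1/6")

# Craft four unit vectors in R^3 whose pairwise cosines put pairs 12,13,14,23
# above a 0.9 correlation threshold and pairs 24,34 well below it, then embed
# them as rows of a genes x samples matrix through an orthonormal zero-sum
# basis (Helmert contrasts), so the *sample* correlation matrix equals their
# Gram matrix exactly (rows are zero-mean by construction).
workedExampleCorrData <- function(mean = 8) {
  c1 <- 0.95; s1 <- sqrt(1 - c1^2)
  cphi <- 0.3; sphi <- sqrt(1 - cphi^2)
  u1 <- c(1, 0, 0)
  u2 <- c(c1, s1, 0)
  u3 <- c(c1, s1 * cphi, s1 * sphi)
  # u4 tilts away from the u2/u3 side: r14 = 0.92, r24 = r34 ~ 0.78
  p <- c(0, 1, 0) + c(0, cphi, sphi)
  w <- -p / sqrt(sum(p^2))
  cb <- 0.92; sb <- sqrt(1 - cb^2)
  u4 <- c(cb, sb * w[2], sb * w[3])
  U <- rbind(u1, u2, u3, u4)
  rownames(U) <- c("1", "2", "3", "4")
  m <- 5L
  H <- stats::contr.helmert(m)                  # m x (m-1), zero-sum
  B <- sweep(H, 2L, sqrt(colSums(H^2)), "/")    # orthonormal columns
  X <- U %*% t(B[, 1:3]) + mean
  colnames(X) <- sprintf("d%d", 1:m)
  list(mat = X, R = U %*% t(U))
}

# Case/control experiment whose case-sample correlations are exactly the
# crafted Gram matrix (control samples: independent noise, seeded).
exactCorrExperiment <- function(seed = 99L) {
  cs <- workedExampleCorrData()$mat
  set.seed(seed)
  ct <- matrix(stats::rnorm(length(cs), 8, 1), nrow(cs), ncol(cs),
               dimnames = list(rownames(cs), sprintf("r%d", 1:ncol(cs))))
  microarrayExperimentSituation(cs, ct)
}

# Exact-fraction comparison against an LRIScoreTable
expectFractions <- function(tab, expected) {
  fr <- lriFractions(tab)
  expect_identical(fr[names(expected)], expected)
}

ratAsNumericHelper <- function(r) r$num / r$den

randomConnectedNetwork <- function() {
  n <- sample(3:8, 1L)
  links <- sample(seq(n - 1L, min(10L, choose(n, 2L))), 1L)
  randomNetwork(n, links, connected = TRUE)
}
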