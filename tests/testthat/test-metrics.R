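chain3 <- CloneTree(c(0L, 1L, 2L), list("A", "B", "C"), rep(1 / 3, 3))
star3 <- CloneTree(c(0L, 1L, 1L), list("A", "B", "C"), rep(1 / 3, 3))

pairKeys <- function(p) paste(p$ancestor, p$descendant)

test_that("estimated beta is y/N with the N = 0 convention", {
  expect_identical(estimatedBeta(0, 50), 0)
  expect_identical(estimatedBeta(5, 100), 0.05)
  expect_warning(b0 <- estimatedBeta(0, 0), "N = 0")
  expect_identical(b0, 0)
  expect_error(estimatedBeta(5, 4), "exceed")
})

test_that("ancestor-descendant pairs follow the edge partial order", {
  expect_setequal(pairKeys(adPairs(chain3)), c("A B", "A C", "B C"))
  expect_setequal(pairKeys(adPairs(star3)), c("A B", "A C"))
  # two mutations on one edge form no pair
  tr <- CloneTree(c(0L, 1L), list(c("A", "B"), "C"), c(0.5, 0.5))
  expect_setequal(pairKeys(adPairs(tr)), c("A C", "B C"))
})

test_that("linear solutions merge equal one-states onto one pseudo-edge", {
  g <- cbind(A = c(1L, 1L, 1L), B = c(0L, 1L, 1L), C = c(0L, 1L, 1L))
  p <- adPairs(GenotypeMatrix(g))
  expect_setequal(pairKeys(p), c("A B", "A C"))  # B,C share an edge: no pair
  sol <- solveLPPF(GenotypeMatrix(g))
  expect_setequal(pairKeys(adPairs(sol)), c("A B", "A C"))
})

test_that("AD distance is the symmetric difference of pair sets", {
  expect_identical(adDistance(chain3, chain3), 0L)
  expect_identical(adDistance(chain3, star3), 1L)  # (B,C) only in the chain
  expect_identical(adDistance(star3, chain3), 1L)
  other <- CloneTree(c(0L, 1L, 2L), list("B", "A", "C"), rep(1 / 3, 3))
  expect_identical(adDistance(chain3, other), 2L)  # (A,B) vs (B,A)
  bad <- CloneTree(c(0L, 1L), list("A", "X"), c(0.5, 0.5))
  expect_error(adDistance(chain3, bad), "different mutation sets")
})

test_that("AD distance is a pseudometric on random small trees", {
  set.seed(451)
  for (r in 1:20) {
    t1 <- generateCloneTree(6, "BRANCHED")
    t2 <- generateCloneTree(6, "BRANCHED")
    d12 <- adDistance(t1, t2)
    expect_gte(d12, 0L)
    expect_identical(d12, adDistance(t2, t1))
    expect_identical(adDistance(t1, t1), 0L)
  }
})

test_that("error-free linear data recovers the true tree exactly", {
  # uniform prevalences so every clone is represented in the sample (an
  # unsampled clone's mutation is unidentifiable from the cells alone)
  set.seed(452)
  for (r in 1:5) {
    tr <- generateCloneTree(6, "LINEAR", prevalence = rep(1 / 6, 6))
    B <- sampleCells(tr, 200)
    sol <- solveLPPF(B)
    expect_identical(objectiveY(sol), 0L)
    expect_identical(adDistance(tr, sol), 0L)
  }
})

test_that("beta-hat grows with the degree of branching", {
  # across branched topologies (alpha = delta = 0), mean AD distance to the
  # inferred linear tree and mean beta-hat correlate positively
  set.seed(453)
  meanAD <- meanBH <- numeric(10)
  for (topo in 1:10) {
    tr <- generateCloneTree(8, "BRANCHED")
    ad <- bh <- numeric(3)
    for (rep in 1:3) {
      B <- injectErrors(sampleCells(tr, 80), beta = 0.1)
      sol <- solveLPPF(B, seed = topo * 10 + rep)
      ad[rep] <- adDistance(tr, sol)
      bh[rep] <- estimatedBeta(objectiveY(sol), solutionN(sol))
    }
    meanAD[topo] <- mean(ad)
    meanBH[topo] <- mean(bh)
  }
  expect_gt(cor(meanAD, meanBH, method = "spearman"), 0)
})

test_that("confusion summary counts and medians match direct recomputation", {
  toy <- data.frame(
    truth = c("LINEAR", "LINEAR", "BRANCHED", "BRANCHED"),
    label = c("LINEAR", "BRANCHED", "BRANCHED", "BRANCHED"),
    beta_hat = c(0.03, 0.08, 0.4, 0.6),
    K = c(12, 0.9, 0.1, 0.01))
  s <- confusionSummary(toy)
  expect_identical(s$accuracy, 0.75)
  expect_identical(unname(s$counts["LINEAR", "LINEAR"]), 1L)
  expect_identical(unname(s$counts["BRANCHED", "BRANCHED"]), 2L)
  expect_equal(unname(s$medianBetaHat["LINEAR"]), median(c(0.03, 0.08)))
  expect_equal(unname(s$medianK["BRANCHED"]), median(c(0.1, 0.01)))
  expect_error(confusionSummary(toy[0, ]), "empty")
  allRight <- transform(toy, label = truth)
  expect_identical(confusionSummary(allRight)$accuracy, 1)
})
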