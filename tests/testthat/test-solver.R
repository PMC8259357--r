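conflict2 <- GenotypeMatrix(rbind(c(1, 0), c(0, 1)))

test_that("solver reproduces the worked micro-examples", {
  expect_identical(objectiveY(solveLPPF(conflict2, z = 0)), 1L)
  expect_identical(objectiveY(solveLPPF(GenotypeMatrix(rbind(c(1, 1),
                                                             c(0, 1))))), 0L)
  expect_identical(
    objectiveY(solveLPPF(GenotypeMatrix(rbind(c(1, 0), c(0, 1), c(0, 1))))),
    1L)
  expect_identical(objectiveY(solveLPPF(conflict2, z = 1)), 0L)
})

test_that("solutions are valid linear perfect phylogenies", {
  set.seed(421)
  for (r in 1:30) {
    B <- randomGenotypeMatrix(sample(2:10, 1), sample(2:6, 1),
                              runif(1, 0.2, 0.8),
                              missingProp = ifelse(r %% 3 == 0, 0.1, 0))
    z <- sample(0:2, 1)
    sol <- solveLPPF(B, z = z, seed = r)
    flipped <- GenotypeMatrix(flippedMatrix(sol))
    # linearity verified by the independent definition-level check
    chk <- isLinear(flipped)
    expect_true(chk$linear)
    # the reported order realizes the one-state chain
    ord <- match(mutationOrder(sol), mutationNames(B))
    cards <- colSums(flippedMatrix(sol))[ord]
    expect_true(all(diff(cards) >= 0))
    # flips restricted to observed entries; everything else preserved
    g <- genotypes(B)
    same <- !is.na(g) & g == flippedMatrix(sol)
    nChanged <- sum(!is.na(g)) - sum(same)
    expect_identical(nChanged, nrow(fnFlips(sol)) + nrow(fpFlips(sol)))
    expect_lte(nrow(fpFlips(sol)), z)
    expect_identical(objectiveY(sol), nrow(fnFlips(sol)))
    expect_identical(nrow(imputedPositions(sol)), sum(is.na(g)))
  }
})

test_that("objective is monotone in z and bounded by the zero count", {
  set.seed(422)
  for (r in 1:15) {
    B <- randomGenotypeMatrix(sample(3:8, 1), sample(2:5, 1),
                              runif(1, 0.3, 0.7))
    prev <- Inf
    for (z in 0:3) {
      y <- objectiveY(solveLPPF(B, z = z, seed = 1))
      expect_lte(y, prev)
      expect_lte(y, sum(genotypes(B) == 0L))
      prev <- y
    }
  }
})

test_that("solver and brute-force oracle agree on random instances", {
  set.seed(423)
  for (r in 1:60) {
    B <- randomGenotypeMatrix(sample(2:10, 1), sample(2:5, 1),
                              runif(1, 0.2, 0.8),
                              missingProp = ifelse(r %% 4 == 0, 0.15, 0))
    z <- sample(0:2, 1)
    expect_identical(objectiveY(solveLPPF(B, z = z, seed = r)),
                     objectiveY(bruteForceLPPF(B, z = z)))
  }
})

test_that("objective is deterministic under a fixed seed", {
  set.seed(424)
  B <- randomGenotypeMatrix(10, 6, 0.5)
  y <- vapply(1:3, function(k) objectiveY(solveLPPF(B, z = 1, seed = 7)), 0L)
  expect_identical(y, rep(y[1], 3))
})

test_that("permutation cost handles fixed orders and the shared budget", {
  # order with column 1 most derived: row (1,0) must extend to (1,1)
  expect_identical(permutationCost(conflict2, c(1, 2), z = 0)$flips, 1L)
  B2 <- GenotypeMatrix(rbind(c(1, 1), c(0, 1)))
  expect_identical(permutationCost(B2, c(1, 2), z = 0)$flips, 0L)
  # both conflicts removable by 1->0 flips within a budget of 2
  expect_identical(permutationCost(conflict2, c(1, 2), z = 2)$flips, 0L)
  expect_identical(permutationCost(conflict2, c(2, 1), z = 2)$flips, 0L)
  expect_error(permutationCost(conflict2, c(1, 1), z = 0), "permutation")
  # the budget is shared across rows, not per row
  B3 <- GenotypeMatrix(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 1)))
  pc <- permutationCost(B3, c(3, 2, 1), z = 1)
  expect_identical(pc$flips + 0L, objectiveY(bruteForceLPPF(B3, z = 1)))
  expect_lte(pc$flips1to0, 1L)
})

test_that("z derives from alpha by ceiling over the observed ones", {
  B <- GenotypeMatrix(matrix(1L, 10, 25))  # 250 ones
  expect_identical(computeZ(B, 0), 0L)
  expect_identical(computeZ(B, 0.001), 1L)
  expect_identical(computeZ(B, 0.01), 3L)
  g <- matrix(1L, 10, 25)
  g[1, 1:10] <- NA_integer_  # missing excluded from the count: 240 ones
  expect_identical(computeZ(GenotypeMatrix(g), 0.01), 3L)  # ceiling(2.4)
  expect_error(computeZ(B, 1), "alpha")
  expect_error(computeZ(B, -0.1), "alpha")
})

test_that("degenerate and guard cases are handled", {
  expect_identical(objectiveY(solveLPPF(GenotypeMatrix(matrix(0L, 4, 3)))),
                   0L)
  expect_identical(objectiveY(solveLPPF(GenotypeMatrix(matrix(1L, 4, 3)))),
                   0L)
  expect_identical(objectiveY(solveLPPF(GenotypeMatrix(matrix(c(0L, 1L),
                                                              2, 1)))), 0L)
  expect_error(solveLPPF(conflict2, z = -1), "non-negative")
  expect_error(solveLPPF(conflict2, timeLimit = 0), "positive")
  expect_error(solveLPPF(conflict2, z = 1, alpha = 0.1), "not both")
  expect_error(bruteForceLPPF(randomGenotypeMatrix(3, 9), z = 0), "guard")
})

test_that("injected false negatives are always repairable", {
  # with alpha = delta = 0, flipping the injected positions back restores a
  # linear matrix, so the optimum is at most the injected count
  set.seed(425)
  for (r in 1:10) {
    sim <- simulateInstance(80, sample(5:10, 1), "LINEAR",
                            beta = runif(1, 0.05, 0.3))
    f <- nrow(metadata(sim$observed)$injectedFN)
    sol <- solveLPPF(sim$observed, z = 0, seed = r)
    expect_identical(solverStatus(sol), "OPTIMAL")
    expect_lte(objectiveY(sol), f)
  }
})
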