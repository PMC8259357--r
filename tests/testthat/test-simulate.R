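test_that("clone trees honor pattern, labels and determinism", {
  tr <- generateCloneTree(4, "LINEAR", seed = 11)
  expect_identical(treePattern(tr), "LINEAR")
  expect_true(isLinear(GenotypeMatrix(cloneGenotypes(tr)))$linear)
  expect_identical(sort(unlist(tr@edgeMutations)), paste0("mut", 1:4))
  expect_equal(sum(prevalence(tr)), 1)

  tb <- generateCloneTree(6, "BRANCHED", seed = 12)
  expect_identical(treePattern(tb), "BRANCHED")
  kids <- tabulate(tb@parent[tb@parent > 0], nbins = 6)
  expect_true(any(kids >= 2) || sum(tb@parent == 0) >= 2)

  expect_identical(generateCloneTree(5, "BRANCHED", seed = 3)@parent,
                   generateCloneTree(5, "BRANCHED", seed = 3)@parent)
  expect_error(generateCloneTree(1, "BRANCHED"), "impossible")
  expect_error(generateCloneTree(3, "LINEAR", branchFactor = 0), "branchFactor")
})

test_that("sampled cells carry their clone's root-path genotype", {
  tr <- generateCloneTree(5, "BRANCHED", seed = 21)
  B <- sampleCells(tr, 40, seed = 22)
  cg <- cloneGenotypes(tr)
  clone <- metadata(B)$clone
  for (i in seq_len(40))
    expect_identical(unname(genotypes(B)[i, ]), unname(cg[clone[i], ]))
})

test_that("single-clone tree gives identical rows", {
  tr <- CloneTree(0L, list(c("mutA", "mutB")), 1)
  B <- sampleCells(tr, 10, seed = 1)
  expect_true(all(genotypes(B) == 1L))
})

test_that("observed clone fractions concentrate around prevalences", {
  tr <- generateCloneTree(2, "LINEAR", seed = 31, prevalence = c(0.5, 0.5))
  B <- sampleCells(tr, 10000, seed = 32)
  frac <- mean(metadata(B)$clone == 1L)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("branched truth with cells on two branches is not linear", {
  set.seed(433)
  found <- 0L
  for (r in 1:20) {
    tr <- generateCloneTree(6, "BRANCHED")
    B <- sampleCells(tr, 30)
    # detect whether two disjoint branches both received cells
    if (!isLinear(B)$linear) found <- found + 1L
  }
  # with 30 cells over Dirichlet prevalences this is nearly certain
  expect_gte(found, 18L)
})

test_that("error injection matches its rates and is reproducible", {
  tr <- generateCloneTree(10, "LINEAR", seed = 41)
  B <- sampleCells(tr, 200, seed = 42)
  expect_identical(genotypes(injectErrors(B, 0, 0, seed = 1)), genotypes(B))

  ones <- sum(genotypes(B) == 1L)
  obs <- injectErrors(B, 0.15, 0.01, seed = 43)
  fn <- nrow(metadata(obs)$injectedFN)
  sigma <- sqrt(ones * 0.15 * 0.85)
  expect_lt(abs(fn - ones * 0.15), 3 * sigma)
  # flips recorded faithfully
  expect_identical(sum(genotypes(B) == 1L & genotypes(obs) == 0L), fn)
  expect_identical(genotypes(injectErrors(B, 0.2, 0.005, seed = 7)),
                   genotypes(injectErrors(B, 0.2, 0.005, seed = 7)))
})

test_that("doublets merge genotypes by union", {
  tr <- generateCloneTree(4, "LINEAR", seed = 51)
  B <- sampleCells(tr, 50, seed = 52)
  expect_identical(genotypes(injectDoublets(B, tr, 0, seed = 1)),
                   genotypes(B))
  # on a linear path the union of nested genotypes is the more derived one
  merged <- injectDoublets(B, tr, 0.9, seed = 53)
  cg <- cloneGenotypes(tr)
  partner <- metadata(merged)$doubletPartner
  clone <- metadata(B)$clone
  for (i in which(!is.na(partner))) {
    deeper <- max(clone[i], partner[i])  # chain: higher index = more derived
    expect_identical(unname(genotypes(merged)[i, ]), unname(cg[deeper, ]))
  }
})

test_that("cross-branch doublets carry mutations from both branches", {
  # two clones hanging off the root: genotypes are disjoint singletons
  tr <- CloneTree(c(0L, 0L), list("mutA", "mutB"), c(0.5, 0.5))
  B <- sampleCells(tr, 200, seed = 61)
  merged <- injectDoublets(B, tr, 0.5, seed = 62)
  partner <- metadata(merged)$doubletPartner
  clone <- metadata(B)$clone
  cross <- which(!is.na(partner) & partner != clone)
  expect_gt(length(cross), 0)
  for (i in cross) expect_identical(unname(genotypes(merged)[i, ]), c(1L, 1L))
})

test_that("instances are fully reproducible from the seed", {
  a <- simulateInstance(60, 7, "BRANCHED", beta = 0.1, alpha = 0.01,
                        delta = 0.2, seed = 71)
  b <- simulateInstance(60, 7, "BRANCHED", beta = 0.1, alpha = 0.01,
                        delta = 0.2, seed = 71)
  expect_identical(genotypes(a$observed), genotypes(b$observed))
  expect_identical(a$tree@parent, b$tree@parent)
  c <- simulateInstance(60, 7, "BRANCHED", beta = 0.1, alpha = 0.01,
                        delta = 0.2, seed = 72)
  expect_false(identical(genotypes(a$observed), genotypes(c$observed)))
})
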