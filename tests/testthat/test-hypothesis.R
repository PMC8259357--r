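test_that("mean/precision convert to shapes and back", {
  expect_equal(convertParams(0.05, 10), c(theta1 = 0.5, theta2 = 9.5))
  expect_equal(convertParams(0.15, 10), c(theta1 = 1.5, theta2 = 8.5))
  set.seed(431)
  for (r in 1:10) {
    mu <- runif(1, 0.01, 0.99)
    s <- runif(1, 0.5, 50)
    th <- convertParams(mu, s)
    expect_equal(unname(th[1] / sum(th)), mu)
    expect_equal(unname(sum(th)), s)
  }
  expect_error(convertParams(0, 10), "inside")
  expect_error(convertParams(1, 10), "inside")
  expect_error(convertParams(0.5, 0), "positive")
})

test_that("beta-binomial likelihood normalizes and matches direct evaluation", {
  # Beta(1,1) mixing gives the discrete uniform
  expect_equal(exp(betaBinomLogLik(0:2, 2, 1, 1)), rep(1 / 3, 3))
  set.seed(432)
  for (r in 1:10) {
    N <- sample(5:40, 1)
    th <- exp(runif(2, -1.5, 2.5))
    expect_equal(sum(exp(betaBinomLogLik(0:N, N, th[1], th[2]))), 1)
  }
  # frozen value from an arbitrary-precision evaluation of the pmf
  expect_equal(betaBinomLogLik(10, 100, 0.5, 9.5), -3.823835639489902,
               tolerance = 1e-12)
  # independent direct product-form evaluation
  for (r in 1:10) {
    N <- sample(5:60, 1)
    y <- sample(0:N, 1)
    th <- exp(runif(2, -1.5, 2.5))
    expect_equal(exp(betaBinomLogLik(y, N, th[1], th[2])),
                 directBetaBinom(y, N, th[1], th[2]))
  }
  expect_error(betaBinomLogLik(5, 4, 1, 1), "y must satisfy")
  expect_error(betaBinomLogLik(1.5, 4, 1, 1), "integers")
})

test_that("Bayes factor behaves as a likelihood ratio", {
  lin <- HypothesisParams(0.05, 10)
  bra <- HypothesisParams(0.15, 10)
  # identical hypotheses: K = 1 for any (y, N)
  for (y in c(0, 3, 17)) expect_equal(bayesFactor(y, 20, lin, lin), 1)
  # frozen value from an arbitrary-precision evaluation
  expect_equal(bayesFactor(0, 100, lin, bra), 12.764705882352941,
               tolerance = 1e-12)
  expect_gt(bayesFactor(0, 100, lin, bra), 1)
  # swapping hypotheses inverts K
  expect_equal(bayesFactor(7, 50, lin, bra) * bayesFactor(7, 50, bra, lin), 1)
  # with equal precision and a larger branched mean, K decreases in y
  K <- vapply(0:100, function(y) bayesFactor(y, 100, lin, bra), 0)
  expect_true(all(diff(K) < 0))
})

test_that("Bayes classification uses the published decision rule", {
  expect_identical(classifyBayes(14.0), "LINEAR")
  expect_identical(classifyBayes(0.3), "BRANCHED")
  expect_warning(lab <- classifyBayes(1), "K = 1")
  expect_identical(lab, "BRANCHED")
  expect_error(classifyBayes(Inf), "finite")
  expect_error(classifyBayes(-2), "positive")
})

test_that("hard threshold rejects linearity but never supports it", {
  expect_identical(classifyThreshold(0.36, 0.18), "BRANCHED")
  expect_identical(classifyThreshold(0.15, 0.18), "NOT_REJECTED")
  expect_identical(classifyThreshold(0.18, 0.18), "NOT_REJECTED")  # strict
  expect_error(classifyThreshold(1.2, 0.18), "\\[0, 1\\]")
})

test_that("branched prior fitting recovers beta parameters by moments", {
  set.seed(433)
  target <- convertParams(0.22, 11.8)
  x <- rbeta(500, target[1], target[2])
  fit <- fitBranchedPrior(x)
  expect_lt(abs(fit@mu - 0.22), 0.02)
  expect_lt(abs(fit@s - 11.8) / 11.8, 0.3)
  expect_equal(fitBranchedPrior(rep(c(0.1, 0.3), 2))@mu, 0.2)
  expect_error(fitBranchedPrior(rep(0.2, 5)), "variance")
  expect_error(fitBranchedPrior(c(0.1, 0.2)), "at least 3")
  expect_error(fitBranchedPrior(c(0.1, 0.2, 1.0)), "inside")
})

test_that("N counts ones in the completed matrix, imputed excluded by default", {
  g <- rbind(c(1L, 0L), c(NA, 1L), c(1L, 1L))
  sol <- solveLPPF(GenotypeMatrix(g))
  nImputedOnes <- sum(imputedPositions(sol)[, "value"] == 1L)
  expect_identical(solutionN(sol, includeImputed = TRUE),
                   solutionN(sol) + nImputedOnes)
  expect_identical(solutionN(sol, includeImputed = TRUE),
                   sum(flippedMatrix(sol) == 1L))
})

test_that("Bayes factor and threshold agree on clean linear simulations", {
  set.seed(434)
  lin <- HypothesisParams(0.05, 10)
  bra <- HypothesisParams(0.15, 10)
  for (r in 1:8) {
    sim <- simulateInstance(500, 5, "LINEAR", beta = 0.05)
    sol <- solveLPPF(sim$observed, seed = r)
    res <- classifyMatrix(sol, linear = lin, branched = bra)
    expect_identical(res@label, "LINEAR")
    # the hard threshold at the true rate does not reject linearity either
    expect_identical(classifyThreshold(res@betaHat, 0.05), "NOT_REJECTED")
  }
})
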