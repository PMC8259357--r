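#' Robustness grid: simulate, solve, classify
#'
#' Runs the full simulation-classification experiment over a factorial grid
#' of matrix sizes and error regimes.  For each number of mutations m, the
#' branched hypothesis is first fitted (method of moments, see
#' \code{\link{fitBranchedPrior}}) from an independent set of branched-only
#' simulations spanning the same error grid; each main-grid instance is then
#' simulated, solved with the false-positive budget z = ceiling(alpha *
#' ones), and classified by Bayes factor.  The linear hypothesis of each
#' instance uses the known simulated false-negative rate of that condition
#' as its mean, with precision \code{sLinear}.
#'
#' @param mValues numbers of mutations.
#' @param betas,alphas,deltas false-negative, false-positive and doublet
#'   probabilities defining the grid.
#' @param patterns ground-truth patterns to simulate.
#' @param replicates replicates per grid cell.
#' @param nCells cells per instance.
#' @param timeLimit per-instance solver cap in seconds.
#' @param sLinear precision of the linear hypothesis.
#' @param priorReplicates branched-only replicates per (beta, alpha, delta)
#'   combination used for fitting the branched hypothesis, per m.
#' @param seed master integer seed; every instance seed derives from it.
#' @param branchFactor passed to \code{\link{generateCloneTree}}.
#' @param verbose print one line per instance.
#' @return A tidy data.frame, one row per instance, with the simulation
#'   condition, the solver outcome (y, N, beta_hat, status, runtime), the
#'   Bayes factor K, the classification \code{label} and the \code{truth};
#'   the fitted branched hypotheses are attached as
#'   \code{attr(, "branchedPriors")}.
#' @export
runRobustnessGrid <- function(mValues = c(10L, 25L, 50L),
                              betas = c(0.05, 0.15, 0.25),
                              alphas = c(0.001, 0.01),
                              deltas = c(0.0, 0.2),
                              patterns = c("LINEAR", "BRANCHED"),
                              replicates = 5L,
                              nCells = 500L,
                              timeLimit = 900,
                              sLinear = 10,
                              priorReplicates = 1L,
                              seed = 1L,
                              branchFactor = 1,
                              verbose = FALSE) {
  stopifnot(all(patterns %in% c("LINEAR", "BRANCHED")))
  grid <- expand.grid(m = as.integer(mValues), beta = betas, alpha = alphas,
                      delta = deltas, pattern = patterns,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  priorGrid <- expand.grid(m = as.integer(mValues), beta = betas,
                           alpha = alphas, delta = deltas,
                           replicate = seq_len(priorReplicates),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr::with_seed(as.integer(seed), {
    priorGrid$seed <- sample.int(.Machine$integer.max - 1L, nrow(priorGrid))
    grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  })

  runOne <- function(m, beta, alpha, delta, pattern, instSeed) {
    sim <- simulateInstance(nCells, m, pattern, beta = beta, alpha = alpha,
                            delta = delta, seed = instSeed,
                            branchFactor = branchFactor)
    z <- computeZ(sim$observed, alpha)
    sol <- solveLPPF(sim$observed, z = z, timeLimit = timeLimit,
                     seed = instSeed)
    y <- objectiveY(sol)
    N <- solutionN(sol)
    list(sim = sim, sol = sol, z = z, y = y, N = N,
         betaHat = estimatedBeta(y, N))
  }

  branchedPriors <- list()
  for (m in as.integer(mValues)) {
    rows <- priorGrid[priorGrid$m == m, , drop = FALSE]
    samples <- vapply(seq_len(nrow(rows)), function(r) {
      with(rows[r, ], runOne(m, beta, alpha, delta, "BRANCHED",
                             seed)$betaHat)
    }, 0)
    samples <- samples[samples > 0 & samples < 1]
    branchedPriors[[as.character(m)]] <- fitBranchedPrior(samples)
    if (verbose)
      message(sprintf("m = %d: branched prior mu = %.3f, s = %.2f", m,
                      branchedPriors[[as.character(m)]]@mu,
                      branchedPriors[[as.character(m)]]@s))
  }

  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    gr <- grid[r, ]
    res <- runOne(gr$m, gr$beta, gr$alpha, gr$delta, gr$pattern, gr$seed)
    branched <- branchedPriors[[as.character(gr$m)]]
    linear <- HypothesisParams(gr$beta, sLinear)
    K <- bayesFactor(res$y, res$N, linear, branched)
    label <- classifyBayes(K)
    out[[r]] <- data.frame(
      m = gr$m, n_cells = nCells, beta = gr$beta, alpha = gr$alpha,
      delta = gr$delta, replicate = gr$replicate, seed = gr$seed,
      truth = gr$pattern, z = res$z, y = res$y, N = res$N,
      beta_hat = res$betaHat, K = K, label = label,
      status = solverStatus(res$sol), runtime = res$sol@runtime,
      mu_branched = branched@mu, s_branched = branched@s,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf(
        "[%d/%d] m=%d beta=%.3f alpha=%.3f delta=%.1f %s -> %s (beta_hat=%.3f, K=%.3g, %s)",
        r, nrow(grid), gr$m, gr$beta, gr$alpha, gr$delta, gr$pattern,
        label, res$betaHat, K, solverStatus(res$sol)))
  }
  res <- do.call(rbind, out)
  attr(res, "branchedPriors") <- branchedPriors
  res
}
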