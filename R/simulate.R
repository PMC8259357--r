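# run expr under a fixed seed when one is given, otherwise use the current
# RNG stream (so composite generators remain a single reproducible stream)
.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Generate a ground-truth clonal tree
#'
#' Builds a rooted clone tree with one mutation per edge and Dirichlet(1)
#' clonal prevalences.  \code{pattern = "LINEAR"} yields a path (each clone
#' the single child of the previous one); \code{pattern = "BRANCHED"} grows
#' the tree by random attachment and rejection-samples until at least one
#' node (possibly the root) has two or more children.
#'
#' @param m number of mutations (>= 1 linear, >= 2 branched).
#' @param pattern "LINEAR" or "BRANCHED".
#' @param seed optional integer; fixes the tree and prevalences.
#' @param branchFactor in (0, 1]: probability that a new clone attaches
#'   uniformly at random among the root and all existing clones (creating
#'   branching opportunities) rather than extending the most recent clone.
#'   1 (default) gives uniform random attachment.
#' @param prevalence optional user-supplied per-clone fractions (normalized);
#'   by default drawn from a symmetric Dirichlet(1).
#' @return A \linkS4class{CloneTree} with m clones labeled mut1..m.
#' @examples
#' tr <- generateCloneTree(4, "LINEAR", seed = 1)
#' isLinear(GenotypeMatrix(cloneGenotypes(tr)))$linear  # TRUE
#' @export
generateCloneTree <- function(m, pattern = c("LINEAR", "BRANCHED"),
                              seed = NULL, branchFactor = 1,
                              prevalence = NULL) {
  pattern <- match.arg(pattern)
  m <- as.integer(m)
  if (m < 1L) stop("m must be at least 1")
  if (pattern == "BRANCHED" && m < 2L)
    stop("branching is impossible with fewer than 2 mutations")
  if (branchFactor <= 0 || branchFactor > 1)
    stop("branchFactor must lie in (0, 1]")
  .withSeed(seed, {
    if (pattern == "LINEAR") {
      parent <- 0:(m - 1L)
    } else {
      repeat {
        parent <- integer(m)
        parent[1L] <- 0L
        for (j in seq_len(m)[-1L]) {
          parent[j] <- if (stats::runif(1) <= branchFactor)
            sample.int(j, 1L) - 1L  # uniform over root (0) and clones 1..j-1
          else
            j - 1L                  # extend the most recent clone
        }
        nChildren <- tabulate(parent[parent > 0L], nbins = m)
        if (any(nChildren >= 2L) || sum(parent == 0L) >= 2L) break
      }
    }
    if (is.null(prevalence))
      prevalence <- stats::rexp(m)  # normalized -> symmetric Dirichlet(1)
    CloneTree(parent, as.list(paste0("mut", seq_len(m))), prevalence,
              pattern = pattern)
  })
}

#' Sample error-free cells from a clonal tree
#'
#' Each cell is assigned to a clone with probability equal to the clone's
#' prevalence and receives that clone's genotype (the mutations on its root
#' path).  The clone assignment is recorded in the metadata for downstream
#' evaluation.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param n number of cells.
#' @param seed optional integer seed.
#' @return A \linkS4class{GenotypeMatrix} (no missing entries) with
#'   \code{metadata(x)$clone} giving each cell's clone index.
#' @export
sampleCells <- function(tree, n, seed = NULL) {
  stopifnot(is(tree, "CloneTree"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (all(prevalence(tree) == 0)) stop("empty prevalence vector")
  .withSeed(seed, {
    cg <- cloneGenotypes(tree)
    clone <- sample.int(nrow(cg), n, replace = TRUE, prob = prevalence(tree))
    g <- cg[clone, , drop = FALSE]
    rownames(g) <- paste0("cell", seq_len(n))
    GenotypeMatrix(g, metadata = list(clone = clone))
  })
}

#' Inject doublets into an error-free matrix
#'
#' A doublet is two cells captured and sequenced as one; the resulting
#' genotype is the entrywise OR of the two true genotypes.  Each row is
#' independently replaced with probability \code{delta} by the OR of itself
#' and the genotype of a partner clone drawn from the clonal prevalences.
#' Apply before \code{\link{injectErrors}}: the co-captured material is
#' merged first, then sequenced with errors.
#'
#' @param B error-free \linkS4class{GenotypeMatrix} from
#'   \code{\link{sampleCells}}.
#' @param tree the \linkS4class{CloneTree} the cells were sampled from.
#' @param delta doublet probability in [0, 1).
#' @param seed optional integer seed.
#' @return A \linkS4class{GenotypeMatrix}; \code{metadata(x)$doubletPartner}
#'   holds the partner clone index (NA for singlets).
#' @export
injectDoublets <- function(B, tree, delta, seed = NULL) {
  stopifnot(is(B, "GenotypeMatrix"), is(tree, "CloneTree"))
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)")
  .withSeed(seed, {
    g <- genotypes(B)
    cg <- cloneGenotypes(tree)
    stopifnot(identical(colnames(g), colnames(cg)))
    n <- nrow(g)
    isDoublet <- stats::runif(n) < delta
    partner <- rep(NA_integer_, n)
    if (any(isDoublet)) {
      partner[isDoublet] <- sample.int(nrow(cg), sum(isDoublet),
                                       replace = TRUE,
                                       prob = prevalence(tree))
      g[isDoublet, ] <- pmax(g[isDoublet, , drop = FALSE],
                             cg[partner[isDoublet], , drop = FALSE])
    }
    md <- metadata(B)
    md$doubletPartner <- partner
    GenotypeMatrix(g, metadata = md)
  })
}

#' Inject sequencing errors
#'
#' Independently per (non-missing) entry, a true 1 is read as 0 with
#' probability \code{beta} (false negative) and a true 0 is read as 1 with
#' probability \code{alpha} (false positive).  Injected positions are
#' recorded in the metadata so repair bounds can be checked downstream.
#'
#' @param B a \linkS4class{GenotypeMatrix} (typically error-free truth).
#' @param beta false-negative probability in [0, 1).
#' @param alpha false-positive probability in [0, 1).
#' @param seed optional integer seed.
#' @return A \linkS4class{GenotypeMatrix}; \code{metadata(x)$injectedFN} and
#'   \code{$injectedFP} hold (cell, mutation) index matrices of the injected
#'   errors.
#' @export
injectErrors <- function(B, beta, alpha = 0, seed = NULL) {
  stopifnot(is(B, "GenotypeMatrix"))
  if (beta < 0 || beta >= 1 || alpha < 0 || alpha >= 1)
    stop("error rates must lie in [0, 1)")
  .withSeed(seed, {
    g <- genotypes(B)
    u <- matrix(stats::runif(length(g)), nrow(g), ncol(g))
    fn <- which(!is.na(g) & g == 1L & u < beta, arr.ind = TRUE)
    fp <- which(!is.na(g) & g == 0L & u < alpha, arr.ind = TRUE)
    colnames(fn) <- colnames(fp) <- c("cell", "mutation")
    g[fn] <- 0L
    g[fp] <- 1L
    md <- metadata(B)
    md$injectedFN <- fn
    md$injectedFP <- fp
    GenotypeMatrix(g, metadata = md)
  })
}

#' Simulate one observed single-cell matrix
#'
#' Full generative pipeline for one instance: clone tree, cell sampling by
#' prevalence, doublet merging, then sequencing errors.
#'
#' @param n cells; \code{m} mutations.
#' @param m number of mutations.
#' @param pattern "LINEAR" or "BRANCHED" ground truth.
#' @param beta,alpha,delta false-negative, false-positive and doublet
#'   probabilities.
#' @param seed optional integer seed fixing the whole instance.
#' @param branchFactor passed to \code{\link{generateCloneTree}}.
#' @return List with \code{tree} (\linkS4class{CloneTree}), \code{truth}
#'   (error-free \linkS4class{GenotypeMatrix}) and \code{observed}
#'   (after doublets and errors; metadata carries injected positions).
#' @examples
#' sim <- simulateInstance(50, 5, "LINEAR", beta = 0.1, seed = 7)
#' objectiveY(solveLPPF(sim$observed)) <= nrow(metadata(sim$observed)$injectedFN)
#' @export
simulateInstance <- function(n, m, pattern, beta = 0, alpha = 0, delta = 0,
                             seed = NULL, branchFactor = 1) {
  .withSeed(seed, {
    tree <- generateCloneTree(m, pattern, branchFactor = branchFactor)
    truth <- sampleCells(tree, n)
    obs <- injectDoublets(truth, tree, delta)
    obs <- injectErrors(obs, beta, alpha)
    list(tree = tree, truth = truth, observed = obs)
  })
}
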