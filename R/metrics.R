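#' Estimated false-negative fraction
#'
#' The fraction betaHat = y / N of the ones in the completed matrix that
#' were created by 0->1 flips.  Defined as 0 (with a warning) when N = 0.
#'
#' @param y number of 0->1 flips, 0 <= y <= N.
#' @param N total ones in the completed matrix.
#' @return Numeric fraction in [0, 1].
#' @examples
#' estimatedBeta(5, 100)  # 0.05
#' @export
estimatedBeta <- function(y, N) {
  if (y < 0 || N < 0) stop("y and N must be non-negative")
  if (y > N) stop("y cannot exceed N")
  if (N == 0) {
    warning("N = 0 ones in the completed matrix; reporting betaHat = 0")
    return(0)
  }
  y / N
}

# pair set from nested one-state groups: 'groups' is a list of character
# vectors of mutations, ordered root-adjacent (largest one-state) first;
# mutations sharing a group share a pseudo-edge and form no pair
.pairsFromChainGroups <- function(groups) {
  anc <- character(0)
  des <- character(0)
  ng <- length(groups)
  if (ng >= 2L) {
    for (a in seq_len(ng - 1L)) {
      below <- unlist(groups[(a + 1L):ng])
      anc <- c(anc, rep(groups[[a]], each = length(below)))
      des <- c(des, rep(below, times = length(groups[[a]])))
    }
  }
  out <- data.frame(ancestor = anc, descendant = des,
                    stringsAsFactors = FALSE)
  attr(out, "mutations") <- sort(unlist(groups))
  out
}

.adPairsFromBinaryMatrix <- function(g) {
  chk <- isLinear(GenotypeMatrix(g))
  if (!chk$linear)
    stop("matrix is not a linear perfect phylogeny")
  card <- colSums(g)
  key <- apply(g, 2L, paste0, collapse = "")
  groups <- split(colnames(g), key)
  groups <- groups[order(-vapply(groups, function(ms) card[[ms[1L]]], 0))]
  .pairsFromChainGroups(unname(groups))
}

#' Ancestor-descendant pairs of an edge-labeled tree
#'
#' The set of ordered mutation pairs (x, y) such that x labels a strict
#' ancestor edge of the edge labeled by y.  Mutations on the same edge form
#' no pair.  For a linear solution, the "edges" are the groups of mutations
#' with identical one-states in the completed matrix, ordered by one-state
#' containment.
#'
#' @param x a \linkS4class{CloneTree}, an \linkS4class{LppfSolution}, or a
#'   complete linear \linkS4class{GenotypeMatrix}.
#' @param ... unused.
#' @return data.frame with character columns \code{ancestor} and
#'   \code{descendant}; the full mutation universe is in
#'   \code{attr(, "mutations")}.
#' @examples
#' chain <- CloneTree(c(0L, 1L, 2L), list("A", "B", "C"), rep(1 / 3, 3))
#' adPairs(chain)  # (A,B), (A,C), (B,C)
#' @export
setMethod("adPairs", "CloneTree", function(x, ...) {
  k <- length(x@parent)
  anc <- character(0)
  des <- character(0)
  for (cl in seq_len(k)) {
    node <- x@parent[cl]
    while (node != 0L) {
      up <- x@edgeMutations[[node]]
      dn <- x@edgeMutations[[cl]]
      anc <- c(anc, rep(up, each = length(dn)))
      des <- c(des, rep(dn, times = length(up)))
      node <- x@parent[node]
    }
  }
  out <- data.frame(ancestor = anc, descendant = des,
                    stringsAsFactors = FALSE)
  attr(out, "mutations") <- sort(unlist(x@edgeMutations))
  out
})

#' @rdname adPairs-CloneTree-method
#' @export
setMethod("adPairs", "LppfSolution", function(x, ...) {
  .adPairsFromBinaryMatrix(flippedMatrix(x))
})

#' @rdname adPairs-CloneTree-method
#' @export
setMethod("adPairs", "GenotypeMatrix", function(x, ...) {
  g <- genotypes(x)
  if (any(is.na(g)))
    stop("ancestor-descendant pairs require a complete matrix")
  .adPairsFromBinaryMatrix(g)
})

.asPairSet <- function(x) {
  if (is.data.frame(x)) return(x)
  adPairs(x)
}

#' Ancestor-descendant distance between two trees
#'
#' The size of the symmetric difference between the ancestor-descendant pair
#' sets of two edge-labeled trees over the same mutations.  Zero iff the
#' trees impose identical ancestral orderings; symmetric by construction.
#'
#' @param x,y trees (\linkS4class{CloneTree}, \linkS4class{LppfSolution},
#'   linear \linkS4class{GenotypeMatrix}) or precomputed \code{adPairs}
#'   data.frames.
#' @return Non-negative integer.
#' @examples
#' chain <- CloneTree(c(0L, 1L, 2L), list("A", "B", "C"), rep(1 / 3, 3))
#' star <- CloneTree(c(0L, 1L, 1L), list("A", "B", "C"), rep(1 / 3, 3))
#' adDistance(chain, star)  # 1: pair (B,C) only in the chain
#' @export
setMethod("adDistance", signature("ANY", "ANY"), function(x, y) {
  px <- .asPairSet(x)
  py <- .asPairSet(y)
  mx <- attr(px, "mutations")
  my <- attr(py, "mutations")
  if (!is.null(mx) && !is.null(my) && !identical(mx, my))
    stop("trees are labeled by different mutation sets")
  kx <- paste(px$ancestor, px$descendant, sep = "\r")
  ky <- paste(py$ancestor, py$descendant, sep = "\r")
  length(setdiff(kx, ky)) + length(setdiff(ky, kx))
})

#' Summarize a grid of classification outcomes
#'
#' @param results data.frame with at least columns \code{truth},
#'   \code{label}, \code{beta_hat} and \code{K} (one row per instance), as
#'   produced by \code{\link{runRobustnessGrid}}.
#' @return List with overall \code{accuracy}, the truth-by-label
#'   \code{counts} table, and per-truth medians of betaHat and K.
#' @export
confusionSummary <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("empty results")
  stopifnot(all(c("truth", "label", "beta_hat", "K") %in% names(results)))
  acc <- mean(results$label == results$truth)
  counts <- table(truth = results$truth, label = results$label)
  med <- function(v) stats::median(v, na.rm = TRUE)
  byTruth <- split(results, results$truth)
  list(accuracy = acc,
       counts = counts,
       medianBetaHat = vapply(byTruth, function(d) med(d$beta_hat), 0),
       medianK = vapply(byTruth, function(d) med(d$K), 0))
}
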