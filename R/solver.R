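#' Estimate the false-positive budget z
#'
#' Given a false-positive rate alpha, the expected number of false positives
#' among the observed ones is alpha times the number of 1-entries; the budget
#' is its ceiling.  Missing entries are excluded from the count.
#'
#' @param B a \linkS4class{GenotypeMatrix}.
#' @param alpha false-positive rate in [0, 1).
#' @return Non-negative integer budget for 1->0 flips.
#' @examples
#' B <- GenotypeMatrix(matrix(1L, 10, 25))
#' computeZ(B, 0.01)  # ceiling(2.5) = 3
#' @export
computeZ <- function(B, alpha) {
  stopifnot(is(B, "GenotypeMatrix"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("alpha must be a single value in [0, 1)")
  ones <- sum(genotypes(B) == 1L, na.rm = TRUE)
  as.integer(ceiling(alpha * ones))
}

# normalize a user-supplied column order to integer indices
.orderIndices <- function(B, order) {
  m <- nMutations(B)
  if (is.character(order))
    order <- match(order, mutationNames(B))
  order <- as.integer(order)
  if (length(order) != m || anyNA(order) || !setequal(order, seq_len(m)))
    stop("'order' must be a permutation of the ", m, " columns")
  order
}

#' Minimum flips under a fixed mutation order
#'
#' Restricts the flipping problem to a fixed column permutation: with the
#' one-states nested along \code{order} (most-derived mutation first), every
#' row of the completed matrix must read as zeros followed by ones.  For each
#' row, each cut position has a 0->1 cost (zeros inside the tail of ones) and
#' a 1->0 cost (observed ones outside it); a small knapsack allocates the
#' shared budget z across rows exactly.  Missing entries cost nothing either
#' way.
#'
#' @param B a \linkS4class{GenotypeMatrix}.
#' @param order a permutation of the columns (indices or labels),
#'   most-derived mutation first.
#' @param z non-negative integer cap on total 1->0 flips.
#' @return List with \code{flips} (minimum total 0->1 flips), \code{cuts}
#'   (per-row number of ones kept at the rootward end of \code{order}) and
#'   \code{flips1to0} (total 1->0 flips used).
#' @examples
#' B <- GenotypeMatrix(rbind(c(1, 0), c(0, 1)))
#' permutationCost(B, c(2, 1), z = 0)$flips  # 1
#' @export
permutationCost <- function(B, order, z = 0L) {
  stopifnot(is(B, "GenotypeMatrix"))
  ordIdx <- .orderIndices(B, order)
  z <- as.integer(z)
  if (z < 0) stop("z must be non-negative")
  g <- genotypes(B)[, ordIdx, drop = FALSE]
  n <- nrow(g)
  m <- ncol(g)
  # tail scans: c01[i, t+1] = zeros among the last t columns,
  #             c10[i, t+1] = observed ones outside that tail
  isOne <- (!is.na(g) & g == 1L) + 0L
  isZero <- (!is.na(g) & g == 0L) + 0L
  onesTail <- isOne[, rev(seq_len(m)), drop = FALSE]
  zerosTail <- isZero[, rev(seq_len(m)), drop = FALSE]
  if (m >= 2L) {
    for (k in 2L:m) {
      onesTail[, k] <- onesTail[, k] + onesTail[, k - 1L]
      zerosTail[, k] <- zerosTail[, k] + zerosTail[, k - 1L]
    }
  }
  totalOnes <- rowSums(isOne)
  c01 <- cbind(0L, zerosTail)                 # t = 0..m
  c10 <- cbind(totalOnes, totalOnes - onesTail)

  cuts <- integer(n)
  if (z == 0L) {
    for (i in seq_len(n)) {
      feas <- which(c10[i, ] == 0L)
      cuts[i] <- feas[which.min(c01[i, feas])] - 1L
    }
  } else {
    # dp[b+1] = min total 0->1 cost with total 1->0 cost <= b
    dp <- numeric(z + 1L)
    choice <- matrix(0L, n, z + 1L)
    for (i in seq_len(n)) {
      ndp <- rep(Inf, z + 1L)
      nch <- integer(z + 1L)
      for (t in 0L:m) {
        w <- c10[i, t + 1L]
        if (w > z) next
        idx <- (w + 1L):(z + 1L)
        cand <- dp[idx - w] + c01[i, t + 1L]
        upd <- cand < ndp[idx]
        ndp[idx[upd]] <- cand[upd]
        nch[idx[upd]] <- t
      }
      dp <- ndp
      choice[i, ] <- nch
    }
    b <- z
    for (i in rev(seq_len(n))) {
      t <- choice[i, b + 1L]
      cuts[i] <- t
      b <- b - c10[i, t + 1L]
    }
  }
  idx <- cbind(seq_len(n), cuts + 1L)
  list(flips = as.integer(sum(c01[idx])),
       cuts = cuts,
       flips1to0 = as.integer(sum(c10[idx])))
}

# assemble an LppfSolution from an order (most-derived first) and row cuts
.buildSolution <- function(B, ordIdx, cuts, z, status, seed, runtime) {
  g <- genotypes(B)
  n <- nrow(g)
  m <- ncol(g)
  flipped <- matrix(0L, n, m, dimnames = dimnames(g))
  for (i in seq_len(n)) {
    if (cuts[i] > 0L)
      flipped[i, ordIdx[(m - cuts[i] + 1L):m]] <- 1L
  }
  f01 <- which(!is.na(g) & g == 0L & flipped == 1L, arr.ind = TRUE)
  f10 <- which(!is.na(g) & g == 1L & flipped == 0L, arr.ind = TRUE)
  miss <- which(is.na(g), arr.ind = TRUE)
  colnames(f01) <- colnames(f10) <- c("cell", "mutation")
  imputed <- cbind(miss, value = flipped[miss])
  if (nrow(imputed)) colnames(imputed) <- c("cell", "mutation", "value")
  new("LppfSolution",
      flippedMatrix = flipped,
      order = colnames(g)[ordIdx],
      flips0to1 = f01,
      flips1to0 = f10,
      imputedMissing = imputed,
      objectiveY = nrow(f01),
      status = status,
      z = as.integer(z),
      seed = as.integer(seed),
      runtime = as.numeric(runtime))
}

#' Solve the minimum-flip linear perfect phylogeny problem
#'
#' Finds the minimum number of 0->1 flips (putative false negatives) turning
#' the observed matrix into a linear perfect phylogeny, allowing at most
#' \code{z} 1->0 flips (putative false positives).  Missing entries are free:
#' they may take either value at no cost and count toward neither flip set
#' nor the budget.  The search is an exact anytime branch-and-bound over
#' column orderings; given enough time it proves optimality
#' (\code{status = "OPTIMAL"}), otherwise it returns the best incumbent
#' (\code{status = "FEASIBLE_TIMEOUT"}).  A feasible solution always exists
#' (flip everything to 1), so the solver never fails on valid input.
#'
#' @param B a \linkS4class{GenotypeMatrix}.
#' @param z non-negative integer cap on 1->0 flips; default 0.
#' @param alpha alternatively, a false-positive rate from which \code{z} is
#'   derived via \code{\link{computeZ}}.  Supply \code{z} or \code{alpha},
#'   not both.
#' @param timeLimit wall-clock limit for the search, in seconds.
#' @param seed integer seed fixing the search randomization (tie-breaking
#'   and randomized greedy starts); with the same seed and a time limit long
#'   enough to prove optimality, the objective is deterministic.
#' @return An \linkS4class{LppfSolution}.
#' @examples
#' B <- GenotypeMatrix(rbind(c(1, 0), c(0, 1)))
#' objectiveY(solveLPPF(B, z = 0))  # 1
#' objectiveY(solveLPPF(B, z = 1))  # 0
#' @seealso \code{\link{bruteForceLPPF}} for the enumeration oracle,
#'   \code{\link{classifyMatrix}} for the downstream classification.
#' @export
solveLPPF <- function(B, z = NULL, alpha = NULL, timeLimit = 500, seed = 1L) {
  stopifnot(is(B, "GenotypeMatrix"))
  if (!is.null(z) && !is.null(alpha))
    stop("supply either 'z' or 'alpha', not both")
  if (is.null(z))
    z <- if (is.null(alpha)) 0L else computeZ(B, alpha)
  z <- as.integer(z)
  if (is.na(z) || z < 0L) stop("z must be a non-negative integer")
  if (!is.numeric(timeLimit) || timeLimit <= 0)
    stop("timeLimit must be positive")
  seed <- as.integer(seed)
  res <- .lppf_search_cpp(genotypes(B), z, as.numeric(timeLimit), seed)
  ordIdx <- rev(res$order + 1L)  # root-adjacent-first -> derived-first
  pc <- permutationCost(B, ordIdx, z)
  if (pc$flips != res$objective)
    stop("internal error: search and reconstruction objectives disagree (",
         res$objective, " vs ", pc$flips, ")")
  sol <- .buildSolution(B, ordIdx, pc$cuts, z,
                        if (res$optimal) "OPTIMAL" else "FEASIBLE_TIMEOUT",
                        seed, res$runtime)
  stopifnot(objectiveY(sol) == res$objective)
  sol
}

# all permutations of 1..m, one per row
.permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(m - 1L)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    rest <- seq_len(m)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), m - 1L))
  }
  do.call(rbind, out)
}

#' Brute-force oracle for the flipping problem
#'
#' Minimizes \code{\link{permutationCost}} over all m! column orders.  Exact
#' by construction and independent of the branch-and-bound search; intended
#' for validation on small instances.
#'
#' @param B a \linkS4class{GenotypeMatrix}.
#' @param z non-negative integer cap on 1->0 flips.
#' @param maxM guard on the number of columns (default 8; 8! = 40320 orders).
#' @return An \linkS4class{LppfSolution} with \code{status = "OPTIMAL"}.
#' @export
bruteForceLPPF <- function(B, z = 0L, maxM = 8L) {
  stopifnot(is(B, "GenotypeMatrix"))
  m <- nMutations(B)
  if (m > maxM)
    stop("bruteForceLPPF enumerates m! orders; m = ", m,
         " exceeds the guard (", maxM, ")")
  z <- as.integer(z)
  if (is.na(z) || z < 0L) stop("z must be a non-negative integer")
  t0 <- proc.time()[["elapsed"]]
  perms <- .permutations(m)
  best <- NULL
  bestOrd <- NULL
  for (r in seq_len(nrow(perms))) {
    pc <- permutationCost(B, perms[r, ], z)
    if (is.null(best) || pc$flips < best$flips) {
      best <- pc
      bestOrd <- perms[r, ]
    }
  }
  .buildSolution(B, bestOrd, best$cuts, z, "OPTIMAL", 0L,
                 proc.time()[["elapsed"]] - t0)
}
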