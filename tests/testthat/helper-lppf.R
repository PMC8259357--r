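# shared fixtures and independent checkers for the test suite

# random 0/1/NA genotype matrix
randomGenotypeMatrix <- function(n, m, density = 0.5, missingProp = 0) {
  g <- matrix(rbinom(n * m, 1L, density), n, m)
  if (missingProp > 0) {
    k <- max(1L, round(missingProp * length(g)))
    g[sample(length(g), k)] <- NA_integer_
  }
  GenotypeMatrix(g)
}

# forbidden-submatrix characterization: a complete binary matrix has nested
# one-states iff no pair of columns (j, k) has both a row (1, 0) and a row
# (0, 1) -- the 2x2 identity pattern of conflicting chain-graph edges
hasConflictPair <- function(g) {
  m <- ncol(g)
  if (m < 2L) return(FALSE)
  for (j in seq_len(m - 1L)) {
    for (k in (j + 1L):m) {
      a <- g[, j]
      b <- g[, k]
      if (any(a == 1L & b == 0L) && any(a == 0L & b == 1L)) return(TRUE)
    }
  }
  FALSE
}

# linearity by exhaustive enumeration over all m! column orders
exhaustiveIsLinear <- function(g) {
  m <- ncol(g)
  perms <- lppf:::.permutations(m)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    ok <- TRUE
    for (k in seq_len(m - 1L)) {
      a <- g[, ord[k]]
      b <- g[, ord[k + 1L]]
      if (any(a == 1L & b == 0L)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# direct (non-log) evaluation of the beta-binomial pmf as a product of
# small factors: C(N,y) * prod(th1+k) * prod(th2+k) / prod(th1+th2+k)
directBetaBinom <- function(y, N, th1, th2) {
  num1 <- if (y > 0) prod(th1 + 0:(y - 1)) else 1
  num2 <- if (N - y > 0) prod(th2 + 0:(N - y - 1)) else 1
  den <- prod(th1 + th2 + 0:(N - 1))
  choose(N, y) * num1 * num2 / den
}
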