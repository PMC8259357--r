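#' Construct a GenotypeMatrix
#'
#' Wraps an n x m matrix of 0/1/NA mutation calls (rows = cells, columns =
#' mutations) in a validated container.  \code{NA} marks missing data.
#'
#' @param x matrix (numeric, integer or logical) with entries 0, 1 or NA.
#' @param cellNames,mutationNames optional label vectors; defaults are taken
#'   from \code{dimnames(x)} or generated as \code{cell1..n} / \code{mut1..m}.
#' @param metadata optional list of annotations.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' B <- GenotypeMatrix(rbind(c(1, 0), c(1, 1)))
#' oneState(B, 2)
#' isLinear(B)
#' @export
GenotypeMatrix <- function(x, cellNames = NULL, mutationNames = NULL,
                           metadata = list()) {
  if (is.logical(x)) x <- x + 0L
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("matrix must have at least one cell and one mutation")
  if (is.null(cellNames))
    cellNames <- rownames(x)
  if (is.null(cellNames))
    cellNames <- paste0("cell", seq_len(nrow(x)))
  if (is.null(mutationNames))
    mutationNames <- colnames(x)
  if (is.null(mutationNames))
    mutationNames <- paste0("mut", seq_len(ncol(x)))
  dimnames(x) <- list(as.character(cellNames), as.character(mutationNames))
  new("GenotypeMatrix", genotypes = x, metadata = metadata)
}

#' @describeIn GenotypeMatrix the underlying integer matrix (NA = missing).
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)

#' @describeIn GenotypeMatrix cell labels.
#' @export
setMethod("cellNames", "GenotypeMatrix", function(x) rownames(x@genotypes))

#' @describeIn GenotypeMatrix mutation labels.
#' @export
setMethod("mutationNames", "GenotypeMatrix", function(x) colnames(x@genotypes))

#' @describeIn GenotypeMatrix number of cells (rows).
#' @export
setMethod("nCells", "GenotypeMatrix", function(x) nrow(x@genotypes))

#' @describeIn GenotypeMatrix number of mutations (columns).
#' @export
setMethod("nMutations", "GenotypeMatrix", function(x) ncol(x@genotypes))

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@genotypes))

#' @export
setMethod("metadata", "GenotypeMatrix", function(x, ...) x@metadata)

#' @export
setReplaceMethod("metadata", "GenotypeMatrix", function(x, ..., value) {
  x@metadata <- value
  validObject(x)
  x
})

#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  g <- x@genotypes[i, j, drop = FALSE]
  new("GenotypeMatrix", genotypes = g, metadata = x@metadata)
})

setMethod("show", "GenotypeMatrix", function(object) {
  g <- object@genotypes
  nm <- sum(is.na(g))
  cat(sprintf("GenotypeMatrix: %d cells x %d mutations\n", nrow(g), ncol(g)))
  cat(sprintf("  ones: %d  zeros: %d  missing: %d (%.1f%%)\n",
              sum(g == 1L, na.rm = TRUE), sum(g == 0L, na.rm = TRUE),
              nm, 100 * nm / length(g)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' One-state of a mutation
#'
#' The one-state O_j of mutation j is the set of cells in which the mutation
#' is observed (entries equal to 1).  Missing entries are excluded.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param j column index (1-based) or mutation label.
#' @return Integer vector of cell indices (sorted).
#' @export
setMethod("oneState", "GenotypeMatrix", function(x, j) {
  g <- x@genotypes
  if (is.character(j)) {
    jj <- match(j, colnames(g))
    if (is.na(jj)) stop("unknown mutation label: ", j)
    j <- jj
  }
  if (length(j) != 1L || is.na(j) || j < 1L || j > ncol(g))
    stop("mutation index out of range")
  which(!is.na(g[, j]) & g[, j] == 1L)
})

#' Test whether a binary matrix is a linear perfect phylogeny
#'
#' A complete binary matrix is a linear perfect phylogeny when its one-states
#' can be totally ordered by set inclusion.  Columns are sorted by one-state
#' cardinality (stable on ties, so mutations carried by the same cells keep
#' their input order) and adjacent containment is verified, which suffices
#' because set inclusion on a chain is transitive.
#'
#' @param x a \linkS4class{GenotypeMatrix} without missing entries.
#' @param ... unused.
#' @return A list with \code{linear} (logical) and \code{order}: when linear,
#'   the column indices sorted so that one-states are nested, most-derived
#'   mutation (smallest one-state) first; otherwise \code{NULL}.
#' @examples
#' isLinear(GenotypeMatrix(rbind(c(1, 0), c(1, 1))))$linear  # TRUE
#' isLinear(GenotypeMatrix(rbind(c(1, 0), c(0, 1))))$linear  # FALSE
#' @export
setMethod("isLinear", "GenotypeMatrix", function(x, ...) {
  g <- x@genotypes
  if (any(is.na(g)))
    stop("matrix has missing entries; linearity is defined only for ",
         "complete matrices (use solveLPPF to impute)")
  card <- colSums(g)
  ord <- order(card)  # stable; ties keep column order
  m <- ncol(g)
  if (m >= 2L) {
    for (k in seq_len(m - 1L)) {
      a <- g[, ord[k]]
      b <- g[, ord[k + 1L]]
      if (any(a == 1L & b == 0L))
        return(list(linear = FALSE, order = NULL))
    }
  }
  list(linear = TRUE, order = ord)
})
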