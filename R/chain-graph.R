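#' Convert between genotype matrices and bipartite (chain) graphs
#'
#' A complete binary genotype matrix is equivalently a bipartite graph with
#' cells on one side, mutations on the other, and an edge (i, j) exactly when
#' cell i carries mutation j.  The matrix is a linear perfect phylogeny if and
#' only if the graph is a chain graph, i.e. the mutation-side neighborhoods
#' are totally ordered by inclusion.  The two maps below are mutual inverses.
#'
#' @param x a \linkS4class{GenotypeMatrix} without missing entries.
#' @return \code{matrixToChainGraph}: a bipartite \code{igraph} graph whose
#'   vertices carry a logical \code{type} attribute (FALSE = cell,
#'   TRUE = mutation) and names taken from the matrix labels.
#' @examples
#' B <- GenotypeMatrix(rbind(c(1, 0), c(0, 1)))
#' g <- matrixToChainGraph(B)
#' identical(genotypes(chainGraphToMatrix(g)), genotypes(B))
#' @export
matrixToChainGraph <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  g <- genotypes(x)
  if (any(is.na(g)))
    stop("chain-graph conversion requires a complete (no missing) matrix")
  igraph::graph_from_biadjacency_matrix(g)
}

#' @rdname matrixToChainGraph
#' @param graph a bipartite \code{igraph} graph with a \code{type} vertex
#'   attribute (FALSE side = cells, TRUE side = mutations).
#' @return \code{chainGraphToMatrix}: the \linkS4class{GenotypeMatrix} whose
#'   entry (i, j) is 1 exactly when the graph has edge (cell i, mutation j).
#' @export
chainGraphToMatrix <- function(graph) {
  stopifnot(igraph::is_bipartite(graph))
  g <- igraph::as_biadjacency_matrix(graph, sparse = FALSE)
  storage.mode(g) <- "integer"
  GenotypeMatrix(g)
}
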