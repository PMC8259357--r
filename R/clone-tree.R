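#' Construct a clonal tree
#'
#' @param parent integer vector; \code{parent[k]} is the parent of clone k
#'   (0 = root / normal cell).  Clones must be topologically ordered.
#' @param edgeMutations list of character vectors: the mutations gained on
#'   the edge into each clone (at least one per edge; jointly disjoint).
#' @param prevalence per-clone sampling fractions; normalized to sum to 1.
#' @param pattern "LINEAR" or "BRANCHED"; derived from the topology when
#'   omitted.
#' @return A \linkS4class{CloneTree}.
#' @examples
#' tr <- CloneTree(c(0L, 1L, 2L), list("A", "B", "C"), rep(1 / 3, 3))
#' treePattern(tr)  # LINEAR
#' @export
CloneTree <- function(parent, edgeMutations, prevalence, pattern = NULL) {
  parent <- as.integer(parent)
  k <- length(parent)
  edgeMutations <- lapply(edgeMutations, as.character)
  prevalence <- as.numeric(prevalence)
  if (sum(prevalence) > 0) prevalence <- prevalence / sum(prevalence)
  if (is.null(pattern)) {
    nChildren <- tabulate(parent[parent > 0L], nbins = k)
    branched <- any(nChildren >= 2L) || sum(parent == 0L) >= 2L
    pattern <- if (branched) "BRANCHED" else "LINEAR"
  }
  new("CloneTree", parent = parent, edgeMutations = edgeMutations,
      prevalence = prevalence, pattern = pattern)
}

#' @describeIn CloneTree-class binary clone-by-mutation genotype matrix;
#'   row k is the union of the mutations on clone k's root path.
#' @param x a \linkS4class{CloneTree}.
#' @export
setMethod("cloneGenotypes", "CloneTree", function(x) {
  k <- length(x@parent)
  muts <- unlist(x@edgeMutations)
  g <- matrix(0L, k, length(muts),
              dimnames = list(paste0("clone", seq_len(k)), muts))
  for (cl in seq_len(k)) {
    node <- cl
    while (node != 0L) {
      g[cl, x@edgeMutations[[node]]] <- 1L
      node <- x@parent[node]
    }
  }
  g
})

#' @describeIn CloneTree-class per-clone sampling fractions.
#' @export
setMethod("prevalence", "CloneTree", function(x) x@prevalence)

#' @describeIn CloneTree-class "LINEAR" or "BRANCHED".
#' @export
setMethod("treePattern", "CloneTree", function(x) x@pattern)

setMethod("show", "CloneTree", function(object) {
  k <- length(object@parent)
  cat(sprintf("CloneTree (%s): %d clones, %d mutations\n", object@pattern,
              k, length(unlist(object@edgeMutations))))
  for (cl in seq_len(min(k, 12L))) {
    cat(sprintf("  clone%d <- %s : {%s} prevalence %.3f\n", cl,
                if (object@parent[cl] == 0L) "root"
                else paste0("clone", object@parent[cl]),
                paste(object@edgeMutations[[cl]], collapse = ","),
                object@prevalence[cl]))
  }
  if (k > 12L) cat("  ...\n")
})
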