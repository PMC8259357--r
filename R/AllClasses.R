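#' @import methods
NULL

.MISSING_CODES <- c("3", "?")

#' GenotypeMatrix: observed single-cell genotypes
#'
#' An n x m binary matrix of mutation presence/absence calls, rows = cells,
#' columns = single-nucleotide variants (SNVs).  Entries are 0 (absent),
#' 1 (present) or \code{NA} (missing, e.g. zero sequencing coverage at the
#' site).  Row and column names carry the user-facing cell and mutation
#' labels; all internal indexing is positional.
#'
#' @slot genotypes integer matrix over \{0, 1, NA\} with unique dimnames.
#' @slot metadata list of free-form annotations (e.g. the simulator records
#'   clone assignments and injected error positions here).
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(genotypes = "matrix", metadata = "list"),
  prototype(metadata = list())
)

setValidity("GenotypeMatrix", function(object) {
  g <- object@genotypes
  if (!is.matrix(g) || !(is.numeric(g) || is.integer(g)))
    return("'genotypes' must be a numeric matrix")
  if (nrow(g) < 1L || ncol(g) < 1L)
    return("matrix must have at least one cell and one mutation")
  vals <- g[!is.na(g)]
  if (any(vals != 0L & vals != 1L))
    return("entries must be 0, 1 or NA (missing)")
  if (is.null(rownames(g)) || is.null(colnames(g)))
    return("cell and mutation labels are required (dimnames)")
  if (anyDuplicated(rownames(g)))
    return("duplicate cell labels")
  if (anyDuplicated(colnames(g)))
    return("duplicate mutation labels")
  TRUE
})

#' LppfSolution: result of the minimum-flip linear-phylogeny search
#'
#' Holds the completed binary matrix B' (a linear perfect phylogeny), the
#' mutation order realizing the one-state chain, the two flip sets, imputed
#' values for missing entries, the objective (number of 0->1 flips) and the
#' solver status.
#'
#' @slot flippedMatrix integer n x m matrix over \{0,1\}; the matrix B'.
#' @slot order character vector of mutation labels, most-derived mutation
#'   first, so one-states are nested left to right.
#' @slot flips0to1 two-column integer matrix of (cell, mutation) positions
#'   flipped 0 -> 1 (inferred false negatives); \code{nrow} equals the
#'   objective.
#' @slot flips1to0 two-column integer matrix of positions flipped 1 -> 0
#'   (inferred false positives); at most \code{z} rows.
#' @slot imputedMissing three-column integer matrix (cell, mutation, value)
#'   giving the value assigned to each missing entry.
#' @slot objectiveY integer, the number of 0->1 flips.
#' @slot status "OPTIMAL" (proven) or "FEASIBLE_TIMEOUT" (best incumbent at
#'   the time limit).
#' @slot z integer cap on 1->0 flips that was in force.
#' @slot seed integer seed used for search randomization.
#' @slot runtime numeric, wall-clock seconds spent in the search.
#'
#' @aliases LppfSolution-class
#' @exportClass LppfSolution
setClass("LppfSolution",
  representation(
    flippedMatrix = "matrix",
    order = "character",
    flips0to1 = "matrix",
    flips1to0 = "matrix",
    imputedMissing = "matrix",
    objectiveY = "integer",
    status = "character",
    z = "integer",
    seed = "integer",
    runtime = "numeric"
  )
)

setValidity("LppfSolution", function(object) {
  g <- object@flippedMatrix
  if (any(is.na(g)) || any(g != 0L & g != 1L))
    return("flipped matrix must be fully binary")
  if (!setequal(object@order, colnames(g)))
    return("'order' must be a permutation of the mutation labels")
  if (!object@status %in% c("OPTIMAL", "FEASIBLE_TIMEOUT"))
    return("unknown status")
  if (object@objectiveY != nrow(object@flips0to1))
    return("objectiveY must equal the number of 0->1 flips")
  if (nrow(object@flips1to0) > object@z)
    return("more 1->0 flips than the budget z allows")
  TRUE
})

#' HypothesisParams: one beta-binomial evolution hypothesis
#'
#' Parameterizes the distribution of the false-negative fraction under one
#' hypothesis (linear or branched evolution) as a beta distribution with
#' mean \code{mu} and precision \code{s}, stored together with the derived
#' shape parameters theta1 = mu * s and theta2 = s - theta1.
#'
#' @slot mu numeric in (0,1), mean false-negative fraction.
#' @slot s numeric > 0, precision (controls dispersion).
#' @slot theta1,theta2 numeric > 0, derived beta shape parameters.
#'
#' @aliases HypothesisParams-class
#' @exportClass HypothesisParams
setClass("HypothesisParams",
  representation(mu = "numeric", s = "numeric",
                 theta1 = "numeric", theta2 = "numeric")
)

setValidity("HypothesisParams", function(object) {
  if (object@mu <= 0 || object@mu >= 1)
    return("mu must lie strictly inside (0,1)")
  if (object@s <= 0)
    return("precision s must be positive")
  if (object@theta1 <= 0 || object@theta2 <= 0)
    return("shape parameters must be positive")
  if (abs(object@theta1 - object@mu * object@s) > 1e-8 ||
      abs(object@theta2 - object@s + object@theta1) > 1e-8)
    return("theta1/theta2 inconsistent with (mu, s)")
  TRUE
})

#' CloneTree: rooted clonal tree with mutation-labeled edges
#'
#' Simulation ground truth: a rooted tree whose non-root nodes are tumor
#' clones.  The edge into clone k is labeled with the mutations gained by
#' that clone; a clone's genotype is the union of the mutations on its
#' root path (infinite sites).  Clonal prevalences give the probability
#' that a sampled cell belongs to each clone.
#'
#' @slot parent integer vector; \code{parent[k]} is the parent clone of
#'   clone k, with 0 denoting the root (normal cell).
#' @slot edgeMutations list of character vectors; mutations gained on the
#'   edge into each clone.  Together they partition the mutation set.
#' @slot prevalence numeric vector of per-clone fractions summing to 1.
#' @slot pattern "LINEAR" or "BRANCHED".
#'
#' @aliases CloneTree-class
#' @exportClass CloneTree
setClass("CloneTree",
  representation(
    parent = "integer",
    edgeMutations = "list",
    prevalence = "numeric",
    pattern = "character"
  )
)

setValidity("CloneTree", function(object) {
  k <- length(object@parent)
  if (k < 1L) return("tree must have at least one clone")
  if (length(object@edgeMutations) != k || length(object@prevalence) != k)
    return("parent, edgeMutations and prevalence lengths must agree")
  if (any(object@parent < 0L) || any(object@parent > k))
    return("parent indices out of range")
  if (any(object@parent >= seq_len(k)))
    return("clones must be topologically ordered (parent index < child index)")
  muts <- unlist(object@edgeMutations)
  if (anyDuplicated(muts))
    return("a mutation may label only one edge")
  if (any(lengths(object@edgeMutations) < 1L))
    return("every edge must carry at least one mutation")
  if (any(object@prevalence < 0))
    return("prevalences must be non-negative")
  if (abs(sum(object@prevalence) - 1) > 1e-9)
    return("prevalences must sum to 1")
  if (!object@pattern %in% c("LINEAR", "BRANCHED"))
    return("pattern must be LINEAR or BRANCHED")
  nChildren <- tabulate(object@parent[object@parent > 0L], nbins = k)
  branched <- any(nChildren >= 2L)
  # the root's children are not branching events of the clonal expansion
  # unless the root itself splits into >= 2 clones
  branched <- branched || sum(object@parent == 0L) >= 2L
  if (object@pattern == "LINEAR" && branched)
    return("pattern LINEAR but a node has >= 2 children")
  if (object@pattern == "BRANCHED" && !branched)
    return("pattern BRANCHED but the tree is a path")
  TRUE
})

#' ClassificationResult: linear-vs-branched call for one matrix
#'
#' @slot y integer, 0->1 flips reported by the solver.
#' @slot N integer, total ones in the flipped matrix B' used as the
#'   denominator of the false-negative fraction.
#' @slot betaHat numeric, y / N (0 when N = 0).
#' @slot K numeric Bayes factor (NA for the threshold heuristic).
#' @slot label "LINEAR", "BRANCHED" or "NOT_REJECTED".
#' @slot method "BAYES" or "THRESHOLD".
#' @slot solverStatus solver status passed through ("OPTIMAL" or
#'   "FEASIBLE_TIMEOUT").
#'
#' @aliases ClassificationResult-class
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  representation(
    y = "integer", N = "integer", betaHat = "numeric", K = "numeric",
    label = "character", method = "character", solverStatus = "character"
  )
)

setValidity("ClassificationResult", function(object) {
  if (object@betaHat < 0 || object@betaHat > 1)
    return("betaHat must lie in [0,1]")
  if (!object@method %in% c("BAYES", "THRESHOLD"))
    return("method must be BAYES or THRESHOLD")
  ok <- switch(object@method,
    BAYES = object@label %in% c("LINEAR", "BRANCHED"),
    THRESHOLD = object@label %in% c("BRANCHED", "NOT_REJECTED"))
  if (!ok) return("label inconsistent with method")
  TRUE
})
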