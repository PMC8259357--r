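#' @describeIn LppfSolution-class the completed binary matrix B'.
#' @param x an \linkS4class{LppfSolution}.
#' @export
setMethod("flippedMatrix", "LppfSolution", function(x) x@flippedMatrix)

#' @describeIn LppfSolution-class mutation labels ordered so one-states are
#'   nested, most-derived mutation first.
#' @export
setMethod("mutationOrder", "LppfSolution", function(x) x@order)

#' @describeIn LppfSolution-class the number of 0->1 flips (objective y).
#' @export
setMethod("objectiveY", "LppfSolution", function(x) x@objectiveY)

#' @describeIn LppfSolution-class "OPTIMAL" or "FEASIBLE_TIMEOUT".
#' @export
setMethod("solverStatus", "LppfSolution", function(x) x@status)

#' @describeIn LppfSolution-class (cell, mutation) positions flipped 0 -> 1
#'   (inferred false negatives).
#' @export
setMethod("fnFlips", "LppfSolution", function(x) x@flips0to1)

#' @describeIn LppfSolution-class (cell, mutation) positions flipped 1 -> 0
#'   (inferred false positives).
#' @export
setMethod("fpFlips", "LppfSolution", function(x) x@flips1to0)

#' @describeIn LppfSolution-class (cell, mutation, value) rows giving the
#'   value imputed at each missing entry.
#' @export
setMethod("imputedPositions", "LppfSolution", function(x) x@imputedMissing)

setMethod("show", "LppfSolution", function(object) {
  g <- object@flippedMatrix
  cat(sprintf("LppfSolution: %d cells x %d mutations (%s)\n",
              nrow(g), ncol(g), object@status))
  cat(sprintf("  flips 0->1 (objective y): %d\n", object@objectiveY))
  cat(sprintf("  flips 1->0: %d (budget z = %d)\n",
              nrow(object@flips1to0), object@z))
  if (nrow(object@imputedMissing))
    cat(sprintf("  imputed missing entries: %d\n",
                nrow(object@imputedMissing)))
  ord <- object@order
  if (length(ord) > 8L)
    ord <- c(ord[1:8], "...")
  cat("  order (derived -> root):", paste(ord, collapse = " < "), "\n")
  cat(sprintf("  runtime: %.2f s\n", object@runtime))
})
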