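.VALID_TOKENS <- c("0", "1", "3", "?")

# pick the field separator by inspection: tab, comma, else whitespace
.detectSep <- function(lines) {
  if (any(grepl("\t", lines))) "\t"
  else if (any(grepl(",", lines))) ","
  else "[[:space:]]+"
}

#' Read a genotype matrix from TSV/CSV
#'
#' Reads SCITE-compatible matrix files: entries 0, 1, and 3 or ? for
#' missing; tab, comma or whitespace separated.  A header row of mutation
#' labels and a first column of cell labels are auto-detected (any token
#' outside \{0, 1, 3, ?\} marks a label line/column).  By convention rows
#' are cells and columns are mutations; use \code{transpose = TRUE} for
#' files in the opposite orientation.
#'
#' @param path file path.
#' @param transpose logical; transpose after reading (for mutations-by-cells
#'   files).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeMatrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  sep <- .detectSep(lines)
  tok <- lapply(lines, function(l) {
    x <- strsplit(trimws(l), sep)[[1]]
    x[nzchar(x) | seq_along(x) == 1L]  # keep a possibly empty corner token
  })
  hasHeader <- !all(tok[[1]] %in% .VALID_TOKENS)
  header <- NULL
  if (hasHeader) {
    header <- tok[[1]]
    tok <- tok[-1]
    if (!length(tok)) stop("header but no data rows in ", path)
  }
  widths <- lengths(tok)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, ": widths ", paste(unique(widths),
                                                     collapse = ", "))
  firstCol <- vapply(tok, `[`, "", 1L)
  hasRowLabels <- !all(firstCol %in% .VALID_TOKENS)
  cellLabels <- NULL
  if (hasRowLabels) {
    cellLabels <- firstCol
    tok <- lapply(tok, `[`, -1L)
  }
  m <- length(tok[[1]])
  if (m < 1L) stop("no data columns in ", path)
  mutLabels <- NULL
  if (hasHeader) {
    if (length(header) == m + 1L && hasRowLabels)
      header <- header[-1L]  # corner label above the cell-label column
    if (length(header) != m)
      stop("header has ", length(header), " labels for ", m, " columns")
    mutLabels <- header
  }
  flat <- unlist(tok)
  bad <- setdiff(unique(flat), .VALID_TOKENS)
  if (length(bad))
    stop("illegal symbols in ", path, ": ",
         paste(utils::head(bad, 5), collapse = " "))
  flat[flat %in% c("3", "?")] <- NA_character_
  g <- matrix(as.integer(flat), nrow = length(tok), ncol = m, byrow = TRUE)
  rownames(g) <- cellLabels
  colnames(g) <- mutLabels
  if (transpose) {
    g <- t(g)
    B <- GenotypeMatrix(g)
  } else {
    B <- GenotypeMatrix(g)
  }
  B
}

#' Write a genotype matrix as TSV
#'
#' Missing entries are written as 3 (SCITE convention).  With
#' \code{labels = TRUE} a header of mutation labels (corner token
#' \code{"cell"}) and a first column of cell labels are included, so
#' \code{readGenotypeMatrix(writeGenotypeMatrix(B, f))} round-trips.
#'
#' @param B a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @param labels include cell/mutation labels?
#' @return Invisibly, \code{path}.
#' @export
writeGenotypeMatrix <- function(B, path, labels = TRUE) {
  stopifnot(is(B, "GenotypeMatrix"))
  g <- genotypes(B)
  ch <- matrix(as.character(g), nrow(g), ncol(g))
  ch[is.na(g)] <- "3"
  rows <- apply(ch, 1L, paste, collapse = "\t")
  if (labels) {
    rows <- paste(rownames(g), rows, sep = "\t")
    rows <- c(paste(c("cell", colnames(g)), collapse = "\t"), rows)
  }
  writeLines(rows, path)
  invisible(path)
}

#' Discretize variant/total read counts into genotype calls
#'
#' A site in a cell is called mutated when the one-sided binomial exact
#' test of observing at least \code{variant} successes in \code{total}
#' trials under the null per-read error rate is significant: the call is 1
#' iff P(X >= variant | total, nullRate) < pCut.  Sites with zero total
#' reads carry no information and are labeled missing.
#'
#' @param variant,total non-negative integer matrices of identical shape
#'   (cells x sites) with \code{variant <= total}.
#' @param nullRate per-read error rate under the null (default 0.001).
#' @param pCut p-value cutoff (default 1e-6).
#' @return A \linkS4class{GenotypeMatrix} with NA where \code{total == 0}.
#' @examples
#' v <- matrix(c(0L, 10L, 0L, 2L), 2, 2)
#' t <- matrix(c(0L, 10L, 100L, 100L), 2, 2)
#' genotypes(discretizeCounts(v, t))
#' @export
discretizeCounts <- function(variant, total, nullRate = 0.001, pCut = 1e-6) {
  variant <- as.matrix(variant)
  total <- as.matrix(total)
  if (!identical(dim(variant), dim(total)))
    stop("variant and total matrices must have identical dimensions")
  if (any(variant < 0) || any(total < 0))
    stop("read counts must be non-negative")
  if (any(variant > total))
    stop("variant reads exceed total reads at ",
         sum(variant > total), " positions")
  if (nullRate <= 0 || nullRate >= 1) stop("nullRate must lie in (0, 1)")
  # P(X >= variant) under Binomial(total, nullRate)
  p <- stats::pbinom(variant - 1L, total, nullRate, lower.tail = FALSE)
  g <- matrix(as.integer(p < pCut), nrow(variant), ncol(variant))
  g[total == 0L] <- NA_integer_
  dimnames(g) <- dimnames(variant)
  GenotypeMatrix(g)
}

#' Serialize a solution or classification to JSON
#'
#' @param sol an \linkS4class{LppfSolution}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSolution <- function(sol, path) {
  stopifnot(is(sol, "LppfSolution"))
  g <- flippedMatrix(sol)
  pairList <- function(pos) {
    if (!nrow(pos)) return(list())
    lapply(seq_len(nrow(pos)), function(r)
      list(cell = rownames(g)[pos[r, "cell"]],
           mutation = colnames(g)[pos[r, "mutation"]]))
  }
  imp <- imputedPositions(sol)
  impList <- if (nrow(imp)) lapply(seq_len(nrow(imp)), function(r)
    list(cell = rownames(g)[imp[r, "cell"]],
         mutation = colnames(g)[imp[r, "mutation"]],
         value = unname(imp[r, "value"]))) else list()
  jsonlite::write_json(list(
    objective = objectiveY(sol),
    status = solverStatus(sol),
    order = as.list(mutationOrder(sol)),
    flips_0to1 = pairList(fnFlips(sol)),
    flips_1to0 = pairList(fpFlips(sol)),
    imputed = impList,
    z = sol@z,
    seed = sol@seed,
    runtime = sol@runtime
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSolution
#' @param res a \linkS4class{ClassificationResult}.
#' @export
writeClassification <- function(res, path) {
  stopifnot(is(res, "ClassificationResult"))
  jsonlite::write_json(list(
    y = res@y, N = res@N, beta_hat = res@betaHat,
    K = if (is.na(res@K)) NULL else res@K,
    label = res@label, method = res@method,
    solver_status = res@solverStatus
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ms-style simulator output
#'
#' Minimal reader for the classic coalescent-simulator text format: each
#' replicate is a block starting with \code{//}, a \code{segsites:} line, an
#' optional \code{positions:} line, then one 0/1 haplotype string per
#' sampled cell.  Provided as an alternative source of founding matrices
#' for users who prefer coalescent genotypes over \code{\link{generateCloneTree}}.
#'
#' @param path file path.
#' @return List of \linkS4class{GenotypeMatrix}, one per replicate.
#' @export
readMsOutput <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  starts <- which(trimws(lines) == "//")
  if (!length(starts)) stop("no '//' replicate blocks found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(b) {
    block <- lines[starts[b]:ends[b]]
    hap <- block[grepl("^[01]+$", trimws(block))]
    if (!length(hap)) stop("replicate ", b, " has no haplotype rows")
    g <- do.call(rbind, lapply(strsplit(trimws(hap), ""), as.integer))
    GenotypeMatrix(g)
  })
}
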