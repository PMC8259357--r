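#' Convert a (mean, precision) pair to beta shape parameters
#'
#' The two evolution hypotheses are parameterized by the mean mu and
#' precision s of a beta distribution over the false-negative fraction;
#' the shape parameters are theta1 = mu * s and theta2 = s * (1 - mu).
#'
#' @param mu mean in (0, 1), exclusive: boundary values give a degenerate
#'   beta and are rejected.
#' @param s precision, > 0.
#' @return Named numeric vector \code{c(theta1, theta2)}.
#' @examples
#' convertParams(0.05, 10)  # c(theta1 = 0.5, theta2 = 9.5)
#' @export
convertParams <- function(mu, s) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0 || mu >= 1)
    stop("mu must lie strictly inside (0, 1)")
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("precision s must be positive")
  c(theta1 = mu * s, theta2 = s * (1 - mu))
}

#' Construct a beta-binomial hypothesis
#'
#' @param mu mean false-negative fraction in (0, 1).
#' @param s precision > 0.
#' @return A \linkS4class{HypothesisParams}.
#' @examples
#' linear <- HypothesisParams(0.05, 10)
#' branched <- HypothesisParams(0.15, 10)
#' @export
HypothesisParams <- function(mu, s) {
  th <- convertParams(mu, s)
  new("HypothesisParams", mu = mu, s = s,
      theta1 = unname(th[1L]), theta2 = unname(th[2L]))
}

setMethod("show", "HypothesisParams", function(object) {
  cat(sprintf(
    "HypothesisParams: mu = %.4g, s = %.4g (theta1 = %.4g, theta2 = %.4g)\n",
    object@mu, object@s, object@theta1, object@theta2))
})

#' Beta-binomial log-likelihood
#'
#' Log of choose(N, y) * Beta(theta1 + y, N - y + theta2) /
#' Beta(theta1, theta2), evaluated entirely in log-gamma space so that N in
#' the thousands poses no overflow problem.  This is the marginal likelihood
#' of y flips out of N trials with the latent per-entry flip probability
#' integrated over a Beta(theta1, theta2) prior.
#'
#' @param y number of flips, integer(s) with 0 <= y <= N.
#' @param N number of trials (total ones in the completed matrix).
#' @param theta1,theta2 beta shape parameters, > 0.
#' @return Log-probability (vectorized over \code{y}).
#' @examples
#' exp(betaBinomLogLik(0:2, 2, 1, 1))  # uniform: 1/3 each
#' @export
betaBinomLogLik <- function(y, N, theta1, theta2) {
  if (any(!is.finite(y)) || any(!is.finite(N)))
    stop("y and N must be finite")
  if (any(y != round(y)) || any(N != round(N)))
    stop("y and N must be integers")
  if (any(y < 0) || any(y > N))
    stop("y must satisfy 0 <= y <= N")
  if (theta1 <= 0 || theta2 <= 0)
    stop("shape parameters must be positive")
  lchoose(N, y) + lbeta(theta1 + y, N - y + theta2) - lbeta(theta1, theta2)
}

#' Bayes factor comparing linear and branched evolution
#'
#' K is the ratio of the beta-binomial marginal likelihoods of observing y
#' flips out of N under the linear hypothesis versus the branched
#' hypothesis.  K > 1 is evidence for linear evolution, K < 1 for branched;
#' the magnitude expresses the strength of the evidence.
#'
#' @param y flips found by the solver (0 <= y <= N).
#' @param N total ones in the completed matrix.
#' @param linear,branched \linkS4class{HypothesisParams} for the two
#'   hypotheses.
#' @return The Bayes factor K (numeric).
#' @examples
#' bayesFactor(0, 100, HypothesisParams(0.05, 10), HypothesisParams(0.15, 10))
#' @export
bayesFactor <- function(y, N, linear, branched) {
  stopifnot(is(linear, "HypothesisParams"), is(branched, "HypothesisParams"))
  exp(betaBinomLogLik(y, N, linear@theta1, linear@theta2) -
        betaBinomLogLik(y, N, branched@theta1, branched@theta2))
}

#' Classify an evolutionary pattern from a Bayes factor
#'
#' K > 1 supports linear evolution, K < 1 branched.  The measure-zero tie
#' K = 1 is resolved conservatively to BRANCHED with a warning, since
#' support for linearity requires a strict inequality.
#'
#' @param K positive, finite Bayes factor.
#' @return \code{"LINEAR"} or \code{"BRANCHED"}.
#' @examples
#' classifyBayes(14.0)  # LINEAR
#' classifyBayes(0.3)   # BRANCHED
#' @export
classifyBayes <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("K must be a single positive finite value")
  if (K == 1) {
    warning("K = 1: no evidence either way; reporting BRANCHED conservatively")
    return("BRANCHED")
  }
  if (K > 1) "LINEAR" else "BRANCHED"
}

#' Hard-threshold classification of the false-negative fraction
#'
#' Rejects linearity when the estimated false-negative fraction exceeds the
#' threshold betaStar (e.g. the known rate of the sequencing technology).
#' Unlike the Bayes factor, a hard threshold provides no positive evidence
#' for linear evolution, so the non-rejected case is reported as
#' \code{"NOT_REJECTED"} rather than \code{"LINEAR"}.
#'
#' @param betaHat estimated false-negative fraction y/N, in [0, 1].
#' @param betaStar threshold in [0, 1].
#' @return \code{"BRANCHED"} (betaHat strictly greater than betaStar) or
#'   \code{"NOT_REJECTED"}.
#' @examples
#' classifyThreshold(0.36, 0.18)  # BRANCHED
#' classifyThreshold(0.15, 0.18)  # NOT_REJECTED
#' @export
classifyThreshold <- function(betaHat, betaStar) {
  for (v in list(betaHat, betaStar))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("betaHat and betaStar must be single values in [0, 1]")
  if (betaHat > betaStar) "BRANCHED" else "NOT_REJECTED"
}

#' Fit the branched hypothesis from solver output on branched simulations
#'
#' Method-of-moments fit of a beta distribution to a sample of estimated
#' false-negative fractions obtained by running the solver on data simulated
#' under branched evolution: mu is the sample mean and the precision is
#' s = mu * (1 - mu) / var - 1, clamped to [0.5, 1000] to keep the beta
#' proper when the sample is over- or under-dispersed.
#'
#' @param betaHatSamples numeric vector (>= 3 values) of fractions strictly
#'   inside (0, 1) with non-zero variance.
#' @return A \linkS4class{HypothesisParams}.
#' @export
fitBranchedPrior <- function(betaHatSamples) {
  x <- as.numeric(betaHatSamples)
  if (length(x) < 3L)
    stop("need at least 3 samples to fit the branched hypothesis")
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("samples must lie strictly inside (0, 1)")
  v <- stats::var(x)
  if (v == 0)
    stop("zero-variance sample: cannot fit a beta distribution; ",
         "supply mu and s manually via HypothesisParams()")
  mu <- mean(x)
  s <- mu * (1 - mu) / v - 1
  s <- min(max(s, 0.5), 1000)
  HypothesisParams(mu, s)
}

#' Total ones in the completed matrix
#'
#' The denominator N of the estimated false-negative fraction: the number of
#' ones in the flipped matrix B'.  Missing entries imputed to 1 carry no
#' observational evidence, so they are excluded by default.
#'
#' @param sol an \linkS4class{LppfSolution}.
#' @param includeImputed logical; count ones at imputed missing positions?
#' @return Integer N.
#' @export
solutionN <- function(sol, includeImputed = FALSE) {
  stopifnot(is(sol, "LppfSolution"))
  N <- sum(sol@flippedMatrix == 1L)
  if (!includeImputed && nrow(sol@imputedMissing))
    N <- N - sum(sol@imputedMissing[, "value"] == 1L)
  as.integer(N)
}

#' Classify a genotype matrix as linear or branched evolution
#'
#' End-to-end convenience wrapper: solves the flipping problem (unless an
#' \linkS4class{LppfSolution} is supplied), computes the estimated
#' false-negative fraction betaHat = y/N, and classifies either by Bayes
#' factor or by hard threshold.  A solution that hit the time limit is used
#' as-is (the incumbent objective upper-bounds the optimum) and its status
#' is surfaced in the result and as a warning.
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{LppfSolution}.
#' @param linear,branched \linkS4class{HypothesisParams}; the defaults
#'   (mu 0.05, s 10 linear; mu 0.15, s 10 branched) suit platforms with a
#'   ~5\% false-negative rate.
#' @param method \code{"BAYES"} or \code{"THRESHOLD"}.
#' @param betaStar threshold for \code{method = "THRESHOLD"}.
#' @param includeImputed passed to \code{\link{solutionN}}.
#' @param ... solver arguments (\code{z}, \code{alpha}, \code{timeLimit},
#'   \code{seed}) when \code{x} is a matrix.
#' @return A \linkS4class{ClassificationResult}.
#' @examples
#' B <- GenotypeMatrix(rbind(c(1, 1), c(0, 1)))
#' classifyMatrix(B)
#' @export
classifyMatrix <- function(x,
                           linear = HypothesisParams(0.05, 10),
                           branched = HypothesisParams(0.15, 10),
                           method = c("BAYES", "THRESHOLD"),
                           betaStar = 0.05,
                           includeImputed = FALSE, ...) {
  method <- match.arg(method)
  sol <- if (is(x, "LppfSolution")) x else solveLPPF(x, ...)
  if (solverStatus(sol) == "FEASIBLE_TIMEOUT")
    warning("solver hit the time limit; classifying from the best incumbent")
  y <- objectiveY(sol)
  N <- solutionN(sol, includeImputed = includeImputed)
  bh <- estimatedBeta(y, N)
  if (method == "BAYES") {
    K <- bayesFactor(y, N, linear, branched)
    label <- classifyBayes(K)
  } else {
    K <- NA_real_
    label <- classifyThreshold(bh, betaStar)
  }
  new("ClassificationResult", y = as.integer(y), N = as.integer(N),
      betaHat = bh, K = K, label = label, method = method,
      solverStatus = solverStatus(sol))
}

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult (%s): %s\n", object@method, object@label))
  cat(sprintf("  y = %d flips, N = %d ones, betaHat = %.4g\n",
              object@y, object@N, object@betaHat))
  if (!is.na(object@K))
    cat(sprintf("  Bayes factor K = %.4g\n", object@K))
  cat(sprintf("  solver status: %s\n", object@solverStatus))
})
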