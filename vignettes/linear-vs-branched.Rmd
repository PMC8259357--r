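---
title: "Classifying tumor evolution as linear or branched from single-cell genotypes"
author: "lppf package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor evolution as linear or branched from single-cell genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lppf)
```

## The question and the model

Single-cell DNA sequencing of a tumor yields a binary matrix $B \in
\{0,1\}^{n \times m}$: rows are cells, columns are somatic single-nucleotide
variants, and $b_{ij} = 1$ records that cell $i$ carries mutation $j$.
Under the infinite-sites assumption every mutation is gained once and never
lost, so an error-free matrix is a *perfect phylogeny*.  The tumor's
evolution is **linear** when the clonal tree is a path — equivalently, when
the *one-states* $O_j = \{\,i : b_{ij} = 1\,\}$ can be totally ordered by
set inclusion — and **branched** otherwise.

Real data are noisy.  False negatives (a present mutation read as absent)
occur at rates up to ~40% with common whole-genome amplification; false
positives are far rarer (~$10^{-4}$–$10^{-3}$); and doublets merge two
cells into one barcode.  The package's core question is: *how many false
negatives would have to be corrected for the observed matrix to be a linear
perfect phylogeny?*  Formally, given a budget $z$ of allowed 1→0 flips,
find the minimum number $y$ of 0→1 flips so that the completed matrix $B'$
has nested one-states.  This minimum-flip completion problem is NP-hard (it
embeds chain-graph edge insertion), which is why the solver is a
branch-and-bound search rather than a closed-form algorithm.

Missing entries (zero coverage) take either value at no cost: they count
toward neither flip set, nor the budget $z$, nor the ones-count used to
derive $z$ from a false-positive rate.  Their imputed values are reported
separately by `imputedPositions()`.

## The two hypotheses and the Bayes factor

Let $N$ be the number of ones in $B'$ and $\hat\beta = y/N$ the implied
false-negative fraction.  Under linear evolution $y$ should look like
sequencing noise, so $y \sim \mathrm{BetaBin}(N, \mu_\ell, s_\ell)$ with
$\mu_\ell$ the known platform false-negative rate; under branched evolution
the flips must also erase real branching, giving a much larger mean
$\mu_b$.  With shapes $\theta_1 = \mu s$, $\theta_2 = s(1-\mu)$, the Bayes
factor

$$
K \;=\;
\frac{\mathcal B(\theta_{\ell,1}+y,\ \theta_{\ell,2}+N-y)\ \mathcal B(\theta_{b,1},\ \theta_{b,2})}
     {\mathcal B(\theta_{b,1}+y,\ \theta_{b,2}+N-y)\ \mathcal B(\theta_{\ell,1},\ \theta_{\ell,2})}
$$

supports linear evolution when $K > 1$ and branched when $K < 1$.  All
likelihood arithmetic is done in log-gamma space (`lbeta`, `lchoose`); the
beta-function ratio above is the mathematical contract, not the numerical
recipe, so $N$ in the thousands is unproblematic.  The measure-zero tie
$K = 1$ is resolved to BRANCHED with a warning: support for linearity is
defined only by a strict inequality, and a silent linear call on a tie
would overstate the evidence.  The simpler heuristic
`classifyThreshold(betaHat, betaStar)` rejects linearity when $\hat\beta >
\beta^*$; it can never *support* linearity, so its non-rejection outcome is
reported as `NOT_REJECTED` rather than `LINEAR`.

$N$ excludes ones at imputed missing positions by default
(`solutionN(sol, includeImputed = FALSE)`): an imputed entry carries no
observational evidence, so letting it inflate the denominator would bias
$\hat\beta$ downward.  The alternative is one flag away.

### Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `mu` linear | platform false-negative rate | 0.05 | typical amplification chemistry; override per platform |
| `s` linear | beta-binomial precision | 10 | weakly informative; dispersion of per-run FN rates |
| `mu`, `s` branched | implausible-FN reference | 0.15, 10 | a theoretical "too many flips" distribution; better fitted from branched simulations |
| `z` / `alpha` | 1→0 flip budget | 0 | `computeZ` gives $\lceil \alpha \sum b_{ij} \rceil$; missing excluded |
| `timeLimit` | solver cap (s) | 500 | anytime search; incumbent returned on timeout |
| `betaStar` | hard threshold | 0.05 | conservative: the platform rate |

The branched hypothesis is best estimated by method of moments from solver
output on branched simulations (`fitBranchedPrior`): $\mu$ is the sample
mean and $s = \mu(1-\mu)/\mathrm{var} - 1$, clamped to $[0.5, 1000]$ so a
degenerate or over-dispersed sample still yields a proper beta.

## How the solver works

A completed matrix is a linear perfect phylogeny exactly when, for some
column order, every row is a contiguous block of ones at the rootward end.
The search therefore builds the column order from the root-adjacent end and
branches on the next column.  Per row it tracks the placed ones and zeros
and the cheapest already-closed cut whose 1→0 cost fits the budget; the sum
of per-row optima is an admissible bound.  Three refinements matter in
practice:

* **budget-aware bound** ($z > 0$): each row's potential saving over its
  no-budget cost forfeits at least its unplaced ones from the shared
  budget, so a fractional knapsack over these (saving, weight) items
  bounds what the budget can buy;
* **transposition table** ($z = 0$): both the committed cost and the
  achievable completions depend only on the *set* of placed columns, so an
  order revisiting a set at no smaller committed cost is pruned;
* **dominance** ($z = 0$, complete matrices): an exchange argument shows
  some optimal order places a column before every strict subset of its
  one-state, so dominated candidates are skipped.  Identical columns are
  interchangeable and forced into index order.

Leaves are scored exactly by a small knapsack that allocates the shared
budget across the per-row cut options.  The incumbent is seeded by a
cardinality sort, steepest-descent and randomized greedy passes, and a
relocation local search.  The search is *anytime*: `status` is `OPTIMAL`
when the tree is exhausted and `FEASIBLE_TIMEOUT` otherwise, in which case
the incumbent — an upper bound on the optimum — is still usable for
classification and the status is surfaced through every downstream result.
With a fixed `seed` and a limit long enough to prove optimality, the
objective is deterministic; among co-optimal solutions the particular flip
set may depend on the seed.

Ties between mutations with identical one-states are kept in column order
(the inclusion in the linearity definition is non-strict, so any order of
an equal group is valid); such groups share one pseudo-edge when
ancestor–descendant pairs are derived from a linear solution, and form no
pair among themselves.

`bruteForceLPPF` minimizes the fixed-order cost over all $m!$ orders (guard
at $m \le 8$) and is the independent oracle the test suite compares the
search against; `permutationCost` exposes the fixed-order restriction
directly.

## What the simulator emulates — and what it does not

`generateCloneTree` grows a clonal tree with one mutation per edge: a path
for linear truth, random attachment with rejection until a node has two or
more children for branched truth (`branchFactor` trades path extension
against uniform attachment).  Clonal prevalences default to a symmetric
Dirichlet(1) draw; real cohorts have structured prevalences, so they are
user-suppliable.  `sampleCells` draws each cell's clone by prevalence and
copies its root-path genotype; `injectDoublets` replaces a row, with
probability $\delta$, by the entrywise OR of its true genotype and a
partner clone drawn from the prevalences; `injectErrors` then flips each
true 1 to 0 with probability $\beta$ and each true 0 to 1 with probability
$\alpha$.  Doublets are applied *before* sequencing errors because a
doublet is co-captured material sequenced once; the OR-merge also
reproduces the observation that cross-branch doublets *reduce* apparent
branching.  Injected positions are recorded in the metadata, which gives
the tests their repair bound: with only false negatives injected, flipping
them back restores linearity, so the optimum never exceeds the injected
count.

The generator emulates clone structure, prevalence sampling and the three
error channels.  It does not emulate allelic dropout correlation along the
genome, per-site coverage variation (missingness must be added separately),
copy-number events violating infinite sites, or real cohort prevalences.
Passing tests therefore demonstrate correctness of the method on its own
generative model, not performance on any particular real platform.

`runRobustnessGrid` wires everything together: for each mutation count $m$
it first fits the branched hypothesis from an independent branched-only
sweep of the same error grid, then simulates, solves (with
$z = \lceil\alpha\sum b_{ij}\rceil$) and classifies every instance.  Each
instance's linear hypothesis uses that condition's known simulated $\beta$
as its mean with $s = 10$ — the natural reading of "the platform's expected
false-negative rate" when the platform is the simulator itself.

## Problem sizes and numerical choices

Default grid parameters are the full study conditions (500 cells, $m \in
\{10, 25, 50\}$, 5 replicates, 900 s cap).  The test suite and
`scripts/acceptance.R` run a reduced grid chosen for desk hardware:
150 cells, $m \in \{10, 25\}$, 2 replicates, and a 10 s per-instance cap.
The cap is deliberately short: incumbents for noisy $m = 25$ instances
stabilize within a few seconds (we observed identical objectives at 5 s and
240 s), so a longer cap buys proof, not better classification — and a
shorter cap can only *hurt* the measured accuracy, never inflate it.  At
$m = 10$ the search proves optimality in well under a second.

Other numerical choices: the linearity check sorts by one-state cardinality
with a stable tie-break and verifies adjacent containment only (inclusion
along a sorted chain is transitive); `isLinear` refuses matrices with
missing entries rather than guessing an imputation (imputation is the
solver's job); a degenerate $N = 0$ yields $\hat\beta = 0$ with a warning;
`fitBranchedPrior` refuses zero-variance samples and directs the user to
set the hypothesis manually; read-count discretization uses the one-sided
(greater) binomial exact test, since false positives inflate variant
reads, with zero-coverage sites labeled missing.

## Known limitations

* Proof of optimality is exponential in the worst case; for noisy matrices
  beyond ~20 mutations expect `FEASIBLE_TIMEOUT` with a high-quality
  incumbent rather than a certificate.
* A branched tree whose side branches received no sampled cells is
  indistinguishable from a path; likewise a clone with no sampled cells
  makes its mutation's placement unidentifiable, so exact tree recovery is
  only guaranteed when every clone is represented.
* The classification is binary by design: neutral or punctuated evolution
  are not modeled, and a mostly-linear tree with one small branch will sit
  near $K = 1$.
* The beta-binomial treats flips as exchangeable across the matrix; it does
  not model per-cell or per-site error-rate variation.

## A worked call

```{r example}
sim <- simulateInstance(150, 10, "BRANCHED", beta = 0.15, alpha = 0.001,
                        delta = 0, seed = 7)
sol <- solveLPPF(sim$observed, alpha = 0.001, timeLimit = 30, seed = 7)
sol
classifyMatrix(sol, linear = HypothesisParams(0.15, 10),
               branched = HypothesisParams(0.5, 10))
adDistance(sim$tree, sol)
```
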