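---
title: "Mixed graphical models for multi-layer cohort data: methods and design"
author: "mgmix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed graphical models for multi-layer cohort data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmix)
```

## The model

Cohort studies increasingly combine layers of very different character:
clinical chemistry panels, demographic and lifestyle questionnaires, drug
treatment records, and high-dimensional metabolomics read-outs such as
bucketed 1D NMR spectra. Some of these variables are continuous, many are
categorical, and their dependencies cross layer boundaries. **mgmix**
estimates a pairwise Mixed Graphical Model (MGM) over all of them at once:
an undirected network in which an edge means conditional dependence given
every other variable, so that indirect associations (a metabolite that
tracks a disease only because both track a drug) are absorbed by the
conditioning set rather than reported as discoveries.

For $p$ continuous variables $x$ and $q$ categorical variables $y$ (with
$L_j$ levels for node $j$), the joint density is modeled as

$$
p(x, y; \Theta) \propto \exp\Big(
 \tfrac12 \textstyle\sum_{s,t} \beta_{st} x_s x_t
 + \sum_s \alpha_s x_s
 + \sum_{s,j} \rho_{sj}(y_j)\, x_s
 + \sum_j \theta_j(y_j)
 + \sum_{r<j} \varphi_{rj}(y_r, y_j) \Big),
$$

with $\beta$ symmetric and $-\beta_{ss} > 0$ the conditional precision of
node $s$. The conditionals implied by this density are exactly linear
(Gaussian) regressions for continuous nodes and multinomial logistic
regressions for categorical nodes, which is what makes both
pseudo-likelihood estimation and Gibbs sampling straightforward.

### Identifiability and coding

Categorical potentials are only identified up to additive shifts. We use
reference-level coding: the first declared level of every categorical
variable pins $\rho_{sj}(1) = 0$, $\theta_j(1) = 0$ and the first row and
column of every $\varphi_{rj}$ block to zero. The practical payoff is that
an edge touching a binary variable carries exactly one free parameter, so
the signed scalar edge weights shown in network figures are well defined
without any post-hoc collapsing convention. (The alternative, sum-to-zero
coding, spreads the same information over redundant entries and would make
"the" edge weight a derived quantity.) For blocks with more than two levels
the network layer reports the signed entry of maximum magnitude together
with the block's L2 norm, so no information is lost.

The diagonal $\beta_{ss}$ is estimated, unpenalized, and projected onto
$\beta_{ss} \le -\varepsilon$ (default $\varepsilon = 10^{-4}$) inside every
proximal step, which keeps all conditional variances finite and positive.

## Estimation

The joint likelihood's normalizing constant is intractable (it sums over all
level combinations), so the estimator minimizes the **negative
pseudo-log-likelihood**: the average over samples of the summed per-node
conditional negative log-densities. We average over $n$ rather than sum so
that the penalty weight $\lambda$ has the same meaning at every sample size;
multiply by $n$ to compare with summed conventions.

Sparsity comes from an L1 penalty on all edge parameters (off-diagonal
$\beta$, all free $\rho$ and $\varphi$ entries); node potentials are never
penalized. A group-L2 variant (one group per $\rho_{sj}$ vector and
$\varphi_{rj}$ block) is available via `fitControl(penalty = "group")` but
plain L1 is the default: for predominantly binary categorical layers the two
coincide, and L1 keeps the per-parameter KKT conditions elementary.

### Optimizer

`fitMGM()` is FISTA: proximal gradient steps with Nesterov momentum,
a backtracking line search (step halved until the quadratic upper bound
holds, with mild step growth between iterations), and **adaptive restarts**.
The default restart rule is function-value based: whenever a momentum step
would increase the penalized objective, the momentum sequence is reset and
the step is retaken from the last accepted iterate, which makes the recorded
objective provably non-increasing. A gradient-based restart criterion is
available (`restart = "gradient"`); plain ISTA is `momentum = FALSE`.
Convergence is declared when the relative objective change drops below
`tol` (default $10^{-6}$; `maxIter` 10000). These defaults were chosen so
that the unpenalized fit reproduces classical estimators to $10^{-6}$:
with only continuous variables the minimizer equals the negated inverse of
the ML covariance matrix (node-wise OLS), and for a pair of binary
variables it equals the logistic regression of each node on the other --
both are enforced as tests.

`lambdaMax()` computes the smallest $\lambda$ with an empty edge set in
closed form (the edge-free optimum is moment matching: ML precisions and
log frequency ratios), `regularizationPath()` warm-starts down a decreasing
grid, and `selectLambda()` picks $\lambda$ by EBIC
($n \cdot \text{loss} + k\log n + 2\gamma k \log P$, $\gamma = 0.5$) or by
K-fold cross-validated pseudo-likelihood. EBIC is the default because the
benchmark regime ($n \gg$ true edges, moderate $P$) is exactly where its
sparsity bias helps; CV tends to overselect edges here.

A note on conventions: because the pseudo-likelihood sums both conditionals
touching an edge, the gradient of a tied edge parameter is the sum of both
contributions. A duplicated standardized variable therefore has
$\lambda_{\max} \approx 2$ (twice the ML correlation), not 1; this scale is
internally consistent and only affects how $\lambda$ values compare across
software.

## Preprocessing

`applyTransforms()` implements the standard pipeline for mixed cohort
tables: optional $\log_2$ for right-skewed positive variables, then
standard units (mean 0, sd 1 with the $n-1$ denominator). The training
(center, scale) pair is stored in the variable metadata and reapplied
verbatim to held-out data (`reference =`), so test-set statistics never leak
into the model; mean-value subtraction of spectral buckets is subsumed by
the centering step.

For raw 1D spectra, `referenceSpectra()` aligns each spectrum to an
internal-standard signal (default formic acid at 8.463 ppm) by axis
translation, flagging spectra whose search window has no peak above a
median-plus-5-MAD baseline. `bucketSpectra()` performs equidistant binning:
half-open intervals $[c - w/2, c + w/2)$ of width 0.01 ppm by default,
which places bucket centers at odd multiples of 0.005 ppm (matching
conventional bucket labels such as 3.275 or 8.115 ppm) and sums the grid
intensities in each interval. Both the width and the alignment are
arguments, and exclusion windows (default: the water band, 4.40--5.00 ppm)
are fully configurable, since published binning setups vary. Buckets
overlapping an exclusion are dropped whole rather than truncated, keeping
all kept buckets strictly comparable.

## Validation of neighborhoods

The first-order neighborhood of a node (all nodes one edge away) is itself
a prediction model: the fitted edge weights, used directly without
refitting, give the node's conditional mean (continuous) or conditional
class probability (categorical). `validateAllNeighborhoods()` scores every
node on held-out data -- Pearson correlation for continuous centers, AUC
for binary ones, one-vs-rest AUCs plus macro average for multi-level
centers. The AUC implementation is the normalized Mann-Whitney statistic
with ties counted 1/2 (trapezoidal ROC integration, thresholds swept
downward); whether the probability or the linear predictor is scored is
immaterial for AUC since the two are monotone transforms of each other.
An optional `refit = TRUE` mode re-estimates the linear/logistic model on
the neighborhood variables for comparison.

## Screening comparison

`univariateScreen()` reproduces the conventional alternative: every
variable regressed on every other variable alone (linear or logistic;
two-sided t/Wald tests; Wald rather than likelihood-ratio for speed, the
difference is immaterial at screening sample sizes), ranked per response by
$-\log_{10} p$. p-values are floored at $10^{-300}$ before the logarithm.
Quasi-separated logistic fits fall back to a small-ridge IRLS fit and are
flagged rather than dropped. No multiple-testing correction is applied
inside the screen because the comparison operates on ranks; a
Benjamini-Hochberg column is available as supplementary output
(`screenWithBH()`).

`compareScreens()` then contrasts, per response, the univariate "top
association" with the MGM "top neighbor" before and after post-hoc
adjustment. Scheme `top5` adjusts each method's pick for that method's next
five variables ("next five" excludes the pick itself and the response);
`random5` adjusts both picks for the same five variables drawn uniformly
without replacement from univariate ranks 2--11. Responses with fewer than
11 ranked predictors, or without MGM neighbors, are excluded and listed.

## The synthetic test bed

Real multi-layer cohort data of this kind are access-restricted, so the
package carries its own generator. `makeGroundTruth()` draws a sparse MGM:
edges independently with probability `density` (default 0.1), weights
uniform on $\pm[0.3, 0.6]$, and $\beta_{ss} = -(1 + \sum_t |\beta_{st}|)$,
which is strictly diagonally dominant -- a conservative sufficient condition
that keeps every conditional precision positive along any Gibbs sweep.
`gibbsSample()` runs a systematic-scan Gibbs chain (fixed variable order,
chosen over random scan for exact reproducibility given a seed) with
defaults of 500 burn-in sweeps and thinning 2.

The benchmark regime used throughout the tests is $p = 15$ continuous plus
$q = 5$ binary variables, $n = 2000$ samples, density 0.1 -- small enough to
run in seconds, large enough that EBIC-selected fits recover the true edge
set with F1 above 0.8 in most runs, improving monotonically with $n$
(checked at $n \in \{250, 1000, 4000\}$). The confounding study uses 30
variables at the same $n$, and the mediation motif uses a binary cause
$z$, a continuous mediator $m = 2.5z + 0.5\epsilon$ and a binary response
with logit $-0.8 + 0.8m + 0.6z$ plus nine decoy variables: effect sizes
chosen once so that, as in real screening practice, the distal cause wins
the marginal ranking while the mediator carries the conditional signal.

What the generator does *not* emulate: real NMR noise structure (baseline
drift, peak overlap, heteroscedastic intensities), covariate distributions
of any particular cohort, or missingness (the model requires complete
cases by design). Passing tests therefore demonstrate correctness of the
estimator and the qualitative confounding phenomena, not field performance
on any specific study.

## Numerical choices and degenerate inputs

* Softmax conditionals are computed with row-max subtraction; conditional
  log-probabilities are floored at $10^{-300}$.
* Backtracking halves the step (factor 0.5 from `stepInit = 1`) and fails
  loudly below $10^{-14}$ with advice to reduce `stepInit`.
* Ties in neighbor ordering and edge collapse are broken lexicographically
  by node name, making all outputs deterministic.
* Constant variables, categorical levels absent from the data (or from a CV
  fold), non-positive values under a log2 transform, and incomplete cells
  are all rejected with errors naming the offending variable and sample.
* JSON model serialization writes 17 significant digits, so parameter
  round-trips are bit-exact.

## Known limitations

The model is pairwise: higher-order interactions are not represented.
Edges are linear couplings; smooth nonlinear effects are out of scope.
The estimator requires a complete data matrix -- imputation must happen
upstream. Undirectedness means no causal orientation; the mediation
analysis in the screening module is a ranking comparison, not causal
discovery. Finally, pseudo-likelihood is a consistent but not efficient
surrogate; in tiny samples the joint MLE (where tractable) would differ.
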