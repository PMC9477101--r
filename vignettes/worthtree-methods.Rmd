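---
title: "Worth parameters and partition trees for ranking data: models and methods"
author: "worthtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worth parameters and partition trees for ranking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(worthtree)
```

## The problem

When subjects judge a latent feature of a set of images — how abstract each
one is, say — a complete ranking is often a more reliable instrument than a
numeric rating: it avoids anchor effects and end-aversion, and it forces a
comparison. `worthtree` turns complete rankings of `J` labelled items into a
latent *worth* scale, and asks whether different kinds of subjects place the
items differently on that scale.

The pipeline has four stages, each usable on its own:

1. **Pattern algebra** — a ranking of `J` items induces `J(J-1)/2` signed
   pairwise decisions; exactly `J!` of the conceivable decision patterns are
   transitive, and those are exactly the patterns rankings can produce.
2. **The loglinear Bradley–Terry (LLBT) pattern model** — a probability model
   on those `J!` patterns whose item parameters transform to worths on a
   standardized 0–1 scale.
3. **Model-based recursive partitioning** — split subjects on covariates
   wherever the fitted item parameters are unstable, yielding a tree whose
   terminal nodes each carry their own worth vector.
4. **Bootstrap stability** — how often does each covariate actually drive a
   split when the whole pipeline is re-run on resampled subjects?

## The model

The Bradley–Terry model gives the probability of preferring item $j$ to item
$k$ as

$$p(j \succ k) \;=\; \frac{\pi_j}{\pi_j + \pi_k},$$

with worths $\pi_j > 0$, $\sum_j \pi_j = 1$. Written as a loglinear model
with item parameters $\lambda_j$, the two are linked by

$$\pi_j = \frac{\exp(2\lambda_j)}{\sum_k \exp(2\lambda_k)}.$$

Because each subject returns one complete ranking, the decisions of a subject
are not independent: the unit of observation is the whole response pattern
$y = (y_{12}, y_{13}, \dots, y_{J-1,J})$, $y_{jk} = +1$ if $j$ precedes $k$.
The pattern probability is an exponential family over the $J!$ transitive
patterns,

$$p(y) \;=\; \frac{\exp\!\big(\sum_j \lambda_j x_j(y)\big)}{Z(\lambda)},
\qquad x_j(y) = \sum_{k \ne j} \pm 1,$$

where $x_j(y)$ is item $j$'s aggregated design score — the signed sum of its
pairwise wins and losses. For a complete ranking the scores are always the
arithmetic sequence $J-1, J-3, \dots, -(J-1)$ in ranking order; `pattern_design()`
prints the full design. The expected frequency of pattern $y$ among $n$
subjects is $n\,p(y)$, which is the Poisson/loglinear formulation with a log
link; both routes have the same maximum-likelihood solution, and the test
suite asserts the equivalence against `glm(family = poisson)` rather than
maintaining two production code paths.

### Fitting

`fit_llbt()` maximizes the `J!`-cell multinomial loglikelihood by damped
Newton iteration on the `J - 1` free coordinates (sum-to-zero constraint on
$\lambda$). The loglikelihood is concave, so convergence is declared when the
per-subject gradient max-norm falls below `1e-10` (at most 200 iterations).
Enumeration is exact and capped at `J <= 7` (5040 patterns): the design grows
factorially and larger item sets should be analyzed differently.

**Separation.** If some item is always ranked first (or last), the MLE runs
to infinity. The fit detects this when any $|\lambda_j|$ exceeds 15 during
iteration, warns, and returns a ridge-penalized fit (penalty
$10^{-4}\lVert\lambda\rVert^2$, recorded in the fit object). Worth vectors
then contain near-degenerate entries (e.g. $10^{-5}$), which is how strongly
consensual rankings legitimately look on the worth scale.

**Confidence intervals.** `worth_ci()` uses the delta method on
$\operatorname{logit}(\pi_j)$ and maps back, so bounds always lie in (0, 1),
always contain the point estimate, and shrink like $n^{-1/2}$. (The scale of
the interval is a genuine design choice: intervals on $\pi$ directly can
escape the unit interval for near-degenerate worths.)

**Focal groups.** `fit_llbt_grouped()` keeps a grouping variable (e.g. expert
vs. novice) inside the model: the reference group carries $\lambda_j$, every
other group adds interaction offsets $\lambda_{js}$. Since that interaction
is saturated, the joint MLE factorizes into per-group fits — the
implementation exploits this and the tests assert the loglik additivity.
In a partition tree the focal group is modeled in every node and never used
for splitting.

## Partitioning

`grow_tree()` follows the model-based recursive partitioning recipe:

1. Fit the node model; compute each subject's score contribution
   $s_i = x(y_i) - E_{\hat\lambda}[x]$ (column sums vanish at the MLE).
2. For every candidate covariate, test whether the scores fluctuate
   systematically along it.
   *Numeric and ordinal covariates* use the supLM statistic: order subjects
   by the covariate (ties broken by subject id for determinism), decorrelate
   the scores by the outer-product-of-gradients information estimate, and
   take the supremum of $\lVert W(t)\rVert^2 / (t(1-t))$ over admissible
   split fractions $t \in [\mathrm{trim}, 1-\mathrm{trim}]$ with
   $\mathrm{trim} = \max(0.1, \mathrm{minsize}/n)$, evaluated only at
   boundaries between distinct covariate values.
   *Nominal covariates* aggregate scores within categories; the statistic is
   chi-square with $(C-1)k$ degrees of freedom ($k$ = free parameters).
3. Bonferroni-adjust across the candidates; split on the covariate with the
   smallest adjusted p-value if it is below `alpha` (default 0.05).
4. Choose the cutpoint maximizing the two children's combined loglikelihood,
   among cuts leaving at least `minsize` subjects per child. The rule is
   reported as the left child's largest observed value, so rules read
   "age <= 15". Values equal to the cutpoint route left. Nominal covariates
   search all binary partitions of at most 10 observed levels.
5. Recurse until no covariate is significant, a node is smaller than
   `2 * minsize`, or `max_depth` is reached; then post-prune bottom-up,
   collapsing any split whose descendant terminals' combined AIC is not lower
   than the node's own AIC. Pruning is idempotent and never increases the
   total AIC.

The default `minsize = 40` suits classroom-scale samples (around a thousand
subjects); small expert panels would use a much smaller value such as 4, at
the price of less stable node fits.

### supLM p-values

The limiting null distribution of the supLM functional (the supremum of a
squared normalized $k$-dimensional Brownian bridge over a trimmed interval)
has no convenient closed form. The package evaluates it by Monte Carlo once
per (degrees of freedom, trimming) pair — 10,000 simulated paths on a grid of
200 steps, under a fixed internal seed that does not disturb the user's RNG
stream — and caches the sample. Trimming fractions are binned to a 0.05 grid
for the reference distribution only; the statistic always uses the exact
trim. Above the empirical 98th percentile, p-values come from an exponential
tail fitted to the top 2% of the sample, so very small p-values remain smooth
and strictly positive. The test suite verifies the size at $\alpha = 0.05$ on
independent covariates stays within [0.02, 0.09] for both the supLM and the
categorical test.

### Weighted data and the bootstrap

`bootstrap_trees()` regrows and re-prunes a tree on `B` subject-level
resamples (rankings and covariates move together) and reports, per covariate,
the fraction of resamples with at least one split on it, plus all observed
cutpoints. Per-resample seeds are spawned from the master seed one at a time,
so enlarging `B` never changes earlier resamples, and any execution order
gives identical summaries.

A resample is handled as a *weighted* dataset (multiplicity = case weight)
rather than as duplicated rows. This matters: with duplicated rows the
covariate-ordered partial sums of scores are over-dispersed relative to the
information estimate and the supLM test rejects far too often — the test
suite demonstrates a false-rejection rate above 0.3 at nominal 0.05 for the
duplicated-rows treatment of the same resamples, against at most 0.12 for the
weighted treatment. With weights, partial sums use $w_i s_i$, the information
uses $w_i^2 s_i s_i^{\top}$, and the Brownian time is the cumulative share of
squared weights. Selection probabilities from this package are therefore
calibrated: a covariate with no effect has selection probability near the
per-tree false-split rate (a few percent), not the 0.3–0.7 a naive
duplicated-rows scheme produces.

## The synthetic-data generator

`sim_design()` pairs covariate sampling specs with *leaf rules*: mutually
exclusive, exhaustive covariate conditions, each owning a worth vector (and
optionally per-focal-group worth vectors). `simulate_study()` samples
covariates, routes every subject to exactly one leaf (validated before any
ranking is drawn), and draws the subject's ranking from the leaf's worth.

Rankings are sampled from the **exact pattern distribution** — enumerate the
`J!` patterns, compute their probabilities under the leaf's $\lambda$, draw
one — *not* from a sequential Plackett–Luce scheme. The two ranking laws
differ for $J \ge 3$, and recovery tests are only meaningful when generator
and estimator share one law. A goodness-of-fit test at $n = 50{,}000$
(J = 3, exhaustive cells) is part of the test suite.

`study_design()` bundles a ready-made emulation of a large classroom ranking
study: five items judged on abstraction; age as a rounded normal
(mean 15.35, sd 2.96, truncated at 13 — note the truncation lifts the
realized mean to about 16.2); task time as a lognormal matched to a 23 s
mean and 10.3 s sd; gender 52% female; an art grade on a 1–6 scale and ten
Likert-type self-ratings whose 1–K marginals are shifted-binomial
distributions matched to realistic means (`likert_probs()`); and four leaves
defined by task time and interest in visual puzzles, with worth profiles
spanning the steep-to-flat range such studies report. Numeric covariates are
sampled independently — the partitioning analysis conditions on covariates,
so a copula would add nothing the tests could detect.

**What the generator does not emulate:** correlated covariates, classroom
clustering (intraclass correlation), response styles that violate the pattern
model (e.g. attention lapses producing near-random rankings), and item-side
structure. Passing recovery tests on this generator therefore demonstrates
the estimator and the tree machinery are correct *under the model*, not that
the model is adequate for any particular real dataset.

## Numerical and design choices

* Canonical pair order is (1,2), (1,3), ..., (J−1,J) in item-label order;
  pattern enumeration is lexicographic in the generating ranking. Both are
  stable so count vectors are citable fixtures.
* Rankings are stored as orderings (label sequences), position 1 = most of
  the attribute; ties and incomplete rankings are rejected — the target task
  is forced complete rankings.
* Identifiability by sum-to-zero on $\lambda$ (symmetric; matches the worth
  normalization).
* Subjects with a missing value in any candidate covariate are dropped at
  tree entry, with the count recorded on the tree object.
* Tie-breaks: covariate ordering ties are resolved by subject id; equal
  adjusted p-values select the earlier-declared covariate; equal cutpoint
  logliks keep the first (smallest) cutpoint.
* Problem sizes in the test suite (e.g. 50 tree replicates at n = 1000,
  bootstrap B = 50, GOF at n = 50,000) were chosen as the smallest sizes at
  which the binomial noise of a pass/fail proportion is clearly separated
  from its threshold.

## Known limitations

* Exact enumeration caps the item count at 7; no approximation for larger J.
* No surrogate splits: missing covariate values drop a subject entirely.
* Bonferroni across candidates is the only multiplicity control; no
  post-selection inference for the node worths.
* The bootstrap quantifies *stability of selection*, not uncertainty of the
  worth estimates; no bias-corrected bootstrap CIs.
* Only ranking-derived paired comparisons are supported — no direct
  paired-comparison data, no ties/mid-ranks, no top-k rankings.
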