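---
title: "Quasi-linear scores: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-linear scores: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlscore)
```

## The model and its assumptions

`qlscore` predicts a dichotomous outcome $Y \in \{0,1\}$ from $p$ numeric
markers whose population is suspected to be *heterogeneous*: the case group
is a mixture of subgroups in which different marker sets, possibly with
different directions of effect, carry the signal. Given a disjoint,
exhaustive partition of the markers into $K$ clusters, each cluster
contributes a linear score

$$L_k = \alpha_k + \beta_k^\top x_{(k)},$$

and the model links the outcome to their **quasi-linear score**, the
Kolmogorov–Nagumo average with $\phi = \exp$:

$$\mathrm{logit}\, \pi = Q = \log \sum_{k=1}^K \exp(L_k).$$

$Q$ is a soft maximum: $M \le Q \le M + \log K$ with $M = \max_k L_k$, so in
the region where one cluster's score dominates the others, $Q$ is locally
that cluster's linear score — the model behaves like a panel of $K$ local
linear classifiers glued together smoothly, and the softmax weights
$S_k = \exp(L_k)/\sum_j \exp(L_j)$ say which cluster is deciding for a given
sample. With $K = 1$ everything reduces exactly to logistic regression.

The form is not merely a heuristic: when controls are $N(0, I)$ and cases
are a $K$-component normal mixture with identity covariance whose component
means load on disjoint clusters, the log posterior odds *is* a quasi-linear
score with $\alpha_k = \log \tau_k - \lVert \mu_{k} \rVert^2/2 +
\mathrm{logit}\, P(Y=1)$ and $\beta_k = \mu_k$ restricted to cluster $k$
(`bayes_optimal_params()`). The partition itself is assumed given — in
practice from Ward clustering of the training markers
(`ward_cluster_markers()`); choosing $K$ is left to the analyst.

A tempered generalization $Q_\tau = \tau^{-1}\log\sum_k \exp(\tau L_k)$
connects the family: $\tau = 1$ is $Q$ and $\tau \to \infty$ is the hard
maximum $M$. For the small-$\tau$ end the package exposes a *normalized*
variant, $\tau^{-1}\log(K^{-1}\sum_k e^{\tau L_k})$, which converges to the
arithmetic mean of the $L_k$ as $\tau \to 0^+$; the unnormalized form
diverges like $\log(K)/\tau$ for $K > 1$, so the often-quoted "$\tau \to 0$
gives the linear score" holds only up to this normalization (the mean of
the cluster scores is a rescaled linear score with tied coefficients, not
the freely-parameterized linear score itself). Both variants are
implemented (`tempered_score(..., normalized =)`), and the limit tests use
the normalized one.

## Estimation

**Likelihood.** $\ell(\theta) = \sum_i y_i Q_i - \log(1 + e^{Q_i})$ with
$\theta = (\alpha_1..\alpha_K, \beta^\top)^\top$. The per-sample gradient is
the softmax-gated design row $(S_1,\dots,S_K, S_{k(1)}x_1,\dots,S_{k(p)}x_p)$,
so $\nabla \ell = W^\top(y - \pi)$; `ql_score_gradient()` is the exact
analytic form and is property-tested against central finite differences.

**Fisher scoring (none / ridge).** The ridge objective subtracts
$\tfrac12\lambda_0\sum_k \alpha_k^2 + \tfrac12\sum_k \lambda_k
\beta_k^\top\beta_k$ and the update solves
$(W^\top V W + R)\,\delta = \nabla$ with
$R = \mathrm{diag}(\lambda_0 I_K, \lambda_{k(1)},\dots)$. Numerical choices:

* *Initialization*: $\alpha_k^{(0)} = \mathrm{logit}(\bar y) - \log K$,
  $\beta^{(0)} = 0$, so the initial score equals the empirical log-odds for
  every sample. At this symmetric start the $K$ intercept columns of $W$
  are identical and the expected information is exactly rank-deficient; the
  first step is therefore taken with the pseudoinverse (the minimum-norm
  Fisher step), after which the data break the symmetry. Rank deficiency at
  any *later* iterate aborts with advice to use ridge — with
  $p + K > n$ and no penalty that is the expected outcome, and the
  simulation harness records such replicates as failures rather than
  keeping them.
* *Safeguard*: a step that would decrease the penalized log-likelihood is
  halved, up to 20 times; the iterate trace is therefore nondecreasing (the
  raw update is not globally ascent-safe because $Q$ is nonlinear in
  $\theta$).
* *Convergence*: relative objective change below $10^{-8}$, at most 100
  iterations.
* $\lambda_0$ defaults to $10^{-4}$: the intercept penalty exists only to
  keep the information matrix invertible, not to shrink intercepts
  materially; it is user-overridable.

**Lasso (directional-derivative gradient ascent).** The objective is
$\ell(\theta) - \sum_k \lambda_k |\beta_k|_1$; intercepts are never
L1-penalized. Each iteration moves along the soft-thresholded gradient
$g(\theta)$ — a zero coordinate moves only if its raw gradient exceeds its
penalty — with step length $\min(t_{\mathrm{opt}}, t_{\mathrm{edge}})$:

* $t_{\mathrm{edge}}$ is the largest step before any coefficient would
  cross zero (a coordinate landing on the boundary is set exactly to zero);
  over an empty candidate set it is $+\infty$.
* $t_{\mathrm{opt}} = \lVert g\rVert^2 / \lvert g^\top W^\top V W\, g\rvert$
  — the exact one-dimensional Newton maximizer along $g$ under the expected
  information. The curvature form of the log-likelihood is negative
  definite, so its absolute value is taken; reading the numerator as the
  squared norm makes the step the exact 1-D Newton length, since the
  directional derivative of the penalized objective along $g$ is
  $\lVert g\rVert^2$.
* The same halving safeguard applies. Once the objective flattens (relative
  change below tolerance) the iterate is *polished* by Newton steps
  restricted to the active set (all intercepts plus nonzero coefficients),
  clamped so no coefficient flips sign; polishing stops when either the
  full KKT conditions hold to $10^{-5}$ — $|\ell_j| \le \lambda_k$ at zero
  coordinates, $\ell_j = \lambda_k \,\mathrm{sign}(\beta_j)$ at active
  ones — or a zero coordinate needs to re-enter, which returns control to
  the gradient phase. The iteration cap is 5000.

Small-instance fits are tested against independent optimizers (BFGS with
analytic gradients for ridge; a proximal-gradient solver for lasso) and the
KKT residuals are asserted below $10^{-4}$.

**Standardization.** Markers are centered and scaled to unit variance
before fitting (penalties then act on comparable scales — the same
convention as mainstream penalized-regression software); estimates are
back-transformed and always reported on the original marker scale. The
transformation is exact, so unpenalized MLEs are unaffected by the choice.

**Cross-validation.** `ql_cv()` tunes a shared $\lambda$ (per-cluster grids
are possible but the default is shared: a full per-cluster grid grows
exponentially in $K$) over 10 log-spaced points in $[10^{-3}, 10^2]$, using
stratified 5-fold splits and mean held-out log-likelihood as the criterion,
with warm starts along the descending grid. Folds derive from an explicit
seed, so tuning is reproducible.

## Clustering and diagnostics

`ward_cluster_markers()` uses `ward.D2` agglomeration on either Euclidean
distance between standardized marker profiles (default — classical Ward) or
$1 - r$ correlation distance; the cut into $K$ clusters is relabeled by
smallest member index so runs are deterministic. The API takes training
data only — the partition must never see evaluation samples.
`split_t_diagnostic()` computes per-marker two-sample t-statistics on two
stratified halves and flags sign mismatches (pure-noise markers mismatch
about half the time; consistently informative ones almost never).
`select_top_t()` implements top-$|t|$ marker preselection. The t-statistic
is the unequal-variance (Welch) form by default, switchable to pooled — the
diagnostic's purpose is robust sign comparison, for which Welch is the
safer default.

## Evaluation

`auc()` is the Mann–Whitney statistic (ties counted half).
`bootstrap_auc_ci()` uses class-stratified resampling and the percentile
interval — the simplest variant consistent with stratified resampling; more
refined intervals (BCa, DeLong) are deliberately out of scope.
`youden_cutoff()` maximizes sensitivity + specificity − 1 over score
midpoints with ties resolved to the lowest threshold.
`stability_index()` is the mean pairwise Jaccard similarity with the
conventions $S(\emptyset,\emptyset) = 1$ and $S(\emptyset, B) = 0$;
`bootstrap_selection_stability()` applies it to lasso selections
($|\hat\beta_j| > 10^{-8}$) over stratified bootstrap refits.

## Simulation designs and study sizes

`sim_design()` ships the generative settings used by the package's studies:
a two-marker consistency design (standard-normal controls, two-component
case mixture at means $(-1,0)$ and $(0,1.5)$, equal weights) and
high-dimensional homo/hetero/correlated settings at $p = 100$ or $p = 70$.
Design conventions the generator fixes once:

* Classes are split exactly 50/50 (`balanced = TRUE`); the consistency
  design's analytic intercepts back out equal class priors, which this
  matches. Mixture weights are equal across components.
* The correlated design `d1` pairs its two 35-marker covariance blocks
  ($\Sigma_1 = 0.7I + 0.3J$ within, $\Sigma_2 = -0.15J$ across) with a
  35/35 cluster partition, so the quasi-linear clusters align with the
  dependence structure.
* `b3` specifies only one informative component; the remaining two
  components sit at the origin. It is retained for completeness but not
  used in headline comparisons.
* In `c1` every informative block spans 10 coordinates
  (cases at $0.5$ in markers 1–10 and $0.8$ in markers 51–60; the second
  control component at $0.3$ in markers 51–60). This width is the only
  choice under which the design's ideal (Bayes) AUC — about 0.84 — is
  compatible with the discrimination reported for fits on it; wider
  informative blocks would make the classes nearly separable and the
  setting uninformative about penalization.

The harnesses run at desk scale: `run_consistency_study()` uses 1000
replicates (a few seconds — the fits are two-dimensional), and
`run_auc_study()` defaults to 100 replicates of 400 training / 200 test
samples per setting, all methods of a replicate sharing the same data so
method contrasts are paired. Per-replicate seeds derive deterministically
from one master seed, making results independent of execution order.
Replicate-level Monte-Carlo spread of mean AUCs at 100 replicates is about
$\mathrm{SD}/10 \approx 0.004$, small against the method differences of
interest (0.03–0.08 on the heterogeneous settings).

**What the generator does and does not emulate.** It produces Gaussian
mixtures with known cluster structure, identity or block-constant
covariance, balanced classes and no missingness. Real expression panels
have heavier tails, marker-specific scales, unbalanced classes and
partitions that must themselves be estimated — so passing tests here
demonstrate correctness of the algorithms and the qualitative advantage of
the quasi-linear form under heterogeneity, not performance guarantees on
any particular real dataset.

## Known limitations

* The penalized likelihood is non-concave in $\theta$; fits find a
  stationary point, and the symmetric initialization makes results
  deterministic but not certified-global. In the supported Bayes-optimal
  family the studies show estimates concentrate on the analytic optimum.
* $K$ is an input, not estimated; automatic cluster-count selection is an
  open problem.
* The lasso path is computed per $\lambda$, not as a full coordinate-wise
  path; for very large $p$ a dedicated path algorithm would be faster.
* Elastic-net and group-lasso penalties are out of scope, as are comparator
  learners (random forests, SVMs) — the package implements the quasi-linear
  family and its direct linear baseline.
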