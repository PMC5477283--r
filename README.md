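# qlscore

Penalized logistic classification with the **quasi-linear score** — a
log-sum-exp (Kolmogorov–Nagumo) average of cluster-wise linear scores — for
dichotomous outcomes predicted from heterogeneous biomarker panels.

## The problem and the model

Linear risk scores assume one direction of effect per marker across the whole
population. When the case group is a mixture of subgroups (different tumour
subtypes, different etiologies), a marker can be elevated in one subgroup and
depressed in another; a single linear score averages these effects away. A
symptom visible in real panels is *sign-mismatched t-statistics*: split the
samples in half and the two halves disagree about a marker's direction.

`qlscore` captures such heterogeneity through the score form itself. Given a
partition of the *p* markers into *K* clusters (typically from Ward
clustering of the markers), each cluster gets its own linear score

    L_k = α_k + β_kᵀ x_(k),     k = 1, …, K

and the quasi-linear score combines them as a *soft maximum*:

    Q = log( Σ_k exp(L_k) ),    with  max_k L_k ≤ Q ≤ max_k L_k + log K.

`Q` is the Kolmogorov–Nagumo average of the `L_k` with φ = exp: smooth enough
to fit by likelihood methods, yet close enough to the hard maximum that the
dominant cluster effectively decides the prediction ("cluster selection";
e.g. `log(e⁵ + e² + e⁻¹ + e⁻⁴) = 5.051`). The outcome follows a logistic
model on `Q`:

    logit P(Y = 1 | x) = Q(x).

Estimation is by Fisher scoring (unpenalized or ridge, per-cluster weights
λ_k) or by a directional-derivative gradient ascent for the lasso whose step
length `min(t_opt, t_edge)` never flips a coefficient's sign within one step.
With `K = 1` everything reduces to ordinary penalized logistic regression.
For case groups that are normal mixtures against standard-normal controls,
the quasi-linear form is exactly the Bayes log-posterior-odds, and
`bayes_optimal_params()` returns the analytic parameters.

## Worked example

Simulate the heterogeneous benchmark design `b1` (controls `N(0, I₁₀₀)`;
cases an equal mixture with mean −1 in marker 1 and mean 1.5 in marker 51),
tune and fit a lasso quasi-linear model with two 50-marker clusters, and
evaluate on an independent test set:

```r
library(qlscore)

design <- sim_design("b1")
train  <- sim_generate(design, n = 400, seed = 1)
test   <- sim_generate(design, n = 200, seed = 2)

cv  <- ql_cv(train, "y", design$partition, penalty = "lasso", seed = 1)
fit <- ql_fit(train, "y", design$partition, penalty = "lasso", lambda = cv$lambda)
fit
#> <ql_fit> quasi-linear logistic model
#>   K = 2  p = 100  n = 400
#>   penalty: lasso (lambda = 7.74/7.74)
#>   logLik: -226.5633  iterations: 135

dplyr::filter(tidy(fit), selected)   # 12 of 100 markers survive shrinkage;
#> x1  (cluster 1)  -0.840              the two truly informative markers
#> x51 (cluster 2)   1.120              carry the largest coefficients
#> ... 10 small noise coefficients ...

scores <- predict(fit, test, type = "link")
auc(scores, test$y)
#> [1] 0.731
bootstrap_auc_ci(scores, test$y, B = 2000, seed = 1)
#> lower upper
#> 0.660 0.797
youden_cutoff(scores, test$y)$error_rate
#> [1] 0.315
```

The fitted model recovers the heterogeneous structure: cluster 1's score is
driven by marker `x1` (negative shift), cluster 2's by `x51` (positive
shift), and for each test sample the larger cluster score dominates `Q`.
A linear score fitted to the same data averages the two opposing subgroups
and reaches a noticeably lower AUC (about 0.64 with ridge tuning — compare
`run_auc_study("b1", c("LL-ridge", "QL-lasso"), ...)`).

Other entry points: `ward_cluster_markers()` (marker partition from training
data), `split_t_diagnostic()` (sign-mismatch heterogeneity plot),
`select_top_t()` (top-|t| preselection), `bootstrap_selection_stability()`
(Jaccard stability of lasso selections), `run_consistency_study()` and
`run_auc_study()` (simulation harnesses), and a command-line interface
(`ql_cli()`, script in `inst/cli/ql.R`) with subcommands
`cluster | fit | predict | evaluate | simulate | diagnose`.

See `vignettes/quasi-linear-scores.Rmd` for the methods account: model
assumptions, estimation algorithms and safeguards, tuning defaults, the
simulation designs, and known limitations.

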