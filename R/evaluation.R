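#' Area under the ROC curve
#'
#' Mann–Whitney AUC: the probability that a random case outscores a random
#' control, counting ties one half — identical to the trapezoidal area under
#' the empirical ROC curve. Invariant under strictly increasing transforms of
#' the scores.
#'
#' @param scores Numeric score vector.
#' @param y 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 1, 0, 1)) # 0.75
#' @export
auc <- function(scores, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Percentile interval of the AUC over `B` stratified bootstrap resamples
#' (cases and controls resampled within class, preserving the class ratio, so
#' no resample is degenerate).
#'
#' @inheritParams auc
#' @param B Number of bootstrap resamples (the reference analysis uses 2000).
#' @param level Confidence level.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_auc_ci <- function(scores, y, B = 2000, level = 0.95, seed = 1) {
  y <- as.numeric(y)
  if (B < 1L) stop("B must be >= 1")
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) stop("both classes must be present")
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ix <- c(sample(i1, length(i1), replace = TRUE),
              sample(i0, length(i0), replace = TRUE))
      auc(scores[ix], y[ix])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  stats::setNames(stats::quantile(aucs, c(a, 1 - a), names = FALSE),
                  c("lower", "upper"))
}

#' Youden-index cutoff and error rate
#'
#' Chooses the score threshold maximizing Youden's J = sensitivity +
#' specificity − 1 over midpoints of adjacent observed scores (plus open
#' thresholds below and above all scores); ties go to the lowest threshold.
#' A sample is called positive when its score exceeds the cutoff.
#'
#' @inheritParams auc
#' @return A list with `cutoff`, `error_rate` (misclassification fraction at
#'   the cutoff), `sensitivity` and `specificity`.
#' @export
youden_cutoff <- function(scores, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- c(s[1L] - 1, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- NULL
  for (ct in cand) {
    pred <- as.numeric(scores > ct)
    sens <- sum(pred == 1 & y == 1) / n1
    spec <- sum(pred == 0 & y == 0) / n0
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12) {
      best <- list(J = J, cutoff = ct, sensitivity = sens, specificity = spec,
                   error_rate = mean(pred != y))
    }
  }
  best[c("cutoff", "error_rate", "sensitivity", "specificity")]
}

#' Stability index of selected marker sets
#'
#' Mean pairwise Jaccard similarity \eqn{S(A,B) = |A \cap B| / |A \cup B|}
#' over all unordered pairs of the `R` sets. Conventions for empty sets:
#' \eqn{S(\emptyset,\emptyset) = 1}, \eqn{S(\emptyset, B \ne \emptyset) = 0}.
#'
#' @param sets List of at least two marker-index (or name) vectors.
#' @return Scalar in `[0, 1]`.
#' @examples
#' stability_index(list(c(1, 2, 3), c(2, 3, 4))) # 0.5
#' @export
stability_index <- function(sets) {
  R <- length(sets)
  if (R < 2L) stop("need at least two sets")
  sets <- lapply(sets, unique)
  tot <- 0
  for (i in seq_len(R - 1L)) {
    for (j in seq.int(i + 1L, R)) {
      a <- sets[[i]]; b <- sets[[j]]
      u <- length(union(a, b))
      tot <- tot + if (u == 0L) 1 else length(intersect(a, b)) / u
    }
  }
  tot * 2 / (R * (R - 1))
}

#' Bootstrap stability of lasso marker selection
#'
#' Refits the lasso quasi-linear model on `R` stratified bootstrap resamples
#' of the training data, records which markers survive shrinkage
#' (\eqn{|\hat\beta_j| > 10^{-8}}) in each refit, and summarizes agreement by
#' the mean pairwise Jaccard [stability_index()].
#'
#' @inheritParams ql_fit
#' @param lambda Lasso penalty weight(s) used for every refit (tune once
#'   beforehand, e.g. with [ql_cv()]).
#' @param R Number of bootstrap refits (the reference analysis uses 100).
#' @param seed Integer master seed; per-resample seeds are derived from it.
#' @param ... Passed to [ql_fit()].
#' @return A list with `stability` (the scalar index), `sets` (list of
#'   selected marker-name vectors) and `failed` (count of refits that raised
#'   an error, reported with their seeds as names of `failures`).
#' @export
bootstrap_selection_stability <- function(data, outcome, partition, lambda,
                                          R = 100, seed = 1, ...) {
  if (R < 2L) stop("R must be >= 2")
  dd <- ql_data(data, outcome)
  i1 <- which(dd$y == 1); i0 <- which(dd$y == 0)
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, R))
  sets <- vector("list", R)
  failures <- integer(0)
  for (r in seq_len(R)) {
    ix <- withr::with_seed(seeds[r], {
      c(sample(i1, length(i1), replace = TRUE),
        sample(i0, length(i0), replace = TRUE))
    })
    fit <- tryCatch(
      ql_fit(dd$X[ix, , drop = FALSE], dd$y[ix], partition,
             penalty = "lasso", lambda = lambda, ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- c(failures, stats::setNames(seeds[r], conditionMessage(fit)))
      sets[[r]] <- NULL
    } else {
      sets[[r]] <- names(fit$beta)[abs(fit$beta) > 1e-8]
    }
  }
  keep <- !vapply(sets, is.null, logical(1))
  list(stability = stability_index(sets[keep]), sets = sets[keep],
       failed = sum(!keep), failures = failures)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs of the empirical ROC curve, suitable for export or
#' plotting.
#'
#' @inheritParams auc
#' @return Tibble with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  ord <- order(-scores)
  tp <- cumsum(y[ord] == 1); fp <- cumsum(y[ord] == 0)
  tibble::tibble(
    threshold = c(Inf, scores[ord]),
    tpr = c(0, tp / sum(y == 1)),
    fpr = c(0, fp / sum(y == 0))
  )
}

#' Evaluate a fitted model on a dataset
#'
#' One-stop evaluation: AUC with bootstrap CI, Youden cutoff and error rate,
#' and the selected-marker set.
#'
#' @param fit A `ql_fit`.
#' @param data,outcome Evaluation data as in [ql_fit()].
#' @param B,level,seed Bootstrap CI settings (see [bootstrap_auc_ci()]).
#' @return One-row tibble: `auc`, `ci_lower`, `ci_upper`, `cutoff`,
#'   `error_rate`, `n_selected`, plus a `selected` list-column of marker
#'   names.
#' @export
evaluate_model <- function(fit, data, outcome, B = 2000, level = 0.95,
                           seed = 1) {
  dd <- ql_data(data, outcome)
  sc <- predict(fit, dd$X, type = "link")
  ci <- bootstrap_auc_ci(sc, dd$y, B = B, level = level, seed = seed)
  yc <- youden_cutoff(sc, dd$y)
  sel <- names(fit$beta)[abs(fit$beta) > 1e-8]
  tibble::tibble(
    auc = auc(sc, dd$y), ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
    cutoff = yc$cutoff, error_rate = yc$error_rate,
    n_selected = length(sel), selected = list(sel)
  )
}
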