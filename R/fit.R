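#' Fit the quasi-linear logistic model
#'
#' Estimates the cluster intercepts \eqn{\alpha_k} and marker coefficients
#' \eqn{\beta} of the quasi-linear logistic model
#' \eqn{\mathrm{logit}\, \pi_i = \log \sum_k \exp(\alpha_k + \beta_k^\top
#' x_{i(k)})} by maximum likelihood (Fisher scoring), ridge-penalized
#' likelihood (regularized Fisher scoring), or lasso-penalized likelihood
#' (directional-derivative gradient ascent whose step length
#' \eqn{\min(t_{opt}, t_{edge})} never flips a coefficient's sign within a
#' step). With a single cluster (`K = 1`) the model is ordinary (penalized)
#' logistic regression.
#'
#' @param data Data frame with the outcome column and numeric marker columns,
#'   or a numeric matrix of markers (then `outcome` must be a vector).
#' @param outcome Name of the 0/1 outcome column (string), or the outcome
#'   vector itself when `data` is a matrix.
#' @param partition A [marker_partition()] over the marker columns. Defaults
#'   to a single cluster (ordinary logistic regression).
#' @param penalty One of `"none"`, `"ridge"`, `"lasso"`.
#' @param lambda Penalty weight: a scalar shared by all clusters or a
#'   length-`K` vector \eqn{\lambda_k}. Ignored for `penalty = "none"`.
#' @param lambda0 Ridge weight on the intercepts (ridge only). The intercepts
#'   are regularized only lightly, to keep the information matrix invertible;
#'   the lasso never penalizes them.
#' @param standardize Center and scale markers to unit variance before
#'   fitting (penalties then act on comparable scales). Estimates are
#'   reported on the original marker scale regardless.
#' @param init Optional list with `alpha`, `beta` start values (original
#'   scale). Default: \eqn{\alpha_k = \mathrm{logit}(\bar y) - \log K},
#'   \eqn{\beta = 0}, so the initial score equals the empirical log-odds.
#' @param tol Relative penalized log-likelihood change declaring convergence.
#' @param max_iter Iteration cap; defaults to 100 for Fisher scoring and
#'   5000 for lasso gradient ascent.
#'
#' @return An object of class `ql_fit` with elements `alpha`, `beta` (original
#'   scale), `partition`, `penalty`, `lambda`, `lambda0`, `converged`,
#'   `n_iter`, `loglik`, `loglik_trace` (penalized objective per iteration, on
#'   the standardized scale), `standardization` (centers/scales), and
#'   `std_params` (estimates on the standardized scale, used for
#'   KKT-style diagnostics). Methods: [predict.ql_fit()], `tidy()`,
#'   `glance()`, `autoplot()`, `print()`.
#'
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(y = rep(0:1, each = 20),
#'                     x1 = rnorm(40, rep(c(0, -1), each = 20)),
#'                     x2 = rnorm(40, rep(c(0, 1.5), each = 20)))
#' fit <- ql_fit(d, "y", marker_partition(c(x1 = 1, x2 = 2)))
#' predict(fit, d[1:3, ])
#' @export
ql_fit <- function(data, outcome, partition = NULL,
                   penalty = c("none", "ridge", "lasso"),
                   lambda = 0, lambda0 = 1e-4, standardize = TRUE,
                   init = NULL, tol = 1e-8, max_iter = NULL) {
  penalty <- match.arg(penalty)
  dd <- ql_data(data, outcome)
  X <- dd$X; y <- dd$y
  p <- ncol(X)
  if (is.null(partition)) partition <- marker_partition(rep(1L, p))
  partition <- as_partition(partition, p, colnames(X))
  K <- partition_k(partition)
  cl <- unclass(partition)
  if (length(unique(y)) < 2L) stop("outcome must contain both classes for fitting")
  if (penalty == "none") lambda <- rep(0, K)
  if (length(lambda) == 1L) lambda <- rep(lambda, K)
  if (length(lambda) != K) stop("lambda must be scalar or length K")
  if (any(lambda < 0) || lambda0 < 0) stop("penalty weights must be >= 0")
  if (is.null(max_iter)) max_iter <- if (penalty == "lasso") 5000L else 100L

  std <- standardize_markers(X, standardize)
  Xs <- std$X

  if (is.null(init)) {
    ybar <- mean(y)
    a0 <- rep(stats::qlogis(ybar) - log(K), K)
    b0 <- rep(0, p)
  } else {
    orig <- to_std_scale(init$alpha, init$beta, std, cl, K)
    a0 <- orig$alpha; b0 <- orig$beta
  }

  lam_marker <- lambda[cl] # per-marker penalty weight lambda_{k(j)}
  if (penalty == "lasso") {
    res <- cpp_fit_lasso(Xs, y, cl - 1L, a0, b0, lam_marker,
                         tol, as.integer(max_iter), 1e-5)
  } else {
    rdiag <- c(rep(if (penalty == "ridge") lambda0 else 0, K),
               if (penalty == "ridge") lam_marker else rep(0, p))
    res <- cpp_fit_fisher(Xs, y, cl - 1L, a0, b0, rdiag,
                          tol, as.integer(max_iter))
    if (isTRUE(res$singular)) {
      stop("information matrix W'VW is singular; refit with penalty = \"ridge\"")
    }
  }

  orig <- to_orig_scale(res$alpha, res$beta, std, cl, K)
  names(orig$beta) <- colnames(X)
  ll <- cpp_ql_loglik(Xs, y, cl - 1L, res$alpha, res$beta)
  structure(list(
    alpha = as.numeric(orig$alpha), beta = orig$beta,
    partition = partition, penalty = penalty,
    lambda = lambda, lambda0 = if (penalty == "ridge") lambda0 else 0,
    converged = isTRUE(res$converged), n_iter = res$n_iter,
    loglik = ll, loglik_trace = as.numeric(res$trace),
    standardization = list(center = std$center, scale = std$scale),
    std_params = list(alpha = as.numeric(res$alpha), beta = as.numeric(res$beta)),
    n = nrow(X), marker_names = colnames(X)
  ), class = "ql_fit")
}

# --- scale handling ---------------------------------------------------------

standardize_markers <- function(X, standardize) {
  if (!standardize) {
    return(list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(X = sweep(sweep(X, 2L, ctr), 2L, scl, "/"), center = ctr, scale = scl)
}

# beta_std = beta_orig * s ; alpha_std_k = alpha_orig_k + sum_{j in k} beta_j c_j
to_std_scale <- function(alpha, beta, std, cl, K) {
  bs <- beta * std$scale
  as <- alpha + vapply(seq_len(K), function(k) {
    sum(beta[cl == k] * std$center[cl == k])
  }, numeric(1))
  list(alpha = as, beta = bs)
}

to_orig_scale <- function(alpha, beta, std, cl, K) {
  bo <- beta / std$scale
  ao <- alpha - vapply(seq_len(K), function(k) {
    sum(beta[cl == k] * std$center[cl == k] / std$scale[cl == k])
  }, numeric(1))
  list(alpha = ao, beta = bo)
}

# Extract (X, y) from data-frame-with-outcome-column or matrix + vector.
ql_data <- function(data, outcome) {
  if (is.matrix(data)) {
    X <- data
    storage.mode(X) <- "double"
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    y <- outcome
  } else {
    if (!is.character(outcome) || length(outcome) != 1L) {
      stop("outcome must name a column of data")
    }
    if (!outcome %in% names(data)) stop("no column '", outcome, "' in data")
    y <- data[[outcome]]
    X <- marker_matrix(data[setdiff(names(data), outcome)])
  }
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(y) != nrow(X)) stop("outcome length does not match sample count")
  list(X = X, y = y)
}

# --- likelihood and gradient (reference R implementations) ------------------

#' Log-likelihood of the quasi-linear logistic model
#'
#' \eqn{\ell(\theta) = \sum_i y_i Q_i - \log(1 + e^{Q_i})} with the
#' quasi-linear score \eqn{Q_i}; evaluated with a stable \eqn{\log(1+e^x)}.
#' Operates on the marker scale it is given — no standardization is applied.
#'
#' @param data Marker data (data frame of numeric columns or matrix).
#' @param y 0/1 outcome vector.
#' @param alpha,beta,partition Model parameters as in [linear_scores()].
#' @return Scalar log-likelihood.
#' @export
ql_log_likelihood <- function(data, y, alpha, beta, partition) {
  X <- marker_matrix(data)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  Q <- row_lse(linear_score_matrix(X, alpha, beta, partition))
  sum(y * Q - (pmax(Q, 0) + log1p(exp(-abs(Q)))))
}

#' Gradient of the quasi-linear log-likelihood
#'
#' The analytic score vector \eqn{\partial\ell/\partial\theta = W^\top(y -
#' \pi)} in the ordering \eqn{(\alpha_1..\alpha_K, \beta_1..\beta_p)}, where
#' each sample contributes its softmax-gated design row
#' \eqn{(S_1,\dots,S_K, S_{k(1)}x_1,\dots,S_{k(p)}x_p)}.
#'
#' @inheritParams ql_log_likelihood
#' @return Numeric vector of length `K + p`.
#' @export
ql_score_gradient <- function(data, y, alpha, beta, partition) {
  X <- marker_matrix(data)
  y <- as.numeric(y)
  partition <- as_partition(partition, ncol(X), colnames(X))
  cl <- unclass(partition)
  L <- linear_score_matrix(X, alpha, beta, partition)
  Q <- row_lse(L)
  S <- exp(L - Q) # softmax rows (Q is the row log-sum-exp)
  pi <- stats::plogis(Q)
  r <- y - pi
  c(colSums(S * r), colSums(X * S[, cl, drop = FALSE] * r))
}

# --- predict & broom methods ------------------------------------------------

#' Predict from a fitted quasi-linear model
#'
#' @param object A [ql_fit()] object.
#' @param new_data Data frame or matrix of markers; an outcome column, if
#'   present under the fitted outcome's name, is ignored. Columns must match
#'   the fitted markers.
#' @param type `"response"` for \eqn{\pi_i = 1/(1+e^{-Q_i})}, `"link"` for the
#'   quasi-linear score \eqn{Q_i}, `"class"` for the 0/1 call at probability
#'   0.5, `"cluster"` for the dominant cluster index.
#' @param ... Unused.
#' @return Numeric (or integer) vector, one element per row.
#' @export
predict.ql_fit <- function(object, new_data,
                           type = c("response", "link", "class", "cluster"),
                           ...) {
  type <- match.arg(type)
  X <- fit_conform(object, new_data)
  L <- linear_score_matrix(X, object$alpha, object$beta, object$partition)
  Q <- row_lse(L)
  switch(type,
    link = Q,
    response = stats::plogis(Q),
    class = as.integer(Q > 0),
    cluster = apply(L, 1L, which.max)
  )
}

fit_conform <- function(object, new_data) {
  if (is.matrix(new_data)) {
    X <- new_data
    storage.mode(X) <- "double"
  } else {
    keep <- intersect(names(new_data), object$marker_names)
    if (length(keep) == length(object$marker_names)) {
      X <- marker_matrix(new_data[object$marker_names])
    } else {
      X <- marker_matrix(new_data[vapply(new_data, is.numeric, logical(1))])
    }
  }
  if (ncol(X) != length(object$beta)) {
    stop("new data has ", ncol(X), " markers but the model was fitted with ",
         length(object$beta))
  }
  X
}

#' @export
print.ql_fit <- function(x, ...) {
  cat("<ql_fit> quasi-linear logistic model\n")
  cat("  K =", partition_k(x$partition), " p =", length(x$beta),
      " n =", x$n, "\n")
  cat("  penalty:", x$penalty,
      if (x$penalty != "none") paste0("(lambda = ",
                                      paste(signif(x$lambda, 3), collapse = "/"),
                                      ")"), "\n")
  cat("  logLik:", format(x$loglik), " iterations:", x$n_iter,
      if (!x$converged) "(not converged)", "\n")
  invisible(x)
}

#' Tidy a quasi-linear fit
#'
#' @param x A `ql_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `cluster`,
#'   `estimate`, and whether the coefficient survived shrinkage (`selected`,
#'   `|estimate| > 1e-8`; intercept rows are always `TRUE`).
#' @export
tidy.ql_fit <- function(x, ...) {
  K <- partition_k(x$partition)
  dplyr::bind_rows(
    tibble::tibble(term = paste0("alpha", seq_len(K)),
                   cluster = seq_len(K), estimate = x$alpha, selected = TRUE),
    tibble::tibble(term = names(x$beta), cluster = as.integer(x$partition),
                   estimate = unname(x$beta),
                   selected = abs(unname(x$beta)) > 1e-8)
  )
}

#' Glance at a quasi-linear fit
#'
#' @inheritParams tidy.ql_fit
#' @return One-row tibble of fit summaries.
#' @export
glance.ql_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, penalty = x$penalty,
    lambda = if (length(unique(x$lambda)) == 1L) x$lambda[1L] else NA_real_,
    n_iter = x$n_iter, converged = x$converged,
    K = partition_k(x$partition), p = length(x$beta), nobs = x$n,
    n_selected = sum(abs(x$beta) > 1e-8)
  )
}

#' Plot the optimization trace of a quasi-linear fit
#'
#' @param object A `ql_fit`.
#' @param ... Unused.
#' @return A ggplot of the penalized log-likelihood per iteration.
#' @export
autoplot.ql_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace) - 1L,
                       objective = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "penalized log-likelihood",
                  title = paste0("Fisher scoring / gradient ascent trace (",
                                 object$penalty, ")"))
}

# --- cross-validation -------------------------------------------------------

#' Cross-validated penalty tuning
#'
#' Selects the shared penalty weight \eqn{\lambda} (applied to every cluster)
#' maximizing the mean held-out log-likelihood over stratified folds. A list
#' of length-`K` vectors may be supplied for per-cluster grids.
#'
#' @inheritParams ql_fit
#' @param lambda_grid Numeric vector of candidate shared \eqn{\lambda} values
#'   (or list of length-`K` vectors). Default: 10 log-spaced points in
#'   \eqn{[10^{-3}, 10^2]}.
#' @param folds Number of stratified CV folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param ... Passed to [ql_fit()] (e.g. `tol`, `max_iter`).
#'
#' @return An object of class `ql_cv`: list with `lambda` (the selected
#'   value), `penalty`, `table` (tibble of per-candidate mean/sd held-out
#'   log-likelihood), `folds`, `seed`. `tidy()` returns the table;
#'   `autoplot()` draws the CV curve.
#' @export
ql_cv <- function(data, outcome, partition = NULL,
                  penalty = c("ridge", "lasso"),
                  lambda_grid = NULL, folds = 5, seed = 1, lambda0 = 1e-4,
                  standardize = TRUE, ...) {
  penalty <- match.arg(penalty)
  dd <- ql_data(data, outcome)
  X <- dd$X; y <- dd$y
  if (is.null(partition)) partition <- marker_partition(rep(1L, ncol(X)))
  partition <- as_partition(partition, ncol(X), colnames(X))
  K <- partition_k(partition)
  cl <- unclass(partition)
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid()
  if (!is.list(lambda_grid)) lambda_grid <- as.list(lambda_grid)
  if (length(lambda_grid) == 0L) stop("lambda_grid is empty")
  if (folds < 2L) stop("folds must be >= 2")

  fold_id <- stratified_folds(y, folds, seed)
  # warm starts along the (descending) grid within each fold
  ord <- order(-vapply(lambda_grid, function(l) max(l), numeric(1)))
  held <- matrix(NA_real_, length(lambda_grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
      stop("fold ", f, " lacks both classes; use fewer folds")
    }
    std <- standardize_markers(X[tr, , drop = FALSE], standardize)
    Xs_te <- sweep(sweep(X[!tr, , drop = FALSE], 2L, std$center), 2L,
                   std$scale, "/")
    a <- rep(stats::qlogis(mean(y[tr])) - log(K), K)
    b <- rep(0, ncol(X))
    for (g in ord) {
      lam <- rep(lambda_grid[[g]], length.out = K)
      res <- cv_fit_std(std$X, y[tr], cl, K, a, b, lam, penalty, lambda0, ...)
      a <- res$alpha; b <- res$beta
      held[g, f] <- cpp_ql_loglik(Xs_te, y[!tr], cl - 1L, a, b) / sum(!tr)
    }
  }
  mean_ll <- rowMeans(held)
  best <- which.max(mean_ll) # ties: first (smaller index) wins
  tab <- tibble::tibble(
    candidate = seq_along(lambda_grid),
    lambda = vapply(lambda_grid, function(l) l[1L], numeric(1)),
    mean_loglik = mean_ll,
    sd_loglik = apply(held, 1L, stats::sd)
  )
  structure(list(lambda = lambda_grid[[best]], penalty = penalty,
                 lambda0 = lambda0, table = tab, folds = folds, seed = seed),
            class = "ql_cv")
}

default_lambda_grid <- function() 10^seq(-3, 2, length.out = 10)

cv_fit_std <- function(Xs, y, cl, K, a0, b0, lam, penalty, lambda0,
                       tol = 1e-8, max_iter = NULL, ...) {
  lam_marker <- lam[cl]
  if (penalty == "lasso") {
    if (is.null(max_iter)) max_iter <- 5000L
    cpp_fit_lasso(Xs, y, cl - 1L, a0, b0, lam_marker, tol,
                  as.integer(max_iter), 1e-5)
  } else {
    if (is.null(max_iter)) max_iter <- 100L
    rdiag <- c(rep(lambda0, K), lam_marker)
    cpp_fit_fisher(Xs, y, cl - 1L, a0, b0, rdiag, tol, as.integer(max_iter))
  }
}

stratified_folds <- function(y, folds, seed) {
  id <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      ix <- sample(which(y == cls))
      id[ix] <- rep_len(seq_len(folds), length(ix))
    }
  })
  id
}

#' @export
print.ql_cv <- function(x, ...) {
  cat("<ql_cv>", x$penalty, "tuning over", nrow(x$table), "candidates;",
      "selected lambda =", paste(signif(x$lambda, 4), collapse = "/"), "\n")
  invisible(x)
}

#' @export
tidy.ql_cv <- function(x, ...) x$table

#' @export
autoplot.ql_cv <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$lambda, .data$mean_loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$lambda[1L], linetype = 2) +
    ggplot2::labs(x = expression(lambda),
                  y = "mean held-out log-likelihood / sample",
                  title = paste0("Cross-validation curve (", object$penalty, ")"))
}

# --- model serialization ----------------------------------------------------

#' Write / read a fitted quasi-linear model as JSON
#'
#' Serializes everything needed to reproduce predictions: the partition,
#' standardization constants, penalty specification, parameter estimates and
#' convergence metadata.
#'
#' @param fit A `ql_fit`.
#' @param path File path (`.json`).
#' @return `write_ql_model()` returns `path` invisibly; `read_ql_model()`
#'   returns a `ql_fit`.
#' @export
write_ql_model <- function(fit, path) {
  obj <- list(
    package = "qlscore", class = "ql_fit",
    version = as.character(utils::packageVersion("qlscore")),
    alpha = fit$alpha, beta = as.list(fit$beta),
    partition = as.list(as.integer(fit$partition)) |>
      stats::setNames(names(fit$partition)),
    penalty = fit$penalty, lambda = fit$lambda, lambda0 = fit$lambda0,
    converged = fit$converged, n_iter = fit$n_iter, loglik = fit$loglik,
    standardization = fit$standardization, n = fit$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ql_model
#' @export
read_ql_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$class, "ql_fit")) stop("not a serialized ql_fit: ", path)
  part <- marker_partition(unlist(obj$partition))
  beta <- unlist(obj$beta)
  structure(list(
    alpha = as.numeric(obj$alpha), beta = beta, partition = part,
    penalty = obj$penalty, lambda = as.numeric(obj$lambda),
    lambda0 = obj$lambda0, converged = obj$converged, n_iter = obj$n_iter,
    loglik = obj$loglik, loglik_trace = numeric(0),
    standardization = list(center = as.numeric(obj$standardization$center),
                           scale = as.numeric(obj$standardization$scale)),
    std_params = NULL, n = obj$n, marker_names = names(beta)
  ), class = "ql_fit")
}
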