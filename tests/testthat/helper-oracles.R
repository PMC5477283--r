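# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Central finite differences of the quasi-linear log-likelihood in the
# (alpha, beta) ordering.
fd_gradient <- function(X, y, alpha, beta, partition, h = 1e-5) {
  K <- length(alpha)
  th <- c(alpha, beta)
  vapply(seq_along(th), function(j) {
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (ql_log_likelihood(X, y, tp[1:K], tp[-(1:K)], partition) -
       ql_log_likelihood(X, y, tm[1:K], tm[-(1:K)], partition)) / (2 * h)
  }, numeric(1))
}

# Proximal-gradient (ISTA) solver for the L1-penalized quasi-linear
# likelihood; a slow but independent route to the same optimum.
ista_lasso <- function(X, y, partition, lambda, max_iter = 200000,
                       tol = 1e-12) {
  K <- attr(partition, "K")
  cl <- unclass(partition)
  lamj <- c(rep(0, K), lambda[cl])
  th <- c(rep(stats::qlogis(mean(y)) - log(K), K), rep(0, ncol(X)))
  step <- 1 / (0.25 * norm(cbind(1, X), "2")^2)
  for (i in seq_len(max_iter)) {
    g <- ql_score_gradient(X, y, th[1:K], th[-(1:K)], partition)
    tn <- th + step * g
    tn <- sign(tn) * pmax(abs(tn) - step * lamj, 0)
    if (max(abs(tn - th)) < tol) {
      th <- tn
      break
    }
    th <- tn
  }
  list(alpha = th[1:K], beta = th[-(1:K)],
       objective = ql_log_likelihood(X, y, th[1:K], th[-(1:K)], partition) -
         sum(lamj * abs(th)))
}

# Pairwise-comparison AUC: P(case > control) + P(tie)/2 by enumeration.
brute_auc <- function(scores, y) {
  s1 <- scores[y == 1]
  s0 <- scores[y == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Small two-cluster logistic dataset with a heterogeneous signal.
toy_dataset <- function(n = 80, p = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    part <- marker_partition(stats::setNames(rep(1:2, each = p / 2),
                                             colnames(X)))
    eta <- log(exp(0.3 + 0.8 * X[, 1]) + exp(-0.5 + 1.2 * X[, p]))
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    list(X = X, y = y, partition = part)
  })
}

# KKT residuals of an L1-penalized quasi-linear fit, evaluated on the
# standardized scale the optimizer worked on.
lasso_kkt_residuals <- function(fit, X, y) {
  std <- fit$standardization
  Xs <- sweep(sweep(X, 2, std$center), 2, std$scale, "/")
  K <- partition_k(fit$partition)
  cl <- unclass(fit$partition)
  th <- c(fit$std_params$alpha, fit$std_params$beta)
  g <- ql_score_gradient(Xs, y, fit$std_params$alpha, fit$std_params$beta,
                         fit$partition)
  lamj <- c(rep(0, K), fit$lambda[cl])
  vapply(seq_along(th), function(j) {
    if (j <= K) return(abs(g[j]))
    if (abs(th[j]) <= 1e-10) max(0, abs(g[j]) - lamj[j])
    else abs(g[j] - lamj[j] * sign(th[j]))
  }, numeric(1))
}
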