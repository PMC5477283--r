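test_that("log-likelihood matches closed forms and the K = 1 standard model", {
  td <- toy_dataset()
  K <- 2
  # theta = 0: every Q_i equals log K, so l = n (ybar log K - log(1 + K))
  ll0 <- ql_log_likelihood(td$X, td$y, rep(0, K), rep(0, 6), td$partition)
  n <- length(td$y)
  expect_equal(ll0, n * (mean(td$y) * log(K) - log(1 + K)))
  # single sample at Q = 0 with y = 1: -log 2
  expect_equal(ql_log_likelihood(matrix(0, 1, 1), 1, 0, 0,
                                 marker_partition(1L)),
               -log(2))
  # K = 1: ordinary logistic log-likelihood, computed independently
  a <- 0.3; b <- rnorm(6)
  p1 <- marker_partition(rep(1L, 6))
  eta <- a + as.numeric(td$X %*% b)
  indep <- sum(td$y * log(stats::plogis(eta)) +
                 (1 - td$y) * log(1 - stats::plogis(eta)))
  expect_equal(ql_log_likelihood(td$X, td$y, a, b, p1), indep)
  expect_error(ql_log_likelihood(td$X, td$y + 0.5, a, b, p1), "0/1")
})

test_that("analytic gradient matches central finite differences", {
  withr::with_seed(77, {
    for (rep in 1:8) {
      n <- 30; p <- sample(4:6, 1); K <- 2
      X <- matrix(rnorm(n * p), n, p)
      y <- rbinom(n, 1, 0.5)
      part <- marker_partition(sample(rep(1:K, length.out = p)))
      a <- rnorm(K, sd = 0.5); b <- rnorm(p, sd = 0.5)
      g <- ql_score_gradient(X, y, a, b, part)
      fd <- fd_gradient(X, y, a, b, part)
      expect_lt(max(abs(g - fd) / (abs(fd) + 1e-3)), 1e-5)
    }
  })
  # K = 1: gradient reduces to (1, X)' weighted residuals
  td <- toy_dataset()
  p1 <- marker_partition(rep(1L, 6))
  a <- -0.2; b <- rnorm(6, sd = 0.3)
  r <- td$y - stats::plogis(a + as.numeric(td$X %*% b))
  expect_equal(unname(ql_score_gradient(td$X, td$y, a, b, p1)),
               unname(c(sum(r), as.numeric(t(td$X) %*% r))))
})

test_that("unpenalized MLE agrees with glm for K = 1 and is stationary", {
  td <- toy_dataset(n = 120, seed = 4)
  p1 <- marker_partition(stats::setNames(rep(1L, 6), colnames(td$X)))
  fit <- ql_fit(td$X, td$y, p1, penalty = "none", tol = 1e-12)
  gl <- stats::glm(td$y ~ td$X, family = stats::binomial())
  expect_lt(max(abs(c(fit$alpha, fit$beta) - unname(stats::coef(gl)))), 1e-6)
  # gradient vanishes at the MLE (standardized scale, where the fit ran)
  Xs <- scale(td$X)
  g <- ql_score_gradient(Xs, td$y, fit$std_params$alpha,
                         fit$std_params$beta, p1)
  expect_lt(max(abs(g)), 1e-6)
  # the objective trace never decreases
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("null data yield near-null estimates and two-cluster MLE is stable", {
  withr::with_seed(55, {
    n <- 4000
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rbinom(n, 1, 0.5) # independent of X: true beta = 0
    part <- marker_partition(c(1, 2))
    fit <- ql_fit(X, y, part, penalty = "none")
    expect_true(fit$converged)
    expect_lt(max(abs(fit$beta)), 4 / sqrt(n) * 3) # ~3 SE of the null
  })
})

test_that("ridge fitting matches a black-box optimizer and shrinks monotonically", {
  td <- toy_dataset(n = 60, seed = 9)
  cl <- unclass(td$partition)
  lam <- c(0.8, 1.5); lam0 <- 0.5
  fit <- ql_fit(td$X, td$y, td$partition, penalty = "ridge", lambda = lam,
                lambda0 = lam0, standardize = FALSE, tol = 1e-13)
  obj <- function(th) {
    ql_log_likelihood(td$X, td$y, th[1:2], th[-(1:2)], td$partition) -
      0.5 * lam0 * sum(th[1:2]^2) - 0.5 * sum(lam[cl] * th[-(1:2)]^2)
  }
  grad <- function(th) {
    ql_score_gradient(td$X, td$y, th[1:2], th[-(1:2)], td$partition) -
      c(lam0 * th[1:2], lam[cl] * th[-(1:2)])
  }
  o <- stats::optim(rep(0, 8), obj, grad, method = "BFGS",
                    control = list(fnscale = -1, maxit = 2000, reltol = 1e-15))
  expect_lt(max(abs(c(fit$alpha, fit$beta) - o$par)), 1e-4)
  # lambda = 0 reduces to the MLE
  f0 <- ql_fit(td$X, td$y, td$partition, penalty = "ridge", lambda = 0,
               lambda0 = 0, tol = 1e-12)
  fm <- ql_fit(td$X, td$y, td$partition, penalty = "none", tol = 1e-12)
  expect_lt(max(abs(c(f0$alpha, f0$beta) - c(fm$alpha, fm$beta))), 1e-6)
  # norm of the estimate decreases as lambda grows
  norms <- vapply(c(0.1, 1, 10, 100, 1000), function(l) {
    f <- ql_fit(td$X, td$y, td$partition, penalty = "ridge", lambda = l,
                lambda0 = l)
    sqrt(sum(c(f$std_params$alpha, f$std_params$beta)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 0.05)
})

test_that("lasso fitting satisfies KKT and matches a proximal-gradient oracle", {
  td <- toy_dataset(n = 80, seed = 21)
  lam <- c(0.5, 1.0)
  fit <- ql_fit(td$X, td$y, td$partition, penalty = "lasso", lambda = lam,
                standardize = FALSE)
  expect_true(fit$converged)
  expect_lt(max(lasso_kkt_residuals(fit, td$X, td$y)), 1e-4)
  # penalized objective within 1e-3 of the independent solver's optimum
  or <- ista_lasso(td$X, td$y, td$partition, lam)
  cl <- unclass(td$partition)
  ours <- ql_log_likelihood(td$X, td$y, fit$alpha, fit$beta, td$partition) -
    sum(lam[cl] * abs(fit$beta))
  expect_gt(ours, or$objective - 1e-3)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("a large enough lasso penalty shrinks every coefficient to zero", {
  td <- toy_dataset(n = 80, seed = 33)
  # at beta = 0 and the empirical-log-odds intercepts, the score equation
  # bounds the largest useful penalty
  K <- 2
  Xs <- scale(td$X)
  a0 <- rep(stats::qlogis(mean(td$y)) - log(K), K)
  g0 <- ql_score_gradient(Xs, td$y, a0, rep(0, 6), td$partition)
  lam_max <- max(abs(g0[-(1:K)]))
  fit <- ql_fit(td$X, td$y, td$partition, penalty = "lasso",
                lambda = lam_max * 1.05)
  expect_true(all(fit$beta == 0))
  expect_true(fit$converged)
  # intercept-only model still matches the empirical log-odds:
  # Q = log(sum exp(alpha_k)) = logit(ybar) at the optimum
  expect_lt(abs(quasi_linear_score(fit$alpha) - stats::qlogis(mean(td$y))),
            1e-4)
})

test_that("prediction inverts the logit and respects monotonicity", {
  td <- toy_dataset(n = 50, seed = 2)
  fit <- ql_fit(td$X, td$y, td$partition, penalty = "ridge", lambda = 1)
  q <- predict(fit, td$X, type = "link")
  pr <- predict(fit, td$X, type = "response")
  expect_equal(pr, stats::plogis(q))
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(order(q), order(pr))
  expect_equal(predict(fit, td$X, type = "class"), as.integer(q > 0))
  expect_equal(stats::plogis(5.051), 1 / (1 + exp(-5.051)))
  expect_error(predict(fit, td$X[, 1:3]), "markers")
})

test_that("cross-validation selects sensible penalties deterministically", {
  td <- toy_dataset(n = 100, seed = 8)
  d <- tibble::as_tibble(cbind(y = td$y, td$X))
  # degenerate single-point grid
  cv1 <- ql_cv(d, "y", td$partition, penalty = "ridge", lambda_grid = 3.3,
               seed = 5)
  expect_equal(cv1$lambda, 3.3)
  # strong signal: tiny penalty beats an overwhelming one
  withr::with_seed(14, {
    n <- 200
    X <- matrix(rnorm(n * 4), n, 4)
    colnames(X) <- paste0("x", 1:4)
    y <- rbinom(n, 1, stats::plogis(2 * X[, 1] - 2 * X[, 3]))
    ds <- tibble::as_tibble(cbind(y = y, X))
    part <- marker_partition(stats::setNames(c(1, 1, 2, 2), colnames(X)))
    cv <- ql_cv(ds, "y", part, penalty = "ridge",
                lambda_grid = c(0.001, 1e4), seed = 3)
    expect_equal(cv$lambda, 0.001)
    # permuted labels: the huge penalty wins
    yp <- sample(y)
    dp <- tibble::as_tibble(cbind(y = yp, X))
    cvp <- ql_cv(dp, "y", part, penalty = "ridge",
                 lambda_grid = c(0.001, 1e4), seed = 3)
    expect_equal(cvp$lambda, 1e4)
  })
  # determinism under a fixed seed
  cva <- ql_cv(d, "y", td$partition, penalty = "lasso",
               lambda_grid = c(0.1, 1, 10), seed = 11)
  cvb <- ql_cv(d, "y", td$partition, penalty = "lasso",
               lambda_grid = c(0.1, 1, 10), seed = 11)
  expect_identical(cva$table, cvb$table)
  expect_error(ql_cv(d, "y", td$partition, lambda_grid = numeric(0)), "empty")
  expect_error(ql_cv(d, "y", td$partition, folds = 1), "folds")
})

test_that("fitted models round-trip through JSON with identical predictions", {
  td <- toy_dataset(n = 60, seed = 19)
  fit <- ql_fit(td$X, td$y, td$partition, penalty = "lasso", lambda = 0.5)
  f <- tempfile(fileext = ".json")
  write_ql_model(fit, f)
  back <- read_ql_model(f)
  expect_equal(predict(back, td$X, type = "link"),
               predict(fit, td$X, type = "link"))
  expect_equal(back$alpha, fit$alpha)
  expect_equal(unname(back$beta), unname(fit$beta))
  unlink(f)
})

test_that("tidy, glance and autoplot expose the fit in broom style", {
  td <- toy_dataset(n = 60, seed = 23)
  fit <- ql_fit(td$X, td$y, td$partition, penalty = "lasso", lambda = 1)
  td1 <- tidy(fit)
  expect_equal(nrow(td1), 2 + 6)
  expect_true(all(c("term", "cluster", "estimate", "selected") %in% names(td1)))
  gl <- glance(fit)
  expect_equal(gl$K, 2L)
  expect_equal(gl$n_selected, sum(abs(fit$beta) > 1e-8))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("data-frame and matrix interfaces agree and errors are informative", {
  td <- toy_dataset(n = 40, seed = 31)
  d <- tibble::as_tibble(cbind(y = td$y, td$X))
  f1 <- ql_fit(d, "y", td$partition, penalty = "ridge", lambda = 2)
  f2 <- ql_fit(td$X, td$y, td$partition, penalty = "ridge", lambda = 2)
  expect_equal(f1$beta, f2$beta)
  expect_error(ql_fit(d, "z", td$partition), "no column")
  expect_error(ql_fit(td$X, rep(1, 40), td$partition), "both classes")
  expect_error(ql_fit(td$X, td$y, td$partition, lambda = -1,
                      penalty = "ridge"), ">= 0")
})
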