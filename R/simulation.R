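#' Simulation designs for the quasi-linear score studies
#'
#' Fully parameterized generative models used throughout the package's
#' simulation studies. Each class-conditional distribution is a mixture of
#' multivariate normals with a shared covariance; the built-in settings are:
#'
#' * `"consistency"`: p = 2. Controls standard bivariate normal; cases an
#'   equal-weight two-component mixture at means (−1, 0) and (0, 1.5),
#'   identity covariance. The quasi-linear model with K = 2 singleton
#'   clusters is exactly the Bayes log-posterior-odds here.
#' * `"a1"`–`"a3"` (homo-homo): both classes normal; mean shifts 1 (p = 2),
#'   0.1 and 0.5 (p = 100) in every coordinate.
#' * `"b1"`–`"b4"` (homo-hetero): controls N(0, I_100); cases mixtures whose
#'   component means load on disjoint coordinate blocks (see Details).
#' * `"c1"` (hetero-hetero): both classes two-component mixtures (p = 100).
#' * `"d1"` (correlated): p = 70, block covariance
#'   \eqn{\Sigma_1 = 0.7 I_{35} + 0.3 J_{35}} within and
#'   \eqn{\Sigma_2 = -0.15 J_{35}} across two 35-marker blocks.
#'
#' @details Component means for the heterogeneous settings (writing
#'   \eqn{r_m} for the constant vector of value `r` and length `m`):
#'   b1: (−1, 0_99) and (0_50, 1.5, 0_49), weights 1/2 each;
#'   b2: (−1_10, 0_90) and (0_50, 1.5_10, 0_40);
#'   b3: three components of weight 1/3, first mean (−1.5, 0_99), the other
#'   two at the origin (only the first is specified by the source design;
#'   the remaining means default to zero);
#'   b4: (−1.5_3, 0_97), (0_34, 1.5_3, 0_63), (0_67, 1_3, 0_30);
#'   c1: controls at 0_100 and (0_50, 0.3_10, 0_40), cases at
#'   (0.5_10, 0_90) and (0_50, 0.8_10, 0_40) — every informative block of
#'   this setting spans 10 coordinates, which keeps the design's ideal
#'   (Bayes) AUC of about 0.84 compatible with the discrimination an
#'   unpenalized fit can reach on it;
#'   d1: (−0.5_5, 0_65) and (0_35, 1_5, 0_30).
#'   Each design carries the marker partition its quasi-linear analysis uses
#'   (K = 2 with 50/50 markers for p = 100; K = 3 with 34/33/33 for b3/b4;
#'   K = 2 with 35/35 for d1, matching the covariance blocks; singleton
#'   clusters for p = 2).
#'
#' @param setting One of `"consistency"`, `"a1"`, `"a2"`, `"a3"`, `"b1"`,
#'   `"b2"`, `"b3"`, `"b4"`, `"c1"`, `"d1"`.
#' @return An object of class `sim_design`: list with `name`, `p`, `prior`
#'   (P(Y = 1), 0.5 for all built-ins), `class0`/`class1` (each a list with
#'   `weights` and `means`), `Sigma` (`NULL` for identity), and `partition`.
#' @examples
#' d <- sim_design("b1")
#' head(sim_generate(d, n = 6, seed = 1))
#' @export
sim_design <- function(setting = c("consistency", "a1", "a2", "a3",
                                   "b1", "b2", "b3", "b4", "c1", "d1")) {
  setting <- match.arg(setting)
  rp <- function(r, m) rep(r, m)
  spec <- switch(setting,
    consistency = list(p = 2, c0 = list(1, list(c(0, 0))),
                       c1 = list(c(.5, .5), list(c(-1, 0), c(0, 1.5))),
                       part = c(1L, 2L)),
    a1 = list(p = 2, c0 = list(1, list(rp(0, 2))),
              c1 = list(1, list(rp(1, 2))), part = c(1L, 2L)),
    a2 = list(p = 100, c0 = list(1, list(rp(0, 100))),
              c1 = list(1, list(rp(0.1, 100))), part = rep(1:2, each = 50)),
    a3 = list(p = 100, c0 = list(1, list(rp(0, 100))),
              c1 = list(1, list(rp(0.5, 100))), part = rep(1:2, each = 50)),
    b1 = list(p = 100, c0 = list(1, list(rp(0, 100))),
              c1 = list(c(.5, .5), list(c(-1, rp(0, 99)),
                                        c(rp(0, 50), 1.5, rp(0, 49)))),
              part = rep(1:2, each = 50)),
    b2 = list(p = 100, c0 = list(1, list(rp(0, 100))),
              c1 = list(c(.5, .5), list(c(rp(-1, 10), rp(0, 90)),
                                        c(rp(0, 50), rp(1.5, 10), rp(0, 40)))),
              part = rep(1:2, each = 50)),
    b3 = list(p = 100, c0 = list(1, list(rp(0, 100))),
              c1 = list(rp(1 / 3, 3), list(c(-1.5, rp(0, 99)), rp(0, 100),
                                           rp(0, 100))),
              part = rep(1:3, times = c(34, 33, 33))),
    b4 = list(p = 100, c0 = list(1, list(rp(0, 100))),
              c1 = list(rp(1 / 3, 3),
                        list(c(rp(-1.5, 3), rp(0, 97)),
                             c(rp(0, 34), rp(1.5, 3), rp(0, 63)),
                             c(rp(0, 67), rp(1, 3), rp(0, 30)))),
              part = rep(1:3, times = c(34, 33, 33))),
    c1 = list(p = 100,
              c0 = list(c(.5, .5), list(rp(0, 100),
                                        c(rp(0, 50), rp(0.3, 10), rp(0, 40)))),
              c1 = list(c(.5, .5), list(c(rp(0.5, 10), rp(0, 90)),
                                        c(rp(0, 50), rp(0.8, 10), rp(0, 40)))),
              part = rep(1:2, each = 50)),
    d1 = list(p = 70, c0 = list(1, list(rp(0, 70))),
              c1 = list(c(.5, .5), list(c(rp(-0.5, 5), rp(0, 65)),
                                        c(rp(0, 35), rp(1, 5), rp(0, 30)))),
              part = rep(1:2, each = 35))
  )
  Sigma <- NULL
  if (setting == "d1") {
    J <- matrix(1, 35, 35)
    S1 <- 0.7 * diag(35) + 0.3 * J
    S2 <- -0.15 * J
    Sigma <- rbind(cbind(S1, S2), cbind(t(S2), S1))
  }
  new_sim_design(setting, spec$p, 0.5,
                 list(weights = spec$c0[[1]], means = spec$c0[[2]]),
                 list(weights = spec$c1[[1]], means = spec$c1[[2]]),
                 Sigma, spec$part)
}

#' @rdname sim_design
#' @param name Label for a custom design.
#' @param p Marker count.
#' @param prior P(Y = 1).
#' @param class0,class1 Lists with elements `weights` (summing to 1) and
#'   `means` (list of length-`p` vectors).
#' @param Sigma Shared covariance matrix (`NULL` = identity); must be
#'   symmetric positive definite.
#' @param partition Cluster assignment of the `p` markers used by the
#'   quasi-linear analyses of this design.
#' @export
new_sim_design <- function(name, p, prior, class0, class1, Sigma = NULL,
                           partition = rep(1L, p)) {
  for (cls in list(class0, class1)) {
    if (abs(sum(cls$weights) - 1) > 1e-8) stop("component weights must sum to 1")
    if (length(cls$weights) != length(cls$means)) {
      stop("one mean vector per component weight is required")
    }
    if (any(vapply(cls$means, length, integer(1)) != p)) {
      stop("all component means must have length p = ", p)
    }
  }
  ch <- NULL
  if (!is.null(Sigma)) {
    if (!isSymmetric(unname(Sigma))) stop("Sigma must be symmetric")
    ch <- tryCatch(chol(Sigma),
                   error = function(e) stop("Sigma is not positive definite"))
  }
  structure(list(name = name, p = as.integer(p), prior = prior,
                 class0 = class0, class1 = class1, Sigma = Sigma,
                 chol = ch,
                 partition = as_partition(partition, p)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>", x$name, " p =", x$p,
      " components:", length(x$class0$weights), "/",
      length(x$class1$weights),
      if (!is.null(x$Sigma)) " (correlated)", "\n")
  invisible(x)
}

#' Generate a dataset from a simulation design
#'
#' Draws `n` samples: class labels split exactly in half between cases and
#' controls (set `balanced = FALSE` for Bernoulli(`prior`) labels), then
#' within class a mixture component by its weight, then a multivariate
#' normal draw at that component's mean with the design covariance.
#'
#' @param design A [sim_design()].
#' @param n Total sample count (>= 2).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param balanced Exact 50/50 class split (default) vs random labels.
#' @return Tibble with column `y` and marker columns `x1..xp`.
#' @export
sim_generate <- function(design, n, seed = NULL, balanced = TRUE) {
  stopifnot(inherits(design, "sim_design"))
  if (n < 2L) stop("n must be >= 2")
  gen <- function() {
    y <- if (balanced) {
      rep(c(0L, 1L), c(floor(n / 2), ceiling(n / 2)))
    } else {
      stats::rbinom(n, 1L, design$prior)
    }
    X <- matrix(0, n, design$p)
    for (cls in 0:1) {
      ix <- which(y == cls)
      if (!length(ix)) next
      cc <- if (cls == 0L) design$class0 else design$class1
      comp <- sample.int(length(cc$weights), length(ix), replace = TRUE,
                         prob = cc$weights)
      Z <- matrix(stats::rnorm(length(ix) * design$p), length(ix), design$p)
      if (!is.null(design$chol)) Z <- Z %*% design$chol
      M <- do.call(rbind, cc$means)[comp, , drop = FALSE]
      X[ix, ] <- Z + M
    }
    colnames(X) <- paste0("x", seq_len(design$p))
    tibble::as_tibble(X) |> tibble::add_column(y = y, .before = 1L)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Bayes-optimal quasi-linear parameters
#'
#' For designs whose controls are standard normal and whose cases are a
#' normal mixture with identity covariance and component means confined to
#' disjoint clusters, the log posterior odds is exactly a quasi-linear score
#' with \eqn{\alpha_k = \log \tau_k - \|\mu_{1k}\|^2/2 + \log(\pi_1/\pi_0)}
#' and \eqn{\beta_k = \mu_{1k}} restricted to cluster `k`.
#'
#' @param design A [sim_design()] in the supported family (the built-in
#'   `"consistency"` and `"b*"` settings qualify; others raise an error).
#' @return List with `alpha` (length K), `beta` (length p) and `partition`.
#' @examples
#' round(unlist(bayes_optimal_params(sim_design("consistency"))[c("alpha", "beta")]), 2)
#' @export
bayes_optimal_params <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  c0 <- design$class0; c1 <- design$class1
  if (!is.null(design$Sigma) || length(c0$weights) != 1L ||
      any(c0$means[[1L]] != 0)) {
    stop("supported designs need standard-normal controls and identity covariance")
  }
  part <- design$partition
  K <- partition_k(part)
  G <- length(c1$weights)
  if (G != K) stop("design has ", G, " case components but K = ", K, " clusters")
  cl <- unclass(part)
  alpha <- numeric(K)
  beta <- numeric(design$p)
  for (g in seq_len(G)) {
    mu <- c1$means[[g]]
    nz <- which(mu != 0)
    if (length(nz) && !all(cl[nz] == g)) {
      stop("component ", g, " mean is not confined to cluster ", g)
    }
    alpha[g] <- log(c1$weights[g]) - sum(mu^2) / 2 +
      log(design$prior / (1 - design$prior))
    beta[cl == g] <- mu[cl == g]
  }
  list(alpha = alpha, beta = beta, partition = part)
}

#' Consistency study of the unpenalized quasi-linear MLE
#'
#' Repeatedly generates datasets from the `"consistency"` design, fits the
#' quasi-linear logistic model by Fisher scoring without penalty (K = 2, one
#' marker per cluster) and collects the replicate-wise estimates, whose means
#' approach the analytic Bayes-optimal parameters as `n` grows.
#'
#' @param n Samples per dataset (the reference study uses 400 and 1600).
#' @param replicates Number of simulated datasets.
#' @param seed Master seed; per-replicate seeds are derived from it, so
#'   results do not depend on execution order.
#' @return Tibble with columns `replicate`, `alpha1`, `alpha2`, `beta1`,
#'   `beta2`, `converged`. Replicates whose fit fails are dropped; their
#'   count is in attribute `n_failed`.
#' @export
run_consistency_study <- function(n = 1600, replicates = 1000, seed = 1) {
  if (replicates < 1L) stop("replicates must be >= 1")
  design <- sim_design("consistency")
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, replicates))
  rows <- purrr::map(seq_len(replicates), function(r) {
    d <- sim_generate(design, n, seed = seeds[r])
    fit <- tryCatch(
      ql_fit(d, "y", design$partition, penalty = "none"),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    tibble::tibble(replicate = r, alpha1 = fit$alpha[1], alpha2 = fit$alpha[2],
                   beta1 = unname(fit$beta[1]), beta2 = unname(fit$beta[2]),
                   converged = fit$converged)
  })
  failed <- sum(vapply(rows, is.null, logical(1)))
  out <- dplyr::bind_rows(rows)
  attr(out, "n_failed") <- failed
  out
}

#' AUC study across simulation settings and fitting methods
#'
#' For each setting and replicate, draws a training and a test set, fits the
#' requested methods on the training data (penalties tuned by stratified
#' cross-validation on a shared-\eqn{\lambda} grid) and records the test-set
#' AUC. All methods of a replicate see the same data, so method contrasts
#' are paired. Method labels combine the score (`LL` = linear, one cluster;
#' `QL` = quasi-linear with the design's partition) with the penalty:
#' `"LL-ridge"`, `"LL-lasso"`, `"QL-ridge"`, `"QL-lasso"`, `"LL-none"`,
#' `"QL-none"`.
#'
#' @param settings Character vector of design names (see [sim_design()]).
#' @param methods Character vector of method labels.
#' @param replicates Replicates per setting.
#' @param n_train,n_test Training/test sample sizes per replicate.
#' @param lambda_grid Candidate shared penalty weights for cross-validation.
#' @param folds CV folds.
#' @param seed Master seed (per-replicate seeds derived deterministically).
#' @return Tibble with columns `setting`, `method`, `replicate`, `auc`,
#'   `lambda`, `converged`; summarize with [summarise_auc_study()].
#' @export
run_auc_study <- function(settings, methods = c("LL-ridge", "QL-lasso"),
                          replicates = 100, n_train = 400, n_test = 200,
                          lambda_grid = NULL, folds = 5, seed = 1) {
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid()
  bad <- setdiff(methods, c(outer(c("LL", "QL"), c("none", "ridge", "lasso"),
                                  paste, sep = "-")))
  if (length(bad)) stop("unsupported method label(s): ", paste(bad, collapse = ", "))
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, replicates))
  out <- purrr::map(settings, function(s) {
    design <- sim_design(s)
    purrr::map(seq_len(replicates), function(r) {
      tr <- sim_generate(design, n_train, seed = seeds[r])
      te <- sim_generate(design, n_test, seed = seeds[r] + 1L)
      y_te <- te$y
      purrr::map(methods, function(m) {
        sc <- strsplit(m, "-", fixed = TRUE)[[1L]]
        part <- if (sc[1L] == "QL") design$partition else
          marker_partition(rep(1L, design$p))
        pen <- sc[2L]
        res <- tryCatch({
          lam <- 0
          if (pen %in% c("ridge", "lasso")) {
            cv <- ql_cv(tr, "y", part, penalty = pen,
                        lambda_grid = lambda_grid, folds = folds,
                        seed = seeds[r])
            lam <- cv$lambda
          }
          fit <- ql_fit(tr, "y", part, penalty = pen, lambda = lam)
          tibble::tibble(setting = s, method = m, replicate = r,
                         auc = auc(predict(fit, te, type = "link"), y_te),
                         lambda = lam[1L], converged = fit$converged)
        }, error = function(e) {
          tibble::tibble(setting = s, method = m, replicate = r,
                         auc = NA_real_, lambda = NA_real_, converged = FALSE)
        })
        res
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out
}

#' Summarize an AUC study
#'
#' Mean and standard deviation of the test AUC per setting and method,
#' with the count of failed (excluded) replicates.
#'
#' @param results Tibble from [run_auc_study()].
#' @return Tibble with `setting`, `method`, `mean_auc`, `sd_auc`, `n`,
#'   `n_failed`.
#' @export
summarise_auc_study <- function(results) {
  results |>
    dplyr::group_by(.data$setting, .data$method) |>
    dplyr::summarise(
      mean_auc = mean(.data$auc, na.rm = TRUE),
      sd_auc = stats::sd(.data$auc, na.rm = TRUE),
      n = sum(!is.na(.data$auc)),
      n_failed = sum(is.na(.data$auc)),
      .groups = "drop"
    )
}
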