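#' Cluster-wise linear scores
#'
#' Evaluates the per-cluster linear scores \eqn{L_k = \alpha_k + \beta_k^\top
#' x_{(k)}} for a single sample. These are the building blocks of the
#' quasi-linear score [quasi_linear_score()].
#'
#' @param x Numeric marker vector of length `p`.
#' @param alpha Numeric vector of `K` cluster intercepts.
#' @param beta Numeric coefficient vector of length `p`, in marker order.
#' @param partition A [marker_partition()] (or coercible vector) mapping the
#'   `p` markers to clusters `1..K`.
#'
#' @return Numeric vector of `K` linear scores.
#' @examples
#' part <- marker_partition(c(1, 2))
#' linear_scores(c(0.2, -0.1), alpha = c(1, 1), beta = c(1, 1), part)
#' @export
linear_scores <- function(x, alpha, beta, partition) {
  partition <- as_partition(partition, length(x))
  K <- partition_k(partition)
  if (length(alpha) != K) {
    stop("alpha has length ", length(alpha), " but partition has K = ", K)
  }
  if (length(beta) != length(x)) {
    bad <- which(tabulate(unclass(partition), K) != partition_sizes(partition))
    stop("beta has length ", length(beta), " but partition covers ",
         length(x), " markers",
         if (length(bad)) paste0(" (cluster ", bad[1L], " mismatched)"))
  }
  cl <- unclass(partition)
  as.numeric(alpha + vapply(seq_len(K), function(k) {
    sum(beta[cl == k] * x[cl == k])
  }, numeric(1)))
}

#' Quasi-linear score (log-sum-exp of linear scores)
#'
#' The Kolmogorov–Nagumo average with \eqn{\phi = \exp} of the cluster scores:
#' \eqn{Q = \log \sum_k \exp(L_k)}. A smooth upper approximation of their
#' maximum, satisfying \eqn{M \le Q \le M + \log K}. Evaluated max-shifted
#' (\eqn{M + \log\sum\exp(L_k - M)}) so it never overflows.
#'
#' @param scores Numeric vector of cluster linear scores \eqn{L_k}.
#' @return A scalar.
#' @examples
#' quasi_linear_score(c(5, 2, -1, -4)) # 5.051: the top cluster dominates
#' @export
quasi_linear_score <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  m <- max(scores)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(scores - m)))
}

#' Maximum score
#'
#' The hard maximum \eqn{M = \max_k L_k} of the cluster linear scores; the
#' limit of the tempered quasi-linear score as the temperature grows.
#'
#' @inheritParams quasi_linear_score
#' @return A scalar.
#' @export
max_score <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  max(scores)
}

#' Tempered quasi-linear score
#'
#' \eqn{Q_\tau = \tau^{-1} \log \sum_k \exp(\tau L_k)} interpolates between
#' soft and hard maxima: \eqn{Q_1 = Q} and \eqn{Q_\tau \to M} as
#' \eqn{\tau \to \infty}. The normalized variant divides the inner sum by
#' `K`; it converges to the mean of the `L_k` as \eqn{\tau \to 0^+} and is the
#' form used for limit checks, because the unnormalized score diverges like
#' \eqn{\log(K)/\tau} at small \eqn{\tau} when `K > 1`.
#'
#' @inheritParams quasi_linear_score
#' @param tau Positive temperature.
#' @param normalized If `TRUE`, average rather than sum inside the logarithm.
#' @return A scalar.
#' @export
tempered_score <- function(scores, tau, normalized = FALSE) {
  if (length(scores) == 0L) stop("empty score vector")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("tau must be a positive scalar")
  }
  lse <- quasi_linear_score(tau * scores)
  if (normalized) lse <- lse - log(length(scores))
  lse / tau
}

#' Generalized Kolmogorov–Nagumo average of scores
#'
#' \eqn{G = \phi^{-1}(\sum_k \phi(L_k))} for an invertible \eqn{\phi}.
#' With `phi = exp` this is the quasi-linear score; with the identity it is
#' the plain sum of cluster scores (the linear-score case).
#'
#' @inheritParams quasi_linear_score
#' @param phi,phi_inv A strictly monotone function on the score range and its
#'   inverse. Checked by a round-trip on the input values.
#' @return A scalar.
#' @export
kn_average <- function(scores, phi, phi_inv) {
  if (length(scores) == 0L) stop("empty score vector")
  ph <- vapply(scores, phi, numeric(1))
  if (!all(is.finite(ph))) stop("phi is not finite on the score range")
  rt <- vapply(ph, phi_inv, numeric(1))
  if (max(abs(rt - scores)) > 1e-6 * (1 + max(abs(scores)))) {
    stop("phi_inv does not invert phi on the input range")
  }
  phi_inv(sum(ph))
}

#' Softmax cluster weights
#'
#' \eqn{S_k = \exp(L_k) / \sum_j \exp(L_j)}: the gating weights with which
#' each cluster enters the gradient of the quasi-linear log-likelihood.
#' Computed max-shifted.
#'
#' @inheritParams quasi_linear_score
#' @return Numeric vector on the `K`-simplex.
#' @export
softmax_weights <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Dominant cluster
#'
#' Index of the cluster whose linear score is largest — the cluster that the
#' quasi-linear score effectively selects when one score dominates. Ties are
#' broken deterministically by the lowest cluster index.
#'
#' @inheritParams quasi_linear_score
#' @return Integer cluster index.
#' @export
dominant_cluster <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  which.max(scores)
}

# Batch evaluation over a sample x marker matrix; returns n x K matrix of L.
# Same semantics as linear_scores row by row, vectorized per cluster.
linear_score_matrix <- function(X, alpha, beta, partition) {
  X <- as.matrix(X)
  partition <- as_partition(partition, ncol(X), colnames(X))
  K <- partition_k(partition)
  stopifnot(length(alpha) == K, length(beta) == ncol(X))
  cl <- unclass(partition)
  L <- matrix(rep(alpha, each = nrow(X)), nrow(X), K)
  for (k in seq_len(K)) {
    j <- which(cl == k)
    L[, k] <- L[, k] + X[, j, drop = FALSE] %*% beta[j]
  }
  L
}

# Row-wise stable log-sum-exp of a matrix.
row_lse <- function(L) {
  m <- apply(L, 1L, max)
  m + log(rowSums(exp(L - m)))
}

#' Quasi-linear scores for a dataset
#'
#' Batch version of [quasi_linear_score()]: evaluates the per-sample cluster
#' scores and their log-sum-exp for every row of a marker table.
#'
#' @param data Data frame or matrix of markers (samples in rows).
#' @param alpha,beta,partition Parameters as in [linear_scores()].
#' @return A tibble with one row per sample: the cluster scores `L1..LK`,
#'   the quasi-linear score `Q`, the hard maximum `M`, and the
#'   `dominant_cluster`.
#' @export
ql_score_table <- function(data, alpha, beta, partition) {
  X <- marker_matrix(data)
  L <- linear_score_matrix(X, alpha, beta, partition)
  colnames(L) <- paste0("L", seq_len(ncol(L)))
  tibble::as_tibble(L) |>
    dplyr::mutate(
      Q = row_lse(L),
      M = apply(L, 1L, max),
      dominant_cluster = apply(L, 1L, which.max)
    )
}

# Accept matrix or data frame of numeric marker columns.
marker_matrix <- function(data) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  ok <- vapply(data, is.numeric, logical(1))
  if (!all(ok)) {
    stop("non-numeric marker columns: ", paste(names(data)[!ok], collapse = ", "))
  }
  as.matrix(data)
}
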