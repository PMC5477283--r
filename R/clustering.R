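#' Ward clustering of markers
#'
#' Groups the marker columns by agglomerative Ward clustering and cuts the
#' tree into `k` clusters, producing the [marker_partition()] consumed by
#' [ql_fit()]. Clustering sees training data only — pass nothing you intend
#' to evaluate on.
#'
#' @param data Data frame or matrix of numeric marker columns (samples in
#'   rows; at least 2).
#' @param k Target cluster count, between 1 and the number of markers.
#' @param metric `"euclidean"` for Euclidean distance between standardized
#'   marker profiles (classical Ward), or `"correlation"` for
#'   \eqn{1 - r} distance on Pearson correlations.
#'
#' @return A list of class `ql_clustering` with `tree` (an [stats::hclust]
#'   object, `ward.D2` linkage) and `partition` (a `marker_partition`;
#'   clusters are relabeled `1..k` by the smallest member index so output is
#'   deterministic).
#' @export
ward_cluster_markers <- function(data, k, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  X <- marker_matrix(data)
  if (nrow(X) < 2L) stop("need at least 2 samples to cluster markers")
  p <- ncol(X)
  if (k < 1L || k > p) stop("k must be between 1 and ", p)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  sds <- apply(X, 2L, stats::sd)
  if (metric == "correlation" && any(sds == 0)) {
    stop("constant marker(s) with correlation metric: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  d <- if (metric == "euclidean") {
    Z <- scale(X, center = TRUE, scale = ifelse(sds == 0, 1, sds))
    stats::dist(t(Z))
  } else {
    stats::as.dist(1 - stats::cor(X))
  }
  tree <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  # relabel clusters by order of smallest member index
  first <- vapply(seq_len(k), function(g) min(which(raw == g)), integer(1))
  relab <- rank(first)[raw]
  part <- marker_partition(stats::setNames(relab, colnames(X)))
  structure(list(tree = tree, partition = part, metric = metric),
            class = "ql_clustering")
}

#' @export
print.ql_clustering <- function(x, ...) {
  cat("<ql_clustering> Ward (ward.D2),", x$metric, "metric\n")
  print(x$partition)
  invisible(x)
}

#' Correlation matrix in cluster order
#'
#' Pearson correlations of the markers with rows/columns permuted so that
#' markers of the same cluster are adjacent — the arrangement under which
#' heterogeneous blocks become visible.
#'
#' @param data Data frame or matrix of numeric marker columns.
#' @param partition Optional [marker_partition()] (or a `ql_clustering`)
#'   giving the display order; default is the original column order.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data, partition = NULL) {
  X <- marker_matrix(data)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance marker(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  if (!is.null(partition)) {
    if (inherits(partition, "ql_clustering")) partition <- partition$partition
    partition <- as_partition(partition, ncol(X), colnames(X))
    ord <- order(unclass(partition), seq_len(ncol(X)))
    R <- R[ord, ord]
  }
  R
}

# Vectorized two-sample t statistics for every marker; Welch by default.
t_statistics <- function(X, y, pooled = FALSE) {
  X <- as.matrix(X)
  g1 <- y == 1
  n1 <- sum(g1); n0 <- sum(!g1)
  if (n1 < 2L || n0 < 2L) stop("both classes need at least 2 samples")
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2L, stats::var)
  v0 <- apply(X[!g1, , drop = FALSE], 2L, stats::var)
  se <- if (pooled) {
    sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    sqrt(sp * (1 / n1 + 1 / n0))
  } else {
    sqrt(v1 / n1 + v0 / n0)
  }
  (m1 - m0) / se
}

#' Split-sample t-statistic heterogeneity diagnostic
#'
#' Splits the samples into two stratified halves, computes the two-sample
#' t-statistic of each marker in each half, and flags markers whose t-values
#' disagree in sign — a symptom of heterogeneous subgroups (under pure noise
#' the signs agree only half the time).
#'
#' @param data Data frame with outcome + markers, or marker matrix.
#' @param outcome Outcome column name, or vector when `data` is a matrix.
#' @param seed Integer seed controlling the random half-split.
#' @param pooled Use the pooled-variance t statistic instead of Welch.
#' @return A tibble with columns `marker`, `t1`, `t2`, `sign_mismatch`.
#' @export
split_t_diagnostic <- function(data, outcome, seed = 1, pooled = FALSE) {
  dd <- ql_data(data, outcome)
  X <- dd$X; y <- dd$y
  half <- stratified_folds(y, 2L, seed)
  for (h in 1:2) {
    if (length(unique(y[half == h])) < 2L) {
      stop("half ", h, " lacks both classes")
    }
  }
  t1 <- t_statistics(X[half == 1L, , drop = FALSE], y[half == 1L], pooled)
  t2 <- t_statistics(X[half == 2L, , drop = FALSE], y[half == 2L], pooled)
  tibble::tibble(
    marker = colnames(X), t1 = unname(t1), t2 = unname(t2),
    sign_mismatch = sign(t1) != sign(t2) & t1 != 0 & t2 != 0
  )
}

#' Select the top-|t| markers
#'
#' Marker preselection: indices of the `m` markers with the largest absolute
#' two-sample t-statistic between the classes, ties broken by lower column
#' index. Operates on training data only.
#'
#' @inheritParams split_t_diagnostic
#' @param m Number of markers to keep.
#' @return Integer vector of marker column indices (named by marker).
#' @export
select_top_t <- function(data, outcome, m, pooled = FALSE) {
  dd <- ql_data(data, outcome)
  if (m < 1L) stop("m must be >= 1")
  if (m > ncol(dd$X)) stop("m exceeds the number of markers")
  t <- t_statistics(dd$X, dd$y, pooled)
  ord <- order(-abs(t), seq_along(t))
  sel <- sort(ord[seq_len(m)])
  stats::setNames(sel, colnames(dd$X)[sel])
}

#' Plot the split-sample t diagnostic
#'
#' @param object Tibble from [split_t_diagnostic()].
#' @param ... Unused.
#' @return A ggplot: t in half 1 vs half 2, sign-mismatched markers in red.
#' @export
plot_split_t <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t1, .data$t2,
                                       colour = .data$sign_mismatch)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "t statistic (half 1)", y = "t statistic (half 2)",
                  colour = "sign mismatch")
}
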