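#' Marker partition
#'
#' A disjoint, exhaustive assignment of `p` markers to `K` clusters. The
#' quasi-linear score evaluates one linear score per cluster, so every fitting
#' and scoring function in the package is parameterized by such a partition.
#'
#' @param assignment Integer (or factor/character coercible to integer levels)
#'   vector of length `p` giving, for each marker, its cluster in `1..K`.
#'   Names, when present, are taken as marker names. Alternatively a
#'   two-column data frame with columns `marker` and `cluster`.
#' @param markers Optional character vector of marker names, recycled onto
#'   unnamed assignments.
#'
#' @return An object of class `marker_partition`: an integer vector of cluster
#'   indices named by marker, with attributes `K` (cluster count) and `sizes`
#'   (per-cluster marker counts).
#'
#' @details Cluster labels must cover `1..K` with every cluster non-empty;
#'   gaps in the labels are an error rather than silently re-indexed, so that
#'   partitions read from files keep their printed meaning.
#'
#' @examples
#' marker_partition(c(x1 = 1, x2 = 1, x3 = 2))
#' @export
marker_partition <- function(assignment, markers = NULL) {
  if (is.data.frame(assignment)) {
    if (!all(c("marker", "cluster") %in% names(assignment))) {
      stop("data-frame assignment needs columns 'marker' and 'cluster'")
    }
    markers <- as.character(assignment$marker)
    assignment <- assignment$cluster
  }
  if (is.factor(assignment)) assignment <- as.integer(as.character(assignment))
  if (is.character(assignment)) assignment <- as.integer(assignment)
  if (!is.numeric(assignment) || length(assignment) < 1L) {
    stop("assignment must be a non-empty vector of cluster indices")
  }
  cl <- as.integer(assignment)
  if (anyNA(cl)) stop("assignment contains missing cluster indices")
  if (!is.null(markers)) names(cl) <- markers
  else if (!is.null(names(assignment))) names(cl) <- names(assignment)
  K <- max(cl)
  if (min(cl) < 1L) stop("cluster indices must be >= 1")
  sizes <- tabulate(cl, nbins = K)
  if (any(sizes == 0L)) {
    stop("clusters ", paste(which(sizes == 0L), collapse = ", "),
         " are empty: labels must cover 1..K")
  }
  structure(cl, K = K, sizes = sizes, class = "marker_partition")
}

#' @export
print.marker_partition <- function(x, ...) {
  cat("<marker_partition> p =", length(x), " K =", attr(x, "K"),
      " sizes:", paste(attr(x, "sizes"), collapse = "/"), "\n")
  invisible(x)
}

#' @rdname marker_partition
#' @param x A `marker_partition`.
#' @export
partition_k <- function(x) attr(x, "K")

#' @rdname marker_partition
#' @export
partition_sizes <- function(x) attr(x, "sizes")

#' @export
as_tibble.marker_partition <- function(x, ...) {
  tibble::tibble(
    marker = if (is.null(names(x))) paste0("x", seq_along(x)) else names(x),
    cluster = as.integer(x)
  )
}

# Coerce user input (marker_partition, bare vector, df) + check p conformity.
as_partition <- function(partition, p, marker_names = NULL) {
  if (!inherits(partition, "marker_partition")) {
    partition <- marker_partition(partition)
  }
  if (length(partition) != p) {
    stop("partition covers ", length(partition), " markers but data has ", p)
  }
  if (!is.null(marker_names) && !is.null(names(partition)) &&
      !identical(names(partition), marker_names)) {
    if (setequal(names(partition), marker_names)) {
      partition <- marker_partition(unclass(partition)[marker_names])
    } else {
      stop("partition marker names do not match data marker names")
    }
  }
  partition
}
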