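#' Read a delimited marker table
#'
#' Reads a CSV/TSV file whose first row holds marker names, whose first
#' column holds sample IDs, and whose body is numeric. The delimiter is
#' chosen from the extension (`.csv` comma; `.tsv`/`.txt` tab).
#'
#' @param path File path.
#' @return A tibble whose first column is `sample_id` followed by numeric
#'   marker columns, in file order. Attributes are plain; use
#'   [marker_matrix()]-style subsetting downstream.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 2L) stop("expected a sample-ID column plus marker columns")
  markers <- names(raw)[-1L]
  if (anyDuplicated(markers)) {
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  body <- raw[-1L]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) | body[[j]] == "")
    if (length(bad)) {
      stop("non-numeric or missing value at row ", bad[1L],
           ", column '", markers[j], "'")
    }
    body[[j]] <- v
  }
  tibble::as_tibble(body) |>
    tibble::add_column(sample_id = as.character(raw[[1L]]), .before = 1L)
}

#' Write a marker table
#'
#' Inverse of [read_marker_table()]: writes sample IDs plus numeric marker
#' columns with full precision, delimiter chosen from the extension.
#'
#' @param data Data frame; a `sample_id` column is used if present, else row
#'   numbers are written.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(data, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(data)
  if (!"sample_id" %in% names(df)) {
    df <- cbind(sample_id = paste0("s", seq_len(nrow(df))), df)
  } else {
    df <- df[c("sample_id", setdiff(names(df), "sample_id"))]
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format, digits = 17, trim = TRUE,
                    scientific = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a marker partition
#'
#' JSON files store an object `{marker_name: cluster_id}`; TSV files store
#' two columns `marker` and `cluster`. Cluster indices are 1-based.
#'
#' @param partition A [marker_partition()].
#' @param path Output path; format chosen from the extension (`.json` or
#'   `.tsv`).
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a `marker_partition`.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "marker_partition"))
  nm <- names(partition)
  if (is.null(nm)) nm <- paste0("x", seq_along(partition))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(stats::setNames(as.list(as.integer(partition)), nm),
                         path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(
      data.frame(marker = nm, cluster = as.integer(partition)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    marker_partition(unlist(obj))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    marker_partition(df)
  }
}

#' Export a linkage tree as a merge table
#'
#' Writes the merge sequence of an [stats::hclust] tree as TSV with columns
#' `left`, `right`, `height` (negative values reference leaves, positive
#' values earlier merges, following the hclust convention).
#'
#' @param tree An `hclust` object (or a `ql_clustering`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(tree, path) {
  if (inherits(tree, "ql_clustering")) tree <- tree$tree
  stopifnot(inherits(tree, "hclust"))
  utils::write.table(
    data.frame(left = tree$merge[, 1L], right = tree$merge[, 2L],
               height = tree$height),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
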