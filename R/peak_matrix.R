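#' Samples-by-peak-cluster intensity matrix
#'
#' The feature table every downstream statistic and classifier
#' consumes: one row per sample, one column per peak cluster (columns
#' sorted by ascending cluster centre m/z, named `mz_<rounded centre>`).
#'
#' @param values Numeric matrix (samples x clusters), nonnegative, with
#'   rownames = sample ids.
#' @param clusters `data.frame` with columns `cluster_id`, `mz_center`,
#'   `window_lo`, `window_hi`, `prevalence`.
#' @param labels Character vector of per-sample class labels.
#' @param flags Optional logical matrix, same shape as `values`, marking
#'   cells filled by the second pass whose window maximum fell below the
#'   second-pass signal-to-noise threshold.
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(values, clusters, labels, flags = NULL) {
  values <- as.matrix(values)
  if (nrow(clusters) != ncol(values))
    stop("clusters table and value columns disagree")
  if (length(labels) != nrow(values))
    stop("labels and value rows disagree")
  if (any(!is.finite(values)))
    stop("peak matrix must be complete and finite")
  if (any(values < 0)) stop("peak intensities must be nonnegative")
  if (is.unsorted(clusters$mz_center))
    stop("clusters must be sorted by ascending mz_center")
  colnames(values) <- paste0("mz_", round(clusters$mz_center))
  if (is.null(flags))
    flags <- matrix(FALSE, nrow(values), ncol(values))
  dimnames(flags) <- dimnames(values)
  structure(list(values = values, clusters = clusters,
                 labels = as.character(labels), flags = flags),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d samples x %d clusters (%d node_positive, %d node_negative)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "node_positive"), sum(x$labels == "node_negative")))
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$values)

#' Read/write a peak matrix as CSV
#'
#' Layout: first column `sample_id`, second `label`, remaining columns
#' `mz_<rounded centre>`.  A companion cluster table (columns
#' `cluster_id`, `mz_center`, `window_lo`, `window_hi`, `prevalence`)
#' is written alongside with suffix `_clusters.csv` and restored on
#' read when present; otherwise windows are reconstructed as +/- 0.25%
#' of the column m/z.
#'
#' @param pm A [peak_matrix()].
#' @param path CSV path.
#' @return `read_peak_matrix()` returns a [peak_matrix()];
#'   `write_peak_matrix()` returns `path` invisibly.
#' @export
write_peak_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "peak_matrix"))
  df <- data.frame(sample_id = rownames(pm$values), label = pm$labels,
                   pm$values, check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  data.table::fwrite(pm$clusters, companion_cluster_path(path))
  invisible(path)
}

#' @rdname write_peak_matrix
#' @export
read_peak_matrix <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "label") %in% names(df)))
    stop("peak matrix file must start with sample_id and label columns")
  vals <- as.matrix(df[, setdiff(names(df), c("sample_id", "label")), drop = FALSE])
  rownames(vals) <- df$sample_id
  cpath <- companion_cluster_path(path)
  if (file.exists(cpath)) {
    clusters <- data.table::fread(cpath, data.table = FALSE)
  } else {
    mz <- as.numeric(sub("^mz_", "", colnames(vals)))
    clusters <- data.frame(cluster_id = seq_along(mz), mz_center = mz,
                           window_lo = mz * (1 - 0.0025),
                           window_hi = mz * (1 + 0.0025),
                           prevalence = NA_real_)
  }
  peak_matrix(vals, clusters, df$label)
}

companion_cluster_path <- function(path) {
  sub("(\\.[^.]*)?$", "_clusters\\1", path)
}

# Cluster centres as numeric m/z, used when matching model features.
matrix_mz <- function(pm) pm$clusters$mz_center
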