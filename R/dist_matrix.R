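#' Sample-by-sample dissimilarity matrix
#'
#' @param values symmetric non-negative numeric matrix with zero diagonal.
#' @param sample_ids sample labels; defaults to rownames.
#' @param method dissimilarity tag: "bray_curtis", "aitchison", "pearson",
#'   "euclidean", or another descriptive string.
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, sample_ids = rownames(values),
                        method = "bray_curtis") {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (max(abs(values - t(values))) > 1e-12)
    stop("validation error: asymmetric distance matrix")
  if (any(diag(values) != 0)) stop("validation error: nonzero diagonal")
  if (any(values < 0)) stop("validation error: negative distances")
  if (method == "bray_curtis" && any(values > 1 + 1e-12))
    stop("bray_curtis distances must be <= 1")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 method = method),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d samples\n", x$method, length(x$sample_ids)))
  invisible(x)
}

#' Subset a distance matrix by sample ids (original order preserved)
#' @param dm dist_matrix.
#' @param samples sample ids to keep.
#' @export
dm_subset <- function(dm, samples) {
  idx <- sort(match(samples, dm$sample_ids))
  if (anyNA(idx)) stop("unknown sample ids")
  dist_matrix(dm$values[idx, idx, drop = FALSE], dm$sample_ids[idx], dm$method)
}

#' Write a distance matrix as square labelled TSV
#'
#' Values are written with 12 decimal digits so a write/read round trip is
#' exact at that precision. The method tag rides in the header's first cell
#' as `dist:<method>`.
#'
#' @param dm dist_matrix.
#' @param path destination.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- as.data.frame(formatC(dm$values, format = "f", digits = 12),
                      check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(dm$sample_ids), paste0("dist:", dm$method)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square labelled TSV distance matrix
#' @param path file written by [write_distance_matrix()].
#' @return dist_matrix; asymmetric input or a nonzero diagonal is an error.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  method <- sub("^dist:", "", names(df)[1])
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dist_matrix(m, ids, method)
}
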