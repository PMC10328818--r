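#' Taxon-by-sample count table
#'
#' The central abundance container: a non-negative integer matrix with taxa in
#' rows and samples in columns, taxon rank annotations (genus/family lineage,
#' with "unknown" allowed for unannotated reads), and per-sample read depths
#' kept in sync with the column sums.
#'
#' @param counts non-negative integer matrix, taxa in rows, samples in columns.
#' @param taxa data.frame with columns `taxon_id`, `rank` (e.g. "genus"),
#'   and optionally `family` (lineage used when aggregating upwards;
#'   `NA`/"unknown" marks missing annotation).
#' @param sample_ids character vector of unique sample labels; defaults to
#'   `colnames(counts)`.
#' @return object of class `count_table` with fields `counts`, `taxa`,
#'   `sample_ids`, `depths`.
#' @export
count_table <- function(counts, taxa, sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(sample_ids)) stop("sample_ids required (or name the columns)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.data.frame(taxa)) taxa <- data.frame(taxon_id = as.character(taxa),
                                               rank = "genus")
  if (anyDuplicated(taxa$taxon_id)) stop("duplicate taxon ids")
  if (nrow(taxa) != nrow(counts)) stop("taxa table does not match count rows")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != floor(counts))) stop("counts must be integers")
  dimnames(counts) <- list(taxa$taxon_id, sample_ids)
  structure(list(counts = counts, taxa = taxa,
                 sample_ids = as.character(sample_ids),
                 depths = colSums(counts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples (rank: %s; median depth %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$taxa$rank), collapse = "/"),
              format(stats::median(x$depths))))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count table by sample and/or taxon
#'
#' @param ct count_table.
#' @param samples character or logical/integer selector of samples to keep.
#' @param taxa selector of taxa to keep.
#' @return count_table; retained ids keep their original order.
#' @export
ct_subset <- function(ct, samples = NULL, taxa = NULL) {
  ti <- seq_len(nrow(ct$counts)); si <- seq_len(ncol(ct$counts))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, ct$sample_ids) else si[samples]
    if (anyNA(si)) stop("unknown sample ids in subset")
    si <- sort(si)   # never reorder retained samples
  }
  if (!is.null(taxa)) {
    ti <- if (is.character(taxa)) match(taxa, ct$taxa$taxon_id) else ti[taxa]
    if (anyNA(ti)) stop("unknown taxon ids in subset")
    ti <- sort(ti)
  }
  count_table(ct$counts[ti, si, drop = FALSE],
              ct$taxa[ti, , drop = FALSE],
              ct$sample_ids[si])
}

#' Read a taxon-by-sample count table
#'
#' Two plain-text layouts are supported. `tsv`: first column `taxon_id`,
#' second column `rank` (optional third column `family`), remaining columns
#' one per sample; the header's first cell must be `taxon_id` (a sentinel
#' declaring taxa-in-rows orientation). `triplet`: sparse BIOM-style long
#' format with columns `taxon_id`, `rank`, `sample_id`, `count`.
#'
#' @param path file path.
#' @param format "tsv" (wide) or "triplet" (sparse long).
#' @return [count_table()]
#' @export
read_count_table <- function(path, format = c("tsv", "triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("parse error: empty table in ", path)
  if (format == "triplet") {
    need <- c("taxon_id", "rank", "sample_id", "count")
    if (!all(need %in% names(df))) stop("triplet file must have columns ",
                                        paste(need, collapse = ", "))
    cnt <- suppressWarnings(as.numeric(df$count))
    bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
    if (length(bad)) stop(sprintf(
      "parse error: cell at row %d (taxon %s, sample %s) is not a non-negative integer",
      bad[1], df$taxon_id[bad[1]], df$sample_id[bad[1]]))
    taxa <- unique(df[, c("taxon_id", "rank")])
    sids <- unique(df$sample_id)
    m <- matrix(0, nrow(taxa), length(sids),
                dimnames = list(taxa$taxon_id, sids))
    m[cbind(match(df$taxon_id, taxa$taxon_id), match(df$sample_id, sids))] <- cnt
    return(count_table(m, taxa, sids))
  }
  if (names(df)[1] != "taxon_id")
    stop("header sentinel missing: first column must be 'taxon_id' (taxa in rows)")
  meta_cols <- intersect(c("taxon_id", "rank", "family"), names(df))
  taxa <- df[, meta_cols, drop = FALSE]
  if (!"rank" %in% names(taxa)) taxa$rank <- "genus"
  scols <- setdiff(names(df), meta_cols)
  if (!length(scols)) stop("no sample columns found")
  m <- matrix(NA_real_, nrow(df), length(scols))
  for (j in seq_along(scols)) {
    v <- suppressWarnings(as.numeric(df[[scols[j]]]))
    bad <- which(is.na(v))
    if (length(bad)) stop(sprintf(
      "parse error: cell at row %d, column '%s' ('%s') is not numeric",
      bad[1], scols[j], df[[scols[j]]][bad[1]]))
    m[, j] <- v
  }
  if (any(m < 0)) stop("validation error: negative count entries")
  count_table(m, taxa, scols)
}

#' Write a count table as wide TSV
#' @param ct count_table.
#' @param path destination file.
#' @export
write_count_table <- function(ct, path) {
  df <- cbind(ct$taxa, as.data.frame(ct$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
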