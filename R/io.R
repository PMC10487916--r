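#' Read a BED-like interval file
#'
#' Two dialects are accepted. `"one_based_tsv"` (the canonical on-disk form of
#' this package) is a headered TSV whose `start`/`stop` columns are already
#' 1-based inclusive and pass through unchanged. `"bed"` is headerless,
#' 0-based, half-open; on read the start is shifted by +1 and the end kept, so
#' `chr1 0 100` becomes the 1-based inclusive interval (chr1, 1, 100) of size
#' 100.
#'
#' @param path Path to the file.
#' @param dialect `"one_based_tsv"` or `"bed"`.
#' @return data.frame with columns `chrom`, `start`, `stop` plus any extra
#'   columns present in the file.
#' @seealso [write_intervals_tsv()] for the paired writer; write-then-read is
#'   the identity.
#' @export
read_bed_like <- function(path, dialect = c("one_based_tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "one_based_tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    .check_columns(df, c("chrom", "start", "stop"), path)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
    names(df)[1:3] <- c("chrom", "start", "stop")
    if (ncol(df) >= 4L) names(df)[4] <- "name"
    df$start <- df$start + 1  # 0-based half-open -> 1-based inclusive
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$stop) | df$stop < df$start | df$start < 1)
  if (length(bad)) {
    stop(sprintf("malformed interval at line %d of %s", bad[1] + (dialect == "one_based_tsv"), path))
  }
  df
}

#' Write intervals (and any companion columns) as headered one-based TSV
#'
#' @param df data.frame with at least `chrom`, `start`, `stop`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals_tsv <- function(df, path) {
  .check_columns(df, c("chrom", "start", "stop"))
  write_tsv(df, path)
}

#' Write any data.frame as tab-separated text with a header
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a raw count matrix with a feature-class column
#'
#' Expected layout: first column `feature_id`, second column `feature_class`
#' (one of endogenous, negative_control, positive_control, housekeeping),
#' remaining columns one per sample.
#'
#' @param path Path to the TSV.
#' @return list with `counts` (numeric matrix, rownames = feature ids) and
#'   `feature_class` (named character vector).
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_columns(df, c("feature_id", "feature_class"), path)
  counts <- as.matrix(df[, setdiff(names(df), c("feature_id", "feature_class")), drop = FALSE])
  mode(counts) <- "numeric"
  rownames(counts) <- df$feature_id
  list(counts = counts, feature_class = stats::setNames(df$feature_class, df$feature_id))
}

#' Write a count matrix with its feature classes
#'
#' @param counts Numeric matrix (features x samples), rownames = feature ids.
#' @param feature_class Character vector aligned with rows of `counts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, feature_class, path) {
  df <- data.frame(feature_id = rownames(counts),
                   feature_class = as.character(feature_class),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
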