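#' Size of a genomic interval
#'
#' All coordinates in this package are 1-based and inclusive at both ends, the
#' convention of cytogenetic coordinate tables: a single base has
#' `start == stop` and size 1, and `size = stop - start + 1`.
#'
#' @param interval A data.frame with numeric columns `start` and `stop`
#'   (additional columns, e.g. `chrom`, are ignored). May have any number of
#'   rows.
#' @return Integer-valued numeric vector of widths in bp, one per row.
#' @examples
#' interval_size(data.frame(start = 1914109, stop = 20323997))  # 18409889
#' @export
interval_size <- function(interval) {
  .check_columns(interval, c("start", "stop"), "interval")
  start <- as.numeric(interval$start)
  stop_ <- as.numeric(interval$stop)
  if (any(!is.finite(start)) || any(!is.finite(stop_))) {
    stop("interval coordinates must be finite numbers")
  }
  if (any(start < 1)) stop("interval start must be >= 1 (1-based coordinates)")
  if (any(stop_ < start)) stop("interval stop must be >= start")
  stop_ - start + 1
}

# GRanges view of a chrom/start/stop data.frame (1-based inclusive, native fit).
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = as.numeric(df$start), end = as.numeric(df$stop))
  )
}

# All overlapping (query, subject) index pairs between two interval tables;
# overlap means >= 1 shared bp on the same chromosome.
.overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(.as_granges(a), .as_granges(b)))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}
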