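# Copy-number aberration calling and recurrent-region selection.

#' Call copy-number gains and losses from a probe track
#'
#' A gain is a maximal run of at least `min_probes` consecutive probes on one
#' chromosome whose log2 ratios are all `>= gain_threshold`; a loss is the
#' symmetric run at `<= loss_threshold`. Probes exactly at the threshold are
#' included. A single sub-threshold probe terminates a run (no gap tolerance).
#' The call interval spans the first probe's start to the last probe's stop and
#' `mean_log2` is the arithmetic mean over the run.
#'
#' @param track data.frame with columns `chrom`, `start`, `stop`,
#'   `log2_ratio` and optionally `case_id` (a single case per call; a missing
#'   column is filled with `"case1"`). Probes must be sorted by chromosome then
#'   start, with no duplicated positions within a chromosome.
#' @param min_probes Minimum run length (default 3).
#' @param gain_threshold Positive log2 threshold for gains (default +0.25).
#' @param loss_threshold Negative log2 threshold for losses (default -0.25).
#' @return data.frame with columns `case_id`, `chrom`, `start`, `stop`,
#'   `direction` ("gain"/"loss"), `n_probes`, `mean_log2`; zero rows when no
#'   run qualifies.
#' @export
call_aberrations <- function(track, min_probes = 3, gain_threshold = 0.25,
                             loss_threshold = -0.25) {
  .check_columns(track, c("chrom", "start", "stop", "log2_ratio"), "track")
  if (min_probes < 1) stop("min_probes must be >= 1")
  if (!(gain_threshold > 0 && loss_threshold < 0)) {
    stop("need gain_threshold > 0 > loss_threshold")
  }
  if (!"case_id" %in% names(track)) track$case_id <- "case1"
  if (length(unique(track$case_id)) > 1L) {
    stop("call_aberrations takes one case at a time; split by case_id first")
  }

  empty <- .empty_df(list(case_id = character(0), chrom = character(0),
                          start = numeric(0), stop = numeric(0),
                          direction = character(0), n_probes = integer(0),
                          mean_log2 = numeric(0)))
  if (nrow(track) == 0L) return(empty)

  # sortedness within the given chromosome block order; duplicates forbidden
  blocks <- split(seq_len(nrow(track)), factor(track$chrom, levels = unique(track$chrom)))
  for (idx in blocks) {
    s <- track$start[idx]
    if (is.unsorted(s, strictly = FALSE)) stop("track is not sorted by chromosome then start")
    if (anyDuplicated(s)) stop("duplicate probe positions within a chromosome")
  }

  out <- list()
  for (idx in blocks) {
    r <- track$log2_ratio[idx]
    state <- ifelse(r >= gain_threshold, 1L, ifelse(r <= loss_threshold, -1L, 0L))
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values != 0L & runs$lengths >= min_probes
    for (k in which(keep)) {
      run <- idx[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        case_id = track$case_id[run[1]],
        chrom = track$chrom[run[1]],
        start = track$start[run[1]],
        stop = track$stop[run[length(run)]],
        direction = if (runs$values[k] > 0L) "gain" else "loss",
        n_probes = length(run),
        mean_log2 = mean(track$log2_ratio[run]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cytoband penetrance of gains and losses across cases
#'
#' A case contributes at most once per (band, direction), no matter how many of
#' its calls overlap the band; a call overlapping several bands increments each
#' of them. `n_probes` sums the probe counts of all overlapping calls of that
#' direction (a call spanning two bands contributes its probes to both).
#'
#' @param calls data.frame of calls for all cases, as returned by
#'   [call_aberrations()] (rbind over cases).
#' @param bands Cytoband data.frame with `chrom`, `band`, `cytoband`, `start`,
#'   `stop` (e.g. `genome$cytobands`).
#' @param n_cases Total number of analyzed cases (penetrance denominator).
#' @return data.frame with one row per (band, direction), including
#'   zero-count rows: `chrom`, `band`, `cytoband`, `start`, `stop`,
#'   `direction`, `n_cases`, `frequency`, `n_probes`.
#' @export
aggregate_penetrance <- function(calls, bands, n_cases) {
  .check_columns(bands, c("chrom", "band", "cytoband", "start", "stop"), "bands")
  if (nrow(bands) == 0L) stop("empty band list")
  if (n_cases < 1) stop("n_cases must be >= 1")

  out <- bands[rep(seq_len(nrow(bands)), each = 2L),
               c("chrom", "band", "cytoband", "start", "stop")]
  out$direction <- rep(c("gain", "loss"), nrow(bands))
  out$n_cases <- 0L
  out$frequency <- 0
  out$n_probes <- 0L
  rownames(out) <- NULL

  if (nrow(calls) > 0L) {
    .check_columns(calls, c("case_id", "chrom", "start", "stop", "direction", "n_probes"),
                   "calls")
    hits <- .overlap_pairs(calls, bands)
    if (nrow(hits)) {
      key_band <- hits$subject
      key_dir <- calls$direction[hits$query]
      row_of <- (key_band - 1L) * 2L + ifelse(key_dir == "gain", 1L, 2L)
      case_of <- calls$case_id[hits$query]
      # distinct cases per (band, direction)
      uniq <- !duplicated(paste(row_of, case_of))
      tab <- table(factor(row_of[uniq], levels = seq_len(nrow(out))))
      out$n_cases <- as.integer(tab)
      out$frequency <- out$n_cases / n_cases
      ptab <- tapply(calls$n_probes[hits$query], factor(row_of, levels = seq_len(nrow(out))),
                     sum)
      out$n_probes <- as.integer(ifelse(is.na(ptab), 0L, ptab))
    }
  }
  out
}

#' Select recurrent regions from a penetrance table
#'
#' Bands with frequency at or above `min_frequency` are retained; adjacent or
#' overlapping retained bands on the same chromosome with the same direction
#' are merged into one region spanning them. A merged region reports the
#' maximum case count/frequency over its bands and the summed probe count; its
#' cytoband label joins the first and last band names.
#'
#' @param penetrance Output of [aggregate_penetrance()].
#' @param min_frequency Recurrence threshold in (0, 1\] (default 0.19, the
#'   lowest retained frequency in the reference cohort).
#' @return data.frame with `chrom`, `cytoband`, `start`, `stop`, `size`,
#'   `direction`, `n_cases`, `frequency`, `n_probes`.
#' @export
select_recurrent_regions <- function(penetrance, min_frequency = 0.19) {
  if (!(min_frequency > 0 && min_frequency <= 1)) {
    stop("min_frequency must be in (0, 1]")
  }
  .check_columns(penetrance, c("chrom", "band", "cytoband", "start", "stop",
                               "direction", "n_cases", "frequency", "n_probes"),
                 "penetrance")
  sel <- penetrance[penetrance$n_cases > 0 & penetrance$frequency >= min_frequency, ]
  empty <- .empty_df(list(chrom = character(0), cytoband = character(0),
                          start = numeric(0), stop = numeric(0), size = numeric(0),
                          direction = character(0), n_cases = integer(0),
                          frequency = numeric(0), n_probes = integer(0)))
  if (nrow(sel) == 0L) return(empty)

  out <- list()
  for (grp in split(sel, paste(sel$chrom, sel$direction))) {
    grp <- grp[order(grp$start), ]
    cur <- grp[1, ]
    first_band <- cur$band
    for (i in seq_len(nrow(grp))[-1]) {
      nxt <- grp[i, ]
      if (nxt$start <= cur$stop + 1) {  # adjacent or overlapping
        cur$stop <- max(cur$stop, nxt$stop)
        cur$n_cases <- max(cur$n_cases, nxt$n_cases)
        cur$frequency <- max(cur$frequency, nxt$frequency)
        cur$n_probes <- cur$n_probes + nxt$n_probes
        cur$band <- nxt$band  # remember last merged band
      } else {
        cur$cytoband <- .region_label(cur$chrom, first_band, cur$band)
        out[[length(out) + 1L]] <- cur
        cur <- nxt
        first_band <- cur$band
      }
    }
    cur$cytoband <- .region_label(cur$chrom, first_band, cur$band)
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$direction), ]
  data.frame(chrom = res$chrom, cytoband = res$cytoband,
             start = res$start, stop = res$stop,
             size = res$stop - res$start + 1,
             direction = res$direction, n_cases = res$n_cases,
             frequency = res$frequency, n_probes = res$n_probes,
             stringsAsFactors = FALSE, row.names = NULL)
}

.region_label <- function(chrom, first_band, last_band) {
  base <- sub("^chr", "", chrom)
  if (identical(first_band, last_band)) paste0(base, first_band)
  else paste0(base, first_band, "-", last_band)
}

#' Map feature annotations onto recurrent regions
#'
#' A feature hits a region iff their intervals share at least 1 bp (1-based
#' inclusive on both sides); a feature abutting a region (feature stop =
#' region start - 1) does not hit. Features may hit several regions.
#'
#' @param annotations data.frame with `feature_id`, `chrom`, `start`, `stop`.
#' @param regions Output of [select_recurrent_regions()].
#' @param genome Optional `genome_model`; if supplied, annotation chromosomes
#'   absent from the genome raise a warning (not an error).
#' @return data.frame sorted by feature id: `feature_id`, `chrom`,
#'   `feature_start`, `feature_stop`, `cytoband`, `region_start`,
#'   `region_stop`, `direction`.
#' @export
map_features_to_regions <- function(annotations, regions, genome = NULL) {
  .check_columns(annotations, c("feature_id", "chrom", "start", "stop"), "annotations")
  .check_columns(regions, c("chrom", "cytoband", "start", "stop", "direction"), "regions")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(annotations$chrom), genome$chromosomes$chrom)
    if (length(unknown)) {
      warning("annotation chromosome(s) not in genome model: ",
              paste(unknown, collapse = ", "))
    }
  }
  hits <- .overlap_pairs(annotations, regions)
  res <- data.frame(
    feature_id = annotations$feature_id[hits$query],
    chrom = annotations$chrom[hits$query],
    feature_start = annotations$start[hits$query],
    feature_stop = annotations$stop[hits$query],
    cytoband = regions$cytoband[hits$subject],
    region_start = regions$start[hits$subject],
    region_stop = regions$stop[hits$subject],
    direction = regions$direction[hits$subject],
    stringsAsFactors = FALSE)
  res <- res[order(res$feature_id, res$region_start), ]
  rownames(res) <- NULL
  res
}
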