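# Two-stage CNA-miRNA integration and cross-study DE-list comparison.

#' Direction concordance of a DE miRNA with a copy-number region
#'
#' Concordant iff (up-regulated AND gain) or (down-regulated AND loss); every
#' other combination is discordant. Vectorized pure function.
#'
#' @param de_direction "up" or "down" (recycled).
#' @param cna_direction "gain" or "loss" (recycled).
#' @return Character vector, "concordant" or "discordant".
#' @export
classify_concordance <- function(de_direction, cna_direction) {
  if (!all(de_direction %in% c("up", "down"))) {
    stop("de_direction must be 'up' or 'down'")
  }
  if (!all(cna_direction %in% c("gain", "loss"))) {
    stop("cna_direction must be 'gain' or 'loss'")
  }
  ifelse((de_direction == "up" & cna_direction == "gain") |
           (de_direction == "down" & cna_direction == "loss"),
         "concordant", "discordant")
}

#' Integrate DE miRNAs with recurrent copy-number regions
#'
#' First integration approach: each DE miRNA is joined (by normalized id:
#' case-folded, "hsa-" prefix stripped) to every recurrent region its
#' annotation overlaps, producing one record per (miRNA, region) pair with a
#' concordance verdict. A miRNA overlapping several regions yields several
#' records but counts once in `n_mapped`, and counts as concordant if at
#' least one of its records is concordant.
#'
#' @param de_records data.frame with `feature_id` and `log2_fc` (typically the
#'   significant subset from [differential_expression()]). Must be non-empty.
#' @param feature_hits Output of [map_features_to_regions()] for the miRNA
#'   annotations.
#' @return list with `records` (data.frame: feature_id, log2_fc,
#'   de_direction, cytoband, region_start, region_stop, cna_direction,
#'   concordant) and `summary` (list: n_de, n_mapped, pct_mapped,
#'   n_concordant, pct_concordant; percentages to one decimal, half away from
#'   zero).
#' @export
integrate_cna_mirna <- function(de_records, feature_hits) {
  .check_columns(de_records, c("feature_id", "log2_fc"), "de_records")
  if (nrow(de_records) == 0L) stop("empty DE list")
  .check_columns(feature_hits, c("feature_id", "cytoband", "region_start",
                                 "region_stop", "direction"), "feature_hits")

  de_key <- .norm_id(de_records$feature_id)
  hit_key <- .norm_id(feature_hits$feature_id)
  idx <- which(hit_key %in% de_key)
  de_row <- match(hit_key[idx], de_key)

  records <- data.frame(
    feature_id = de_records$feature_id[de_row],
    log2_fc = de_records$log2_fc[de_row],
    de_direction = ifelse(de_records$log2_fc[de_row] >= 0, "up", "down"),
    cytoband = feature_hits$cytoband[idx],
    region_start = feature_hits$region_start[idx],
    region_stop = feature_hits$region_stop[idx],
    cna_direction = feature_hits$direction[idx],
    stringsAsFactors = FALSE)
  records$concordant <- classify_concordance(records$de_direction,
                                             records$cna_direction) == "concordant"
  records <- records[order(records$feature_id, records$region_start), ]
  rownames(records) <- NULL

  mapped <- unique(.norm_id(records$feature_id))
  concordant <- unique(.norm_id(records$feature_id[records$concordant]))
  n_de <- length(unique(de_key))
  summary <- list(
    n_de = n_de,
    n_mapped = length(mapped),
    pct_mapped = .round_half_up(100 * length(mapped) / n_de, 1),
    n_concordant = length(concordant),
    pct_concordant = if (length(mapped))
      .round_half_up(100 * length(concordant) / length(mapped), 1) else 0)
  list(records = records, summary = summary)
}

#' Consensus miRNA targets across three prediction tables
#'
#' A gene is a consensus target of a miRNA iff it appears, for that miRNA, in
#' at least `min_dbs` of the three tables. Duplicate (miRNA, gene) rows within
#' one table are deduplicated silently. Ids are matched in normalized form but
#' reported as given in the first table listing them.
#'
#' @param db1,db2,db3 data.frames with `mirna_id`, `gene_id`.
#' @param min_dbs Minimum supporting databases, 1-3 (default 2: "2-of-3").
#' @return Named list: miRNA id -> sorted character vector of consensus genes.
#' @export
consensus_targets <- function(db1, db2, db3, min_dbs = 2) {
  if (!min_dbs %in% 1:3) stop("min_dbs must be 1, 2 or 3")
  tables <- lapply(list(db1, db2, db3), function(t) {
    .check_columns(t, c("mirna_id", "gene_id"))
    t$mkey <- .norm_id(t$mirna_id)
    t$gkey <- .norm_id(t$gene_id)
    t[!duplicated(paste(t$mkey, t$gkey)), , drop = FALSE]
  })
  all_rows <- do.call(rbind, tables)
  if (nrow(all_rows) == 0L) return(stats::setNames(list(), character(0)))

  mirnas <- unique(all_rows$mkey)
  out <- lapply(stats::setNames(mirnas, mirnas), function(m) {
    per_db <- lapply(tables, function(t) t$gkey[t$mkey == m])
    genes <- unique(unlist(per_db))
    support <- vapply(genes, function(g)
      sum(vapply(per_db, function(s) g %in% s, logical(1))), integer(1))
    keep <- genes[support >= min_dbs]
    # report original spelling of the gene id (first occurrence)
    sort(all_rows$gene_id[match(keep, all_rows$gkey)])
  })
  # name the list by original miRNA spelling
  names(out) <- all_rows$mirna_id[match(mirnas, all_rows$mkey)]
  out
}

#' Intersect consensus target genes with CNA-resident genes
#'
#' Second integration approach: only consensus targets that lie inside a
#' recurrent copy-number region are kept; each gene reports the set of
#' miRNAs targeting it (multi-targeting ranking). Sorted by the number of
#' targeting miRNAs (descending), then gene id (ascending).
#'
#' @param consensus Named list from [consensus_targets()].
#' @param cna_genes data.frame with `feature_id` and `direction` for genes
#'   mapped onto recurrent regions (from [map_features_to_regions()] applied
#'   to gene annotations).
#' @return data.frame: `gene_id`, `n_mirnas`, `mirnas` (comma-joined),
#'   `cna_direction`.
#' @export
intersect_with_cna_genes <- function(consensus, cna_genes) {
  .check_columns(cna_genes, c("feature_id", "direction"), "cna_genes")
  empty <- .empty_df(list(gene_id = character(0), n_mirnas = integer(0),
                          mirnas = character(0), cna_direction = character(0)))
  if (length(consensus) == 0L || nrow(cna_genes) == 0L) return(empty)

  pairs <- do.call(rbind, lapply(names(consensus), function(m) {
    g <- consensus[[m]]
    if (length(g)) data.frame(mirna_id = m, gene_id = g, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) return(empty)

  cna_key <- .norm_id(cna_genes$feature_id)
  pairs <- pairs[.norm_id(pairs$gene_id) %in% cna_key, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)

  by_gene <- split(pairs$mirna_id, .norm_id(pairs$gene_id))
  genes <- names(by_gene)
  res <- data.frame(
    gene_id = cna_genes$feature_id[match(genes, cna_key)],
    n_mirnas = vapply(by_gene, function(m) length(unique(m)), integer(1)),
    mirnas = vapply(by_gene, function(m) paste(sort(unique(m)), collapse = ","),
                    character(1)),
    cna_direction = cna_genes$direction[match(genes, cna_key)],
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(-res$n_mirnas, res$gene_id), ]
  rownames(res) <- NULL
  res
}

#' Compare two differential-expression lists by identity and direction
#'
#' Ids are matched after normalization (case-folded, "hsa-" stripped);
#' `same_direction` are the common ids whose `log2_fc` signs agree.
#'
#' @param list_a,list_b data.frames with `feature_id`, `log2_fc`.
#' @return list: `common` (ids as spelled in `list_a`), `same_direction`,
#'   `n_common`, `n_same_direction`.
#' @export
compare_de_lists <- function(list_a, list_b) {
  .check_columns(list_a, c("feature_id", "log2_fc"), "list_a")
  .check_columns(list_b, c("feature_id", "log2_fc"), "list_b")
  ka <- .norm_id(list_a$feature_id)
  kb <- .norm_id(list_b$feature_id)
  common_key <- intersect(ka, kb)
  ia <- match(common_key, ka)
  ib <- match(common_key, kb)
  same <- sign(list_a$log2_fc[ia]) == sign(list_b$log2_fc[ib])
  list(common = list_a$feature_id[ia],
       same_direction = list_a$feature_id[ia][same],
       n_common = length(common_key),
       n_same_direction = sum(same))
}
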