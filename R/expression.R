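# Count normalization, differential expression and sample clustering.

#' Control-based normalization of a raw count matrix
#'
#' Three sequential per-sample steps, in the order of a standard
#' NanoString-style workflow:
#' 1. background subtraction: the sample's negative-control geometric mean is
#'    subtracted from every count, flooring at 1 so downstream logs are
#'    defined;
#' 2. positive-control normalization: each sample is scaled by
#'    (grand geometric mean of per-sample positive-control geometric means) /
#'    (this sample's positive-control geometric mean);
#' 3. content normalization: step 2 repeated with all endogenous features as
#'    the reference set.
#'
#' The grand mean across samples is geometric, which makes re-running steps
#' 2-3 an exact no-op (the scaling is a fixed point).
#'
#' @param counts Numeric matrix, features x samples, rownames = feature ids.
#' @param feature_class Character vector aligned with rows (values
#'   `endogenous`, `negative_control`, `positive_control`, `housekeeping`).
#' @return Normalized matrix with the same dimnames (all rows scaled).
#' @export
normalize_counts <- function(counts, feature_class) {
  counts <- as.matrix(counts)
  if (length(feature_class) != nrow(counts)) {
    stop("feature_class must align with the rows of counts")
  }
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0")
  neg <- counts[feature_class == "negative_control", , drop = FALSE]
  pos <- counts[feature_class == "positive_control", , drop = FALSE]
  if (nrow(neg) == 0L || nrow(pos) == 0L) {
    stop("normalization needs at least one negative and one positive control row")
  }

  # step 1: background subtraction, floored at 1
  bg <- apply(neg, 2, .geomean)
  x <- pmax(sweep(counts, 2, bg, "-"), 1)

  # steps 2-3: control and content scaling
  .scale_normalize(x, feature_class)
}

# Steps 2-3 of normalize_counts; a fixed point, so re-running it is a no-op.
.scale_normalize <- function(x, feature_class) {
  pg <- apply(x[feature_class == "positive_control", , drop = FALSE], 2, .geomean)
  if (any(pg == 0)) {
    stop("sample(s) with zero positive-control geometric mean: ",
         paste(colnames(x)[pg == 0], collapse = ", "))
  }
  x <- sweep(x, 2, .geomean(pg) / pg, "*")

  eg <- apply(x[feature_class == "endogenous", , drop = FALSE], 2, .geomean)
  if (any(eg == 0)) stop("sample(s) with zero endogenous geometric mean")
  sweep(x, 2, .geomean(eg) / eg, "*")
}

#' Two-group differential expression with BH-FDR
#'
#' Per endogenous feature: a two-sample t statistic on `log2(x + 1)` of the
#' normalized values; `log2_fc` is mean(case) - mean(control) on that scale;
#' BH adjustment is across all endogenous features. The significant subset is
#' `p < p_cutoff` AND `fdr < fdr_cutoff`. If both groups have zero variance
#' and equal means, p = 1 by convention (p = 0 with unequal means).
#'
#' @param normalized Normalized matrix from [normalize_counts()].
#' @param feature_class Character vector aligned with rows.
#' @param groups data.frame with `sample_id`, `group` (columns of `normalized`
#'   must all appear in `sample_id`).
#' @param case Group label treated as the case (numerator) group.
#' @param p_cutoff,fdr_cutoff Dual significance cutoffs (defaults 0.01, 0.05).
#' @param var_equal `TRUE` (default) for the pooled-variance Student t used in
#'   the array analysis; `FALSE` for Welch.
#' @return data.frame (one row per endogenous feature): `feature_id`,
#'   `log2_fc`, `p_value`, `fdr`, `direction` ("up"/"down"), `significant`.
#' @export
differential_expression <- function(normalized, feature_class, groups,
                                    case = "case", p_cutoff = 0.01,
                                    fdr_cutoff = 0.05, var_equal = TRUE) {
  .check_columns(groups, c("sample_id", "group"), "groups")
  samples <- colnames(normalized)
  if (!all(samples %in% groups$sample_id)) {
    stop("samples missing from the group table: ",
         paste(setdiff(samples, groups$sample_id), collapse = ", "))
  }
  grp <- groups$group[match(samples, groups$sample_id)]
  if (!case %in% grp) stop("case level '", case, "' not present in groups")
  if (length(unique(grp)) != 2L) stop("exactly two groups are required")
  a <- grp == case
  if (sum(a) < 2L || sum(!a) < 2L) stop("need >= 2 samples per group")

  x <- log2(normalized[feature_class == "endogenous", , drop = FALSE] + 1)
  n1 <- sum(a); n2 <- sum(!a)
  m1 <- rowMeans(x[, a, drop = FALSE]); m2 <- rowMeans(x[, !a, drop = FALSE])
  v1 <- apply(x[, a, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, !a, drop = FALSE], 1, stats::var)
  dm <- m1 - m2

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(dm))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(abs(dm / se), df = df, lower.tail = FALSE)
  degenerate <- se == 0 | !is.finite(se)
  p[degenerate] <- ifelse(dm[degenerate] == 0, 1, 0)

  fdr <- bh_fdr(p)
  res <- data.frame(feature_id = rownames(x), log2_fc = dm, p_value = p,
                    fdr = fdr,
                    direction = ifelse(dm >= 0, "up", "down"),
                    significant = p < p_cutoff & fdr < fdr_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement (a validated
#' front-end to `stats::p.adjust(method = "BH")`); output order matches input
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlation-based average-linkage clustering of samples
#'
#' Sample-sample distance is 1 - Pearson correlation computed on the
#' significant-feature submatrix (log2(x + 1) scale), agglomerated by
#' unweighted average linkage (UPGMA).
#'
#' @param normalized Normalized matrix from [normalize_counts()].
#' @param features Character vector of feature ids (rows) to cluster on;
#'   typically the significant DE subset. At least 2.
#' @param log_transform Apply `log2(x + 1)` first (default `TRUE`).
#' @return Object of class `sample_clustering`: list with `hclust` (the merge
#'   tree with heights), `order` (leaf order), `labels`, and `dist` (the full
#'   distance matrix).
#' @export
hierarchical_cluster <- function(normalized, features, log_transform = TRUE) {
  features <- intersect(features, rownames(normalized))
  if (length(features) < 2L) stop("need >= 2 features to cluster on")
  if (ncol(normalized) < 2L) stop("need >= 2 samples")
  x <- normalized[features, , drop = FALSE]
  if (log_transform) x <- log2(x + 1)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero variance across features for sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(x, method = "pearson"))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, order = hc$order, labels = hc$labels,
                 dist = as.matrix(d)),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("sample_clustering:", length(x$labels), "samples, average linkage on 1 - Pearson r\n")
  cat("leaf order:", paste(x$labels[x$order], collapse = " "), "\n")
  invisible(x)
}

#' Export a sample clustering as a Newick tree string
#'
#' @param clustering A `sample_clustering`.
#' @param path Optional file path; if given the tree is also written there.
#' @return Newick string, invisibly if `path` is given.
#' @export
cluster_newick <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "sample_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
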