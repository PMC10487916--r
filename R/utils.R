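# Internal helpers shared across modules.

# Geometric mean over strictly positive entries; 0 if none are positive.
.geomean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0L) return(0)
  exp(mean(log(x)))
}

# Round half away from zero (report convention for percentages, e.g. 7.4%).
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical miRNA/gene id form: case-folded, "hsa-" prefix stripped.
.norm_id <- function(x) tolower(sub("^hsa-", "", as.character(x), ignore.case = TRUE))

.check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Empty data.frame with a given column prototype (named list of zero-length vectors).
.empty_df <- function(proto) {
  as.data.frame(proto, stringsAsFactors = FALSE)
}
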