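#' Bundled reference tables from a published TNBC cohort
#'
#' Three small plain-text tables ship with the package for worked examples
#' and coordinate-convention checks:
#' * `recurrent_cytobands` — the most frequently altered cytobands of a
#'   24-case TNBC array-CGH cohort (chromosome, cytoband, 1-based inclusive
#'   start/stop, printed size, case count, direction, probe count). Stops
#'   printed only to three significant figures, and two rows whose printed
#'   size disagrees with `stop - start + 1`, are flagged
#'   `consistent = FALSE`.
#' * `cna_mirnas` — DE miRNAs mapped to those cytobands with their fold
#'   change, p, FDR and the copy-number direction of the hosting region.
#' * `tcga_comparison` — miRNAs differentially expressed both in that cohort
#'   and in a TCGA-BRCA Hispanic/Latina comparison, with the fold changes of
#'   each analysis.
#'
#' @param name Which table to load.
#' @return data.frame.
#' @examples
#' tab <- reference_table("recurrent_cytobands")
#' interval_size(tab[tab$consistent, ])
#' @export
reference_table <- function(name = c("recurrent_cytobands", "cna_mirnas",
                                     "tcga_comparison")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "mircna",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
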