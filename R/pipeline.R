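# End-to-end orchestration over the synthetic scenario (or user files).

#' Build a validated pipeline configuration
#'
#' All tunable thresholds of the pipeline in one place, with the defaults of
#' the analysis it implements: runs of >= 3 probes beyond +/-0.25 log2 for
#' CNA calls, recurrence frequency 0.19, DE at p < 0.01 and FDR < 0.05,
#' 2-of-3 target consensus, and Ct exclusion at 31 (reference) / 35 (target).
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults (see the source of
#'   `pipeline_config` for the full set).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # synthetic scenario
    seed = 1,
    n_chromosomes = 2, bands_per_chromosome = 8,
    n_genes = 400, n_mirnas = 200,
    n_cases = 24, segments_per_case = 3,
    amplitude = 0.5, probe_spacing = 1e4, noise_sd = 0.1,
    n_group_a = 18, n_group_b = 32,
    de_fraction = 0.1, effect = 2,
    targets_per_mirna = 30, db_agreement = 0.5,
    hazard_coef = 1.5, baseline_hazard = 0.02, censor_month = 60,
    # thresholds
    min_probes = 3, gain_threshold = 0.25, loss_threshold = -0.25,
    min_frequency = 0.19,
    p_cutoff = 0.01, fdr_cutoff = 0.05,
    min_dbs = 2,
    ref_ct_max = 31, target_ct_max = 35,
    # output
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$min_probes >= 1, cfg$gain_threshold > 0, cfg$loss_threshold < 0,
            cfg$min_frequency > 0, cfg$min_frequency <= 1,
            cfg$p_cutoff > 0, cfg$p_cutoff <= 1,
            cfg$fdr_cutoff > 0, cfg$fdr_cutoff <= 1,
            cfg$min_dbs %in% 1:3, cfg$de_fraction >= 0, cfg$de_fraction <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the integrated CNA/miRNA pipeline on a synthetic scenario
#'
#' Executes the full stage order: simulate -> CNA calling -> penetrance and
#' recurrent regions -> normalization and differential expression ->
#' integration (direction concordance, then 2-of-3 target consensus
#' intersected with CNA genes) -> validation statistics (ROC of the driver
#' miRNA and of the combined DE panel, clinical associations, Kaplan-Meier
#' with median split). All randomness is controlled by `config$seed`, fanned
#' out to per-stage substreams by fixed offsets, so a run is reproducible
#' bit-for-bit. When `config$out_dir` is set, per-stage TSVs and a MANIFEST
#' are written there.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `tnbc_report`: list with `config`, `truth`,
#'   `cna` (calls, penetrance, regions, mirna_hits, gene_hits), `de`,
#'   `clustering`, `integration`, `gene_hits`, `comparison-ready` DE table,
#'   `validation` (roc, combined_roc, associations, km) and `summary`
#'   (the headline counts).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  seed <- cfg$seed

  # --- simulate -------------------------------------------------------------
  genome <- generate_genome(cfg$n_chromosomes, cfg$bands_per_chromosome,
                            cfg$n_genes, cfg$n_mirnas, seed = seed)
  acgh <- generate_acgh_profiles(genome, n_cases = cfg$n_cases,
                                 segments_per_case = cfg$segments_per_case,
                                 amplitude = cfg$amplitude,
                                 probe_spacing = cfg$probe_spacing,
                                 noise_sd = cfg$noise_sd, seed = seed + 101)
  expr <- generate_expression(genome, n_group_a = cfg$n_group_a,
                              n_group_b = cfg$n_group_b,
                              de_fraction = cfg$de_fraction,
                              effect = cfg$effect, seed = seed + 202)

  # --- CNA calling ----------------------------------------------------------
  calls <- do.call(rbind, lapply(split(acgh$probes, acgh$probes$case_id),
                                 call_aberrations,
                                 min_probes = cfg$min_probes,
                                 gain_threshold = cfg$gain_threshold,
                                 loss_threshold = cfg$loss_threshold))
  rownames(calls) <- NULL
  penetrance <- aggregate_penetrance(calls, genome$cytobands, cfg$n_cases)
  regions <- select_recurrent_regions(penetrance, cfg$min_frequency)
  mirna_hits <- map_features_to_regions(genome$mirnas, regions, genome)
  gene_hits <- map_features_to_regions(genome$genes, regions, genome)

  # --- expression / DE ------------------------------------------------------
  normalized <- normalize_counts(expr$counts, expr$feature_class)
  de <- differential_expression(normalized, expr$feature_class, expr$groups,
                                p_cutoff = cfg$p_cutoff,
                                fdr_cutoff = cfg$fdr_cutoff)
  sig <- de[de$significant, , drop = FALSE]
  clustering <- if (nrow(sig) >= 2L)
    hierarchical_cluster(normalized, sig$feature_id) else NULL

  # --- integration ----------------------------------------------------------
  integration <- if (nrow(sig) > 0L)
    integrate_cna_mirna(sig, mirna_hits) else NULL
  concordant_mirnas <- if (!is.null(integration))
    unique(integration$records$feature_id[integration$records$concordant])
    else character(0)

  gene_panel <- NULL
  if (length(concordant_mirnas) > 0L) {
    dbs <- generate_target_dbs(genome, concordant_mirnas,
                               targets_per_mirna = cfg$targets_per_mirna,
                               db_agreement = cfg$db_agreement,
                               seed = seed + 303)
    consensus <- consensus_targets(dbs$db1, dbs$db2, dbs$db3,
                                   min_dbs = cfg$min_dbs)
    gene_panel <- intersect_with_cna_genes(
      consensus,
      gene_hits[, c("feature_id", "direction")])
  }

  # --- validation -----------------------------------------------------------
  lx <- log2(normalized[expr$feature_class == "endogenous", , drop = FALSE] + 1)
  driver <- if (nrow(expr$truth) > 0L) expr$truth$feature_id[1] else rownames(lx)[1]
  grp <- expr$groups$group[match(colnames(lx), expr$groups$sample_id)]
  roc <- roc_auc(lx[driver, ], grp, positive = "case",
                 n_boot = 500, seed = seed + 404)

  combined_roc <- NULL
  panel <- utils::head(sig$feature_id, 4)
  if (length(panel) >= 2L) {
    combined <- combine_scores(t(lx[panel, , drop = FALSE]))
    combined_roc <- roc_auc(combined, grp, positive = "case",
                            n_boot = 500, seed = seed + 505)
  }

  driver_case <- as.numeric(scale(lx[driver, grp == "case"]))
  clin <- generate_clinical(n_patients = cfg$n_group_a,
                            driver_expression = driver_case,
                            hazard_coef = cfg$hazard_coef,
                            baseline_hazard = cfg$baseline_hazard,
                            censor_month = cfg$censor_month,
                            seed = seed + 606)
  assoc <- lapply(c("tumor_size", "recurrence", "p53"), function(v) {
    tryCatch(associate_clinical(driver_case, clin$clinical, v),
             error = function(e) list(variable = v, p_value = NA_real_,
                                      error = conditionMessage(e)))
  })
  names(assoc) <- vapply(assoc, `[[`, character(1), "variable")
  km <- km_logrank(clin$clinical$follow_up, clin$clinical$status,
                   median_split(driver_case))

  summary <- list(
    n_cases = cfg$n_cases,
    n_cna_calls = nrow(calls),
    mean_calls_per_case = .round_half_up(nrow(calls) / cfg$n_cases, 1),
    n_recurrent_regions = nrow(regions),
    n_de = nrow(sig),
    n_mapped = if (!is.null(integration)) integration$summary$n_mapped else 0L,
    pct_mapped = if (!is.null(integration)) integration$summary$pct_mapped else 0,
    n_concordant = if (!is.null(integration)) integration$summary$n_concordant else 0L,
    pct_concordant = if (!is.null(integration)) integration$summary$pct_concordant else 0,
    n_gene_hits = if (!is.null(gene_panel)) nrow(gene_panel) else 0L,
    driver = driver,
    driver_auc = roc$auc,
    combined_auc = if (!is.null(combined_roc)) combined_roc$auc else NA_real_,
    logrank_p = km$p_value)

  report <- structure(list(
    config = cfg,
    genome = genome,
    truth = list(segments = acgh$truth, de = expr$truth,
                 survival = clin$truth),
    cna = list(calls = calls, penetrance = penetrance, regions = regions,
               mirna_hits = mirna_hits, gene_hits = gene_hits),
    de = de, clustering = clustering,
    integration = integration, gene_panel = gene_panel,
    validation = list(roc = roc, combined_roc = combined_roc,
                      associations = assoc, km = km,
                      clinical = clin$clinical),
    summary = summary), class = "tnbc_report")

  if (!is.null(cfg$out_dir)) .write_report(report, cfg$out_dir)
  report
}

#' @export
print.tnbc_report <- function(x, ...) {
  s <- x$summary
  cat("Integrated CNA/miRNA pipeline report\n")
  cat(sprintf("  CNA: %d calls over %d cases (mean %.1f/case), %d recurrent regions\n",
              s$n_cna_calls, s$n_cases, s$mean_calls_per_case, s$n_recurrent_regions))
  cat(sprintf("  DE: %d significant miRNAs; %d mapped to recurrent regions (%.1f%%), %d concordant (%.1f%%)\n",
              s$n_de, s$n_mapped, s$pct_mapped, s$n_concordant, s$pct_concordant))
  cat(sprintf("  Targets: %d consensus genes inside CNA regions\n", s$n_gene_hits))
  cat(sprintf("  Validation: driver %s AUC %.3f; combined AUC %s; log-rank p = %.4g\n",
              s$driver, s$driver_auc,
              ifelse(is.na(s$combined_auc), "NA", sprintf("%.3f", s$combined_auc)),
              s$logrank_p))
  invisible(x)
}

# Per-stage TSV outputs plus a MANIFEST listing them.
.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    files <<- c(files, name)
  }
  put(report$cna$calls, "cna_calls.tsv")
  put(report$cna$penetrance, "penetrance.tsv")
  put(report$cna$regions, "recurrent_regions.tsv")
  put(report$de, "differential_expression.tsv")
  if (!is.null(report$integration)) put(report$integration$records, "integration.tsv")
  if (!is.null(report$gene_panel)) put(report$gene_panel, "gene_panel.tsv")
  put(report$validation$roc$curve, "roc_curve.tsv")
  put(report$validation$clinical, "clinical.tsv")
  if (!is.null(report$clustering)) {
    cluster_newick(report$clustering, file.path(out_dir, "dendrogram.nwk"))
    files <- c(files, "dendrogram.nwk")
  }
  s <- report$summary
  put(data.frame(key = names(s), value = vapply(s, function(v)
    paste(format(v), collapse = ","), character(1))), "summary.tsv")
  writeLines(c("complete", files), file.path(out_dir, "MANIFEST"))
  invisible(out_dir)
}
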