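# Synthetic-data generators.
#
# Every pipeline input can be generated with known implanted truth: a desk-scale
# genome model, step-shaped CNA segments in Gaussian probe noise, log-normal
# expression counts with group mean-shifts on a chosen DE fraction, partially
# overlapping target-prediction tables, and exponential survival times whose
# hazard depends on a chosen driver miRNA. Truth objects are returned alongside
# the data and are never consumed by the analysis stages themselves.

#' Generate a desk-scale genome model
#'
#' Chromosomes of equal length are partitioned into equal-width cytobands
#' (first half "p", second half "q", numbered outward-in reading order), and
#' gene/miRNA annotations are placed uniformly at random within chromosomes.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param bands_per_chromosome Cytobands per chromosome (>= 1).
#' @param n_genes,n_mirnas Number of gene / miRNA annotations (>= 0).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param chrom_length Chromosome length in bp (default 10 Mb).
#' @param gene_width,mirna_width Feature widths in bp.
#' @return An object of class `genome_model`: a list with data.frames
#'   `chromosomes` (chrom, length), `cytobands` (chrom, band, cytoband, start,
#'   stop), `genes` and `mirnas` (feature_id, chrom, start, stop).
#' @export
generate_genome <- function(n_chromosomes, bands_per_chromosome, n_genes, n_mirnas,
                            seed, chrom_length = 1e7,
                            gene_width = 5000, mirna_width = 100) {
  if (n_chromosomes < 1 || bands_per_chromosome < 1) {
    stop("n_chromosomes and bands_per_chromosome must be >= 1")
  }
  if (n_genes < 0 || n_mirnas < 0) stop("feature counts must be >= 0")
  set.seed(seed)

  chroms <- paste0("chr", seq_len(n_chromosomes))
  chromosomes <- data.frame(chrom = chroms, length = rep(chrom_length, n_chromosomes),
                            stringsAsFactors = FALSE)

  bands <- do.call(rbind, lapply(seq_len(n_chromosomes), function(i) {
    k <- bands_per_chromosome
    bounds <- round(seq(0, chrom_length, length.out = k + 1))
    n_p <- ceiling(k / 2)
    band <- c(if (n_p > 0) paste0("p", rev(seq_len(n_p))),
              if (k - n_p > 0) paste0("q", seq_len(k - n_p)))
    data.frame(chrom = chroms[i], band = band,
               cytoband = paste0(i, band),
               start = bounds[-(k + 1)] + 1, stop = bounds[-1],
               stringsAsFactors = FALSE)
  }))
  rownames(bands) <- NULL

  place <- function(n, prefix, width, fmt = "%s%03d") {
    if (n == 0L) {
      return(.empty_df(list(feature_id = character(0), chrom = character(0),
                            start = numeric(0), stop = numeric(0))))
    }
    chrom <- sample(chroms, n, replace = TRUE)
    start <- floor(stats::runif(n, min = 1, max = chrom_length - width + 1))
    data.frame(feature_id = sprintf(fmt, prefix, seq_len(n)), chrom = chrom,
               start = start, stop = start + width - 1, stringsAsFactors = FALSE)
  }

  out <- list(chromosomes = chromosomes, cytobands = bands,
              genes = place(n_genes, "GENE", gene_width),
              mirnas = place(n_mirnas, "miR-", mirna_width))
  class(out) <- "genome_model"
  out
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$cytobands), "cytobands,",
      nrow(x$genes), "genes,", nrow(x$mirnas), "miRNAs\n")
  invisible(x)
}

#' Simulate per-case array-CGH probe tracks with implanted CNA segments
#'
#' Probes are laid at fixed spacing along each chromosome. Within an implanted
#' segment the log2 ratio is Normal(+/- amplitude, noise_sd) (sign by
#' direction); outside it is Normal(0, noise_sd). Implanted segments are
#' non-overlapping runs of consecutive probes whose lengths are drawn uniformly
#' from `seg_probes` and always cover at least 3 probes.
#'
#' @param genome A `genome_model`.
#' @param n_cases Number of cases.
#' @param segments_per_case Implanted segments per case.
#' @param amplitude Absolute implanted log2-ratio shift (>= 0).
#' @param probe_spacing Probe spacing in bp (>= 1).
#' @param noise_sd Gaussian probe noise SD in log2 units (>= 0).
#' @param seed Integer seed.
#' @param seg_probes Integer range (min, max) of probes per implanted segment;
#'   the minimum must be >= 3.
#' @param probe_width Probe footprint in bp.
#' @return list with `probes` (data.frame case_id, chrom, start, stop,
#'   log2_ratio) and `truth` (data.frame case_id, chrom, start, stop,
#'   direction, amplitude, n_probes).
#' @export
generate_acgh_profiles <- function(genome, n_cases, segments_per_case,
                                   amplitude = 0.5, probe_spacing = 1e4,
                                   noise_sd = 0.1, seed = 1,
                                   seg_probes = c(8L, 25L), probe_width = 60) {
  stopifnot(inherits(genome, "genome_model"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (probe_spacing < 1) stop("probe_spacing must be >= 1")
  seg_probes <- as.integer(seg_probes)
  if (length(seg_probes) != 2L || seg_probes[1] > seg_probes[2]) {
    stop("seg_probes must be an increasing (min, max) pair")
  }
  if (segments_per_case > 0 && seg_probes[1] < 3L) {
    stop("implanted segments must cover at least 3 probes (seg_probes[1] >= 3)")
  }
  set.seed(seed)

  # one probe grid shared by all cases
  grid <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    len <- genome$chromosomes$length[i]
    pos <- seq(1, len - probe_width + 1, by = probe_spacing)
    data.frame(chrom = genome$chromosomes$chrom[i], start = pos,
               stop = pos + probe_width - 1, stringsAsFactors = FALSE)
  }))
  n_probes <- nrow(grid)
  chrom_sizes <- table(grid$chrom)[unique(grid$chrom)]
  if (segments_per_case > 0 && any(chrom_sizes < seg_probes[1])) {
    stop("a chromosome is too short to fit an implanted segment of >= ",
         seg_probes[1], " probes")
  }

  cases <- sprintf("case%02d", seq_len(n_cases))
  probes_list <- vector("list", n_cases)
  truth_list <- vector("list", n_cases)
  chrom_index <- split(seq_len(n_probes), grid$chrom)

  for (ci in seq_len(n_cases)) {
    ratio <- stats::rnorm(n_probes, mean = 0, sd = noise_sd)
    truth_rows <- list()
    used <- rep(FALSE, n_probes)  # probes already inside an implant
    k <- 0L
    guard <- 0L
    while (k < segments_per_case && guard < 1000L) {
      guard <- guard + 1L
      chrom <- sample(names(chrom_index), 1L)
      idx <- chrom_index[[chrom]]
      hi <- min(seg_probes[2], length(idx))
      len <- if (seg_probes[1] >= hi) hi else sample(seg_probes[1]:hi, 1L)
      first <- sample(seq_len(length(idx) - len + 1L), 1L)
      run <- idx[first:(first + len - 1L)]
      # pad by one probe on each side so distinct implants never fuse into one run
      pad <- idx[max(1L, first - 1L):min(length(idx), first + len)]
      if (any(used[pad])) next
      used[pad] <- TRUE
      direction <- sample(c("gain", "loss"), 1L)
      shift <- if (direction == "gain") amplitude else -amplitude
      ratio[run] <- stats::rnorm(len, mean = shift, sd = noise_sd)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        case_id = cases[ci], chrom = chrom,
        start = grid$start[run[1]], stop = grid$stop[run[len]],
        direction = direction, amplitude = shift, n_probes = len,
        stringsAsFactors = FALSE)
      k <- k + 1L
    }
    if (k < segments_per_case) {
      stop("could not place ", segments_per_case, " non-overlapping segments")
    }
    probes_list[[ci]] <- data.frame(case_id = cases[ci], grid,
                                    log2_ratio = ratio, stringsAsFactors = FALSE)
    truth_list[[ci]] <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  }

  truth <- do.call(rbind, truth_list)
  if (is.null(truth)) {
    truth <- .empty_df(list(case_id = character(0), chrom = character(0),
                            start = numeric(0), stop = numeric(0),
                            direction = character(0), amplitude = numeric(0),
                            n_probes = integer(0)))
  }
  rownames(truth) <- NULL
  list(probes = do.call(rbind, probes_list), truth = truth)
}

#' Simulate a NanoString-style raw count matrix with control rows
#'
#' Endogenous counts are log-normal: per-feature baseline on the log2 scale
#' plus Gaussian sample noise, with the group-A (case) mean shifted by
#' `effect` log2 units (random sign per feature) for a randomly chosen DE
#' fraction of features. Each sample carries a global library scale factor;
#' negative-control rows are low-level Poisson noise and positive-control rows
#' are a sample-scaled constant ladder, so the control-based normalization has
#' real work to do.
#'
#' @param genome A `genome_model`; endogenous features are its miRNAs.
#' @param n_group_a Samples in group A ("case", TNBC); >= 2.
#' @param n_group_b Samples in group B ("control"); >= 2.
#' @param de_fraction Fraction of endogenous features given a mean shift, in
#'   \[0, 1\].
#' @param effect Absolute log2 mean shift for DE features (sign randomized).
#' @param n_neg_controls,n_pos_controls Number of control rows.
#' @param seed Integer seed.
#' @param base_log2_mean,base_log2_sd Mean/SD of per-feature log2 baselines.
#' @param sample_sd Per-sample Gaussian noise SD on the log2 scale.
#' @param lib_scale_sd SD (log2 scale) of the per-sample library size factor.
#' @return list with `counts` (matrix, features x samples), `feature_class`
#'   (named vector), `groups` (data.frame sample_id, group) and `truth`
#'   (data.frame feature_id, effect for the implanted DE set).
#' @export
generate_expression <- function(genome, n_group_a = 18, n_group_b = 32,
                                de_fraction = 0.1, effect = 2,
                                n_neg_controls = 6, n_pos_controls = 6,
                                seed = 1, base_log2_mean = 7, base_log2_sd = 1,
                                sample_sd = 1, lib_scale_sd = 0.25) {
  stopifnot(inherits(genome, "genome_model"))
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  if (n_group_a < 2 || n_group_b < 2) stop("group sizes must be >= 2")
  if (nrow(genome$mirnas) < 1) stop("genome has no miRNA annotations")
  set.seed(seed)

  features <- genome$mirnas$feature_id
  n_feat <- length(features)
  n_samp <- n_group_a + n_group_b
  samples <- sprintf("S%02d", seq_len(n_samp))
  group <- rep(c("case", "control"), c(n_group_a, n_group_b))

  n_de <- round(de_fraction * n_feat)
  de_idx <- if (n_de > 0) sort(sample.int(n_feat, n_de)) else integer(0)
  effects <- numeric(n_feat)
  if (n_de > 0) effects[de_idx] <- effect * sample(c(-1, 1), n_de, replace = TRUE)

  baseline <- stats::rnorm(n_feat, base_log2_mean, base_log2_sd)
  log2_mu <- outer(baseline, rep(1, n_samp)) +
    outer(effects, as.numeric(group == "case"))
  log2_val <- log2_mu + matrix(stats::rnorm(n_feat * n_samp, 0, sample_sd),
                               n_feat, n_samp)
  lib_scale <- 2^stats::rnorm(n_samp, 0, lib_scale_sd)
  endo <- round(2^log2_val %*% diag(lib_scale))

  neg <- matrix(stats::rpois(n_neg_controls * n_samp, 4), n_neg_controls, n_samp)
  ladder <- 2^seq(13, by = -2, length.out = max(n_pos_controls, 1))[seq_len(n_pos_controls)]
  pos <- round(outer(ladder, lib_scale))

  counts <- rbind(endo, neg, pos)
  ids <- c(features,
           if (n_neg_controls) sprintf("NEG_%02d", seq_len(n_neg_controls)),
           if (n_pos_controls) sprintf("POS_%02d", seq_len(n_pos_controls)))
  rownames(counts) <- ids
  colnames(counts) <- samples
  feature_class <- stats::setNames(
    c(rep("endogenous", n_feat),
      rep("negative_control", n_neg_controls),
      rep("positive_control", n_pos_controls)), ids)

  truth <- data.frame(feature_id = features[de_idx], effect = effects[de_idx],
                      stringsAsFactors = FALSE)
  list(counts = counts, feature_class = feature_class,
       groups = data.frame(sample_id = samples, group = group,
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate three partially overlapping miRNA target-prediction tables
#'
#' Each miRNA receives `targets_per_mirna` candidate genes. With probability
#' `db_agreement` a gene is "shared" (listed by all three databases); otherwise
#' it is private to one database chosen at random. The returned truth consensus
#' is computed by exhaustive 2-of-3 membership counting over the tables
#' actually emitted, never from the assignment shortcut.
#'
#' @param genome A `genome_model` supplying the gene universe.
#' @param mirnas Character vector of miRNA ids (must exist in the genome).
#' @param targets_per_mirna Candidate target genes per miRNA.
#' @param db_agreement Probability a candidate is shared by all three tables,
#'   in \[0, 1\].
#' @param seed Integer seed.
#' @return list with `db1`, `db2`, `db3` (data.frames mirna_id, gene_id) and
#'   `truth` (named list: miRNA id -> character vector of 2-of-3 consensus
#'   genes).
#' @export
generate_target_dbs <- function(genome, mirnas, targets_per_mirna = 30,
                                db_agreement = 0.5, seed = 1) {
  stopifnot(inherits(genome, "genome_model"))
  if (db_agreement < 0 || db_agreement > 1) stop("db_agreement must be in [0, 1]")
  unknown <- setdiff(mirnas, genome$mirnas$feature_id)
  if (length(unknown)) {
    stop("unknown miRNA id(s): ", paste(unknown, collapse = ", "))
  }
  genes <- genome$genes$feature_id
  if (length(genes) < targets_per_mirna) {
    stop("genome has fewer genes than targets_per_mirna")
  }
  set.seed(seed)

  dbs <- list(db1 = list(), db2 = list(), db3 = list())
  for (m in mirnas) {
    cand <- sample(genes, targets_per_mirna)
    shared <- stats::runif(targets_per_mirna) < db_agreement
    home <- sample.int(3L, targets_per_mirna, replace = TRUE)  # used when private
    for (d in 1:3) {
      sel <- shared | home == d
      if (any(sel)) {
        dbs[[d]][[m]] <- data.frame(mirna_id = m, gene_id = cand[sel],
                                    stringsAsFactors = FALSE)
      }
    }
  }
  tables <- lapply(dbs, function(d) {
    if (length(d)) do.call(rbind, unname(d))
    else .empty_df(list(mirna_id = character(0), gene_id = character(0)))
  })

  # truth by exhaustive 2-of-3 counting over the emitted tables
  truth <- lapply(stats::setNames(mirnas, mirnas), function(m) {
    per_db <- lapply(tables, function(t) unique(t$gene_id[t$mirna_id == m]))
    all_genes <- unique(unlist(per_db))
    n_dbs <- vapply(all_genes, function(g)
      sum(vapply(per_db, function(s) g %in% s, logical(1))), integer(1))
    sort(all_genes[n_dbs >= 2L])
  })
  c(tables, list(truth = truth))
}

#' Simulate a clinical table with expression-dependent survival
#'
#' Event times are exponential with per-patient rate
#' `baseline_hazard * exp(hazard_coef * driver_expression)` (log-hazard linear
#' in the driver miRNA's expression), administratively censored at
#' `censor_month`. All other clinical covariates are drawn independently of
#' survival, at ranges typical of a TNBC cohort.
#'
#' @param n_patients Number of patients.
#' @param driver_expression Numeric vector (length `n_patients`) of the driver
#'   miRNA's expression (any scale; z-scores recommended).
#' @param hazard_coef Per-unit log-hazard coefficient of the driver expression.
#' @param baseline_hazard Baseline event rate in events/month (> 0).
#' @param censor_month Administrative censoring time in months (>= 0).
#' @param seed Integer seed.
#' @return list with `clinical` (data.frame: patient_id, age, tumor_size,
#'   grade, stage, ki67, p53, recurrence, distant_metastasis, status, bmi,
#'   comorbidity, hypertension, follow_up) and `truth` (list with
#'   baseline_hazard, hazard_coef).
#' @export
generate_clinical <- function(n_patients, driver_expression, hazard_coef = 0,
                              baseline_hazard = 0.02, censor_month = 60, seed = 1) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_month < 0) stop("censor_month must be >= 0")
  if (length(driver_expression) != n_patients) {
    stop("driver_expression must have length n_patients")
  }
  set.seed(seed)

  rate <- baseline_hazard * exp(hazard_coef * driver_expression)
  event_time <- stats::rexp(n_patients, rate = rate)
  status <- ifelse(event_time <= censor_month, "deceased", "alive")
  follow_up <- pmin(event_time, censor_month)

  clinical <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    age = round(stats::rnorm(n_patients, 55.3, 10.6), 1),
    tumor_size = round(pmax(0.2, stats::rnorm(n_patients, 1.85, 1.25)), 2),
    grade = sample(c(2L, 3L), n_patients, replace = TRUE, prob = c(0.3, 0.7)),
    stage = sample(c("T1/T2", "T3/T4"), n_patients, replace = TRUE, prob = c(0.7, 0.3)),
    ki67 = round(stats::runif(n_patients, 0, 100), 1),
    p53 = round(stats::runif(n_patients, 0, 100), 1),
    recurrence = stats::runif(n_patients) < 0.3,
    distant_metastasis = stats::runif(n_patients) < 0.3,
    status = status,
    bmi = round(stats::rnorm(n_patients, 29.4, 6.7), 1),
    comorbidity = stats::runif(n_patients) < 0.7,
    hypertension = stats::runif(n_patients) < 0.4,
    follow_up = follow_up,
    stringsAsFactors = FALSE)

  list(clinical = clinical,
       truth = list(baseline_hazard = baseline_hazard, hazard_coef = hazard_coef))
}
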