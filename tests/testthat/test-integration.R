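# Concordance classification, CNA-DE joins, target consensus, list comparison.

test_that("concordance rule and its flip symmetry", {
  expect_equal(classify_concordance("up", "gain"), "concordant")
  expect_equal(classify_concordance("down", "loss"), "concordant")
  expect_equal(classify_concordance("up", "loss"), "discordant")
  expect_equal(classify_concordance("down", "gain"), "discordant")
  # simultaneous flip of both directions preserves the verdict
  de <- c("up", "up", "down", "down")
  cna <- c("gain", "loss", "gain", "loss")
  flip_de <- ifelse(de == "up", "down", "up")
  flip_cna <- ifelse(cna == "gain", "loss", "gain")
  expect_equal(classify_concordance(de, cna),
               classify_concordance(flip_de, flip_cna))
  expect_error(classify_concordance("sideways", "gain"), "de_direction")
  expect_error(classify_concordance("up", "neutral"), "cna_direction")
})

test_that("the bundled CNA-mapped miRNA table is fully concordant", {
  tab <- reference_table("cna_mirnas")
  verdict <- classify_concordance(ifelse(tab$log2_fc >= 0, "up", "down"), tab$cna)
  expect_equal(nrow(tab), 15)
  expect_true(all(verdict == "concordant"))
  expect_equal(sum(tab$log2_fc > 0 & tab$cna == "gain"), 12)
  expect_equal(sum(tab$log2_fc < 0 & tab$cna == "loss"), 3)
})

test_that("integration join matches an exhaustive cross-join oracle", {
  de <- data.frame(feature_id = c("hsa-miR-1", "miR-2", "miR-3", "miR-4"),
                   log2_fc = c(2.0, -1.5, 0.7, -3.0), stringsAsFactors = FALSE)
  hits <- data.frame(
    feature_id = c("miR-1", "miR-1", "miR-2", "miR-9"),
    cytoband = c("1q1", "2p1", "1p1", "1q1"),
    region_start = c(100, 5000, 10, 100),
    region_stop = c(900, 6000, 90, 900),
    direction = c("gain", "loss", "loss", "gain"),
    stringsAsFactors = FALSE)

  res <- integrate_cna_mirna(de, hits)
  # miR-1 maps to two regions (two records, counted once), miR-2 to one
  expect_equal(nrow(res$records), 3)
  expect_equal(res$summary$n_mapped, 2)
  expect_equal(res$summary$n_de, 4)
  expect_equal(res$summary$pct_mapped, 50.0)
  # miR-1 up/gain concordant on one of two regions; miR-2 down/loss concordant
  expect_equal(res$summary$n_concordant, 2)
  expect_equal(sum(res$records$concordant),
               sum(classify_concordance(res$records$de_direction,
                                        res$records$cna_direction) == "concordant"))

  # no overlap at all
  none <- integrate_cna_mirna(data.frame(feature_id = "miR-8", log2_fc = 1),
                              hits[hits$feature_id == "miR-9", ])
  expect_equal(none$summary$n_mapped, 0)
  expect_equal(nrow(none$records), 0)
  expect_error(integrate_cna_mirna(de[0, ], hits), "empty DE")
})

test_that("synthetic end-to-end concordant set equals a brute-force check", {
  genome <- generate_genome(2, 6, 0, 60, seed = 51, chrom_length = 5e6)
  sim <- generate_acgh_profiles(genome, n_cases = 12, segments_per_case = 3,
                                amplitude = 0.6, probe_spacing = 1e4,
                                noise_sd = 0.05, seed = 52)
  calls <- do.call(rbind, lapply(split(sim$probes, sim$probes$case_id),
                                 call_aberrations))
  pen <- aggregate_penetrance(calls, genome$cytobands, 12)
  regions <- select_recurrent_regions(pen, 0.19)
  hits <- map_features_to_regions(genome$mirnas, regions)

  set.seed(53)
  de <- data.frame(feature_id = genome$mirnas$feature_id,
                   log2_fc = rnorm(60), stringsAsFactors = FALSE)
  res <- integrate_cna_mirna(de, hits)

  # oracle: double loop over (miRNA, region)
  mapped <- character(0); concordant <- character(0)
  for (i in seq_len(nrow(genome$mirnas))) {
    f <- genome$mirnas[i, ]
    for (r in seq_len(nrow(regions))) {
      rg <- regions[r, ]
      if (f$chrom == rg$chrom && f$start <= rg$stop && rg$start <= f$stop) {
        mapped <- union(mapped, f$feature_id)
        dd <- if (de$log2_fc[de$feature_id == f$feature_id] >= 0) "up" else "down"
        if ((dd == "up" && rg$direction == "gain") ||
            (dd == "down" && rg$direction == "loss")) {
          concordant <- union(concordant, f$feature_id)
        }
      }
    }
  }
  expect_equal(res$summary$n_mapped, length(mapped))
  expect_equal(res$summary$n_concordant, length(concordant))
  expect_setequal(unique(res$records$feature_id), mapped)
  expect_setequal(unique(res$records$feature_id[res$records$concordant]), concordant)
})

test_that("consensus targets: membership counting, monotonicity, dedup", {
  db1 <- data.frame(mirna_id = c("m1", "m1", "m1", "m2"),
                    gene_id = c("A", "B", "B", "C"))  # duplicate row B
  db2 <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("B", "C"))
  db3 <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("C", "D"))

  cons <- consensus_targets(db1, db2, db3)
  expect_equal(cons$m1, "B")          # in 2 tables; A and C in only 1 each
  expect_equal(cons$m2, "C")
  expect_error(consensus_targets(db1, db2, db3, min_dbs = 4), "min_dbs")

  # min_dbs = 1 is the union, min_dbs = 3 the triple intersection, monotone
  u <- consensus_targets(db1, db2, db3, min_dbs = 1)
  i3 <- consensus_targets(db1, db2, db3, min_dbs = 3)
  expect_setequal(u$m1, c("A", "B", "C"))
  expect_equal(length(i3$m1), 0)
  for (m in names(u)) {
    expect_true(all(i3[[m]] %in% cons[[m]]))
    expect_true(all(cons[[m]] %in% u[[m]]))
  }

  # randomized tables against exhaustive per-pair counting
  set.seed(61)
  mk <- function() {
    n <- 40
    data.frame(mirna_id = sample(paste0("m", 1:5), n, replace = TRUE),
               gene_id = sample(paste0("G", 1:15), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  t1 <- mk(); t2 <- mk(); t3 <- mk()
  cons <- consensus_targets(t1, t2, t3)
  for (m in paste0("m", 1:5)) {
    for (g in paste0("G", 1:15)) {
      support <- sum(vapply(list(t1, t2, t3), function(t)
        any(t$mirna_id == m & t$gene_id == g), logical(1)))
      expect_equal(g %in% cons[[m]], support >= 2,
                   info = paste(m, g))
    }
  }
})

test_that("CNA-gene intersection ranks genes by miRNA multiplicity", {
  consensus <- list(m1 = c("A", "B"), m2 = c("B", "C"), m3 = c("B", "Z"))
  cna_genes <- data.frame(feature_id = c("A", "B", "C"),
                          direction = c("gain", "gain", "loss"),
                          stringsAsFactors = FALSE)
  hits <- intersect_with_cna_genes(consensus, cna_genes)
  expect_equal(hits$gene_id, c("B", "A", "C"))  # B targeted by 3, then ties by id
  expect_equal(hits$n_mirnas, c(3L, 1L, 1L))
  expect_equal(hits$cna_direction, c("gain", "gain", "loss"))
  expect_equal(hits$mirnas[1], "m1,m2,m3")

  # nothing in CNA regions
  expect_equal(nrow(intersect_with_cna_genes(list(m1 = "Q"), cna_genes)), 0)

  # brute-force double loop on a random instance
  set.seed(67)
  consensus <- lapply(setNames(paste0("m", 1:6), paste0("m", 1:6)), function(m)
    sample(paste0("G", 1:20), 8))
  cna_genes <- data.frame(feature_id = paste0("G", sample(20, 10)),
                          direction = sample(c("gain", "loss"), 10, replace = TRUE),
                          stringsAsFactors = FALSE)
  hits <- intersect_with_cna_genes(consensus, cna_genes)
  for (g in cna_genes$feature_id) {
    targeting <- names(consensus)[vapply(consensus, function(s) g %in% s, logical(1))]
    if (length(targeting)) {
      row <- hits[hits$gene_id == g, ]
      expect_equal(row$n_mirnas, length(targeting))
      expect_setequal(strsplit(row$mirnas, ",")[[1]], targeting)
    } else {
      expect_false(g %in% hits$gene_id)
    }
  }
  expect_true(all(diff(hits$n_mirnas) <= 0))
})

test_that("DE-list comparison counts shared ids and direction agreement", {
  a <- data.frame(feature_id = c("hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
                  log2_fc = c(2, -1, 0.5))
  b <- data.frame(feature_id = c("miR-2", "miR-3", "miR-9"),
                  log2_fc = c(-0.5, -2, 1))
  cmp <- compare_de_lists(a, b)
  expect_equal(cmp$n_common, 2)
  expect_equal(cmp$n_same_direction, 1)
  expect_equal(cmp$same_direction, "hsa-miR-2")

  disjoint <- compare_de_lists(a, data.frame(feature_id = "miR-7", log2_fc = 1))
  expect_equal(disjoint$n_common, 0)
  expect_equal(length(disjoint$same_direction), 0)

  # random signed lists vs an exhaustive pairwise check
  set.seed(71)
  ids <- paste0("miR-", 1:30)
  la <- data.frame(feature_id = sample(ids, 20), log2_fc = rnorm(20))
  lb <- data.frame(feature_id = sample(ids, 20), log2_fc = rnorm(20))
  cmp <- compare_de_lists(la, lb)
  common <- 0; same <- 0
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(lb))) {
    if (la$feature_id[i] == lb$feature_id[j]) {
      common <- common + 1
      if (sign(la$log2_fc[i]) == sign(lb$log2_fc[j])) same <- same + 1
    }
  }
  expect_equal(cmp$n_common, common)
  expect_equal(cmp$n_same_direction, same)
})

test_that("the bundled cross-study comparison has 23 direction-concordant miRNAs", {
  tab <- reference_table("tcga_comparison")
  cmp <- compare_de_lists(
    data.frame(feature_id = tab$feature_id, log2_fc = tab$fc_study),
    data.frame(feature_id = tab$feature_id, log2_fc = tab$fc_tcga))
  expect_equal(cmp$n_common, 23)
  expect_equal(cmp$n_same_direction, 23)
})
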