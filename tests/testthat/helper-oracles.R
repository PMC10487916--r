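# Independent brute-force oracles used across test files. These deliberately
# re-derive results from first principles (exhaustive enumeration, definitional
# formulas) and never call the package functions they check.

# Every maximal run of >= min_probes consecutive probes all beyond a threshold,
# found by exhaustive window enumeration over one chromosome's ratio vector.
oracle_runs <- function(ratios, min_probes = 3, gain_t = 0.25, loss_t = -0.25) {
  n <- length(ratios)
  qual <- function(i, dir) if (dir == "gain") ratios[i] >= gain_t else ratios[i] <= loss_t
  out <- list()
  for (dir in c("gain", "loss")) {
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!qual(j, dir)) break  # window i:j no longer all-qualifying
        maximal <- (i == 1 || !qual(i - 1, dir)) && (j == n || !qual(j + 1, dir))
        if (maximal && (j - i + 1) >= min_probes) {
          out[[length(out) + 1]] <- data.frame(first = i, last = j, direction = dir,
                                               mean_log2 = mean(ratios[i:j]))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(first = integer(0), last = integer(0),
                      direction = character(0), mean_log2 = numeric(0)))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$first), , drop = FALSE]
}

# AUC by exhaustive pair counting: P(pos > neg) + 0.5 P(tie).
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# BH by the step-up definition: adj_i = min over j with p_(j) >= p_(i) ranked
# j of m * p_(j) / j, computed directly on the sorted sequence.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-group log-rank observed/expected by explicit risk-set tabulation at each
# distinct event time.
oracle_logrank <- function(time, event, group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2)
  g1 <- levels(group)[1]
  obs <- c(0, 0); expd <- c(0, 0); varsum <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    obs <- obs + c(d1, d - d1)
    e1 <- d * n1 / n
    expd <- expd + c(e1, d - e1)
    if (n > 1) varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (varsum > 0) (obs[1] - expd[1])^2 / varsum else 0
  list(observed = obs, expected = expd, chisq = chisq)
}

# All-pairs interval overlap (1-based inclusive, same chromosome, >= 1 bp).
oracle_overlap_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] <= b$stop[j] && b$start[j] <= a$stop[i]) {
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

# Small expression scenario shared by several tests.
make_expression_scenario <- function(seed = 11, n_mirnas = 120, de_fraction = 0.1,
                                     effect = 2, n_a = 20, n_b = 20) {
  genome <- generate_genome(2, 4, 50, n_mirnas, seed = seed)
  expr <- generate_expression(genome, n_group_a = n_a, n_group_b = n_b,
                              de_fraction = de_fraction, effect = effect,
                              seed = seed + 1)
  expr$genome <- genome
  expr
}
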