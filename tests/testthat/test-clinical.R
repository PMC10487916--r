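# ddCt quantification, ROC, score combination, associations, survival.

make_ct <- function(sample_id, tissue, target, tct, rct) {
  data.frame(sample_id = sample_id, tissue = tissue, target = target,
             rep1 = tct, rep2 = tct, rep3 = tct,
             ref_rep1 = rct, ref_rep2 = rct, ref_rep3 = rct,
             stringsAsFactors = FALSE)
}

test_that("relative quantification follows 2^-ddCt with exclusion at 31/35", {
  ct <- make_ct("s1", "tumor", "miR-x", 28, 25)
  rq <- relative_quantity(ct, calibrator_delta_ct = 1)
  expect_false(rq$excluded)
  expect_equal(rq$delta_ct, 3)
  expect_equal(rq$rq, 2^(-2))   # ddCt = 3 - 1

  # ddCt = 0 -> RQ = 1
  expect_equal(relative_quantity(make_ct("s", "tumor", "m", 26, 25),
                                 calibrator_delta_ct = 1)$rq, 1)

  # reference Ct exactly at 31 is excluded; just below is kept
  expect_true(relative_quantity(make_ct("s", "tumor", "m", 28, 31),
                                calibrator_delta_ct = 0)$excluded)
  expect_false(relative_quantity(make_ct("s", "tumor", "m", 28, 30.9),
                                 calibrator_delta_ct = 0)$excluded)
  # target Ct exactly at 35 is excluded
  expect_true(relative_quantity(make_ct("s", "tumor", "m", 35, 25),
                                calibrator_delta_ct = 0)$excluded)

  # replicate means are used: (27,28,29) averages to 28
  ct3 <- make_ct("s1", "tumor", "m", 28, 25)
  ct3[, c("rep1", "rep2", "rep3")] <- c(27, 28, 29)
  expect_equal(relative_quantity(ct3, calibrator_delta_ct = 1)$rq, 0.25)

  # missing replicate names the sample
  bad <- make_ct("s9", "tumor", "m", 28, 25); bad$rep2 <- NA
  expect_error(relative_quantity(bad), "s9")

  # default calibrator is the ANT mean delta-Ct, so ANT records average RQ 1
  ct <- rbind(make_ct(c("a1", "a2"), "ANT", "m", c(27, 29), 25),
              make_ct("t1", "tumor", "m", 26, 25))
  rq <- relative_quantity(ct)
  expect_equal(mean(log2(rq$rq[rq$tissue == "ANT"])), 0)
  expect_equal(rq$rq[rq$tissue == "tumor"], 2^(3 - 1))
})

test_that("RQ is monotone in target and reference Ct", {
  base <- relative_quantity(make_ct("s", "tumor", "m", 28, 25),
                            calibrator_delta_ct = 0)$rq
  up_t <- relative_quantity(make_ct("s", "tumor", "m", 29, 25),
                            calibrator_delta_ct = 0)$rq
  up_r <- relative_quantity(make_ct("s", "tumor", "m", 28, 26),
                            calibrator_delta_ct = 0)$rq
  expect_lt(up_t, base)
  expect_gt(up_r, base)
})

test_that("ROC: separation, ties, complement identity, pair-count oracle", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("ANT", "tumor"), each = 3),
                     positive = "tumor", n_boot = 0)
  expect_equal(perfect$auc, 1)

  ties <- roc_auc(rep(5, 10), rep(c("ANT", "tumor"), 5), positive = "tumor",
                  n_boot = 0)
  expect_equal(ties$auc, 0.5)

  set.seed(73)
  for (i in 1:10) {
    scores <- round(rnorm(20), 1)  # rounding forces some ties
    labels <- sample(rep(c("ANT", "tumor"), each = 10))
    r <- roc_auc(scores, labels, positive = "tumor", n_boot = 0)
    expect_equal(r$auc, oracle_auc(scores, labels == "tumor"))
    rneg <- roc_auc(-scores, labels, positive = "tumor", n_boot = 0)
    expect_equal(r$auc + rneg$auc, 1)
  }
  expect_error(roc_auc(1:5, rep("tumor", 5)), "two classes")

  # agreement with an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(74)
  scores <- rnorm(30); labels <- sample(rep(c("ANT", "tumor"), 15))
  r <- roc_auc(scores, labels, positive = "tumor", n_boot = 0)
  p <- pROC::roc(labels, scores, levels = c("ANT", "tumor"),
                 direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(p)))
})

test_that("bootstrap CI brackets the AUC and is seed-reproducible", {
  set.seed(75)
  scores <- c(rnorm(15, 1), rnorm(15))
  labels <- rep(c("tumor", "ANT"), each = 15)
  r1 <- roc_auc(scores, labels, positive = "tumor", n_boot = 200, seed = 5)
  r2 <- roc_auc(scores, labels, positive = "tumor", n_boot = 200, seed = 5)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$auc)
  expect_gte(r1$ci[2], r1$auc)
})

test_that("combined score is the mean of z-scores", {
  set.seed(77)
  x <- matrix(rnorm(40), ncol = 4)
  comb <- combine_scores(x)
  expect_equal(comb, rowMeans(scale(x)))

  # k identical features reduce to the single feature's z-score
  same <- cbind(x[, 1], x[, 1], x[, 1])
  expect_equal(combine_scores(same), as.numeric(scale(x[, 1])))

  # two features that are negatives of each other cancel
  oppo <- cbind(x[, 1], -x[, 1])
  expect_equal(combine_scores(oppo), rep(0, nrow(x)))

  # combined AUC equals ROC of the hand-computed mean-z vector
  labels <- rep(c("tumor", "ANT"), 5)
  r <- roc_auc(combine_scores(x), labels, positive = "tumor", n_boot = 0)
  expect_equal(r$auc, oracle_auc(rowMeans(scale(x)), labels == "tumor"))

  flat <- cbind(x[, 1], rep(2, nrow(x)))
  expect_error(combine_scores(flat), "zero-variance")
})

test_that("clinical association is the Welch t-test on dichotomized strata", {
  set.seed(79)
  clin <- generate_clinical(40, rnorm(40), seed = 81)$clinical
  expr <- rnorm(40)

  res <- associate_clinical(expr, clin, "tumor_size")
  expect_equal(res$cutpoint, 1.7)
  strata <- factor(ifelse(clin$tumor_size > 1.7, "high", "low"),
                   levels = c("low", "high"))
  tt <- t.test(expr ~ strata)   # Welch by default
  expect_equal(res$p_value, tt$p.value)

  # strongly separated strata
  shifted <- expr + 5 * (clin$tumor_size > 1.7)
  expect_lt(associate_clinical(shifted, clin, "tumor_size")$p_value, 1e-3)

  # binary variable needs no cutpoint
  res_b <- associate_clinical(expr, clin, "recurrence")
  expect_true(is.na(res_b$cutpoint))
  expect_equal(res_b$p_value,
               t.test(expr ~ factor(clin$recurrence))$p.value)

  expect_error(associate_clinical(expr, clin, "nothere"), "unknown clinical")
  tiny <- clin; tiny$p53 <- c(99, rep(1, 39))
  expect_error(associate_clinical(expr, tiny, "p53"), "fewer than 2")
})

test_that("multivariate association is OLS with per-coefficient t-tests", {
  set.seed(83)
  n <- 60
  clin <- data.frame(age = rnorm(n, 55, 10), grade = sample(2:3, n, TRUE),
                     recurrence = runif(n) < 0.4)
  # single binary covariate: coefficient p equals the pooled two-sample t-test
  y <- rnorm(n)
  mv <- multivariate_association(y, clin, "recurrence")
  tt <- t.test(y ~ clin$recurrence, var.equal = TRUE)
  expect_equal(mv$coefficients$p_value[2], tt$p.value)

  # parameter recovery: response = 2 * age + small noise
  y2 <- 2 * clin$age + rnorm(n, 0, 0.01)
  mv2 <- multivariate_association(y2, clin, c("age", "grade"))
  co <- mv2$coefficients[mv2$coefficients$term == "age", ]
  expect_lt(abs(co$estimate - 2), 3 * co$std_error)

  # orthogonal covariates leave coefficients unchanged when others are dropped
  x1 <- rep(c(-1, 1), n / 2); x2 <- rep(c(-1, 1), each = n / 2)
  clin_o <- data.frame(x1 = x1, x2 = x2)
  y3 <- x1 + 0.5 * x2 + rnorm(n)
  full <- multivariate_association(y3, clin_o, c("x1", "x2"))
  part <- multivariate_association(y3, clin_o, "x1")
  expect_equal(full$coefficients$estimate[full$coefficients$term == "x1"],
               part$coefficients$estimate[part$coefficients$term == "x1"])

  # collinear design is an error naming the column
  clin_c <- data.frame(a = clin$age, b = clin$age * 2)
  expect_error(multivariate_association(y, clin_c, c("a", "b")), "collinear")
})

test_that("median split sends ties low and halves odd-length vectors", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_warning(lab <- median_split(rep(3, 5)), "degenerate")
  expect_true(all(lab == "low"))
  set.seed(85)
  v <- rnorm(101)
  expect_equal(sum(median_split(v) == "high"), 50)
})

test_that("log-rank matches a hand risk-set tabulation on a 12-record set", {
  time <- c(3, 5, 7, 7, 9, 12, 4, 6, 8, 10, 12, 12)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0, 1)
  group <- rep(c("low", "high"), each = 6)

  km <- km_logrank(time, event, group)
  hand <- oracle_logrank(time, event, factor(group, levels = c("high", "low")))
  expect_equal(unname(km$observed), hand$observed)
  expect_equal(unname(km$expected), hand$expected, tolerance = 1e-12)
  expect_equal(km$chisq, hand$chisq, tolerance = 1e-12)
  expect_equal(km$p_value, pchisq(hand$chisq, 1, lower.tail = FALSE))

  # label swap leaves the statistic unchanged
  swapped <- km_logrank(time, event, ifelse(group == "low", "high", "low"))
  expect_equal(swapped$chisq, km$chisq)

  # no events: curves at 1, statistic 0
  none <- km_logrank(time, rep(0, 12), group)
  expect_equal(none$chisq, 0)
  expect_equal(none$p_value, 1)
  expect_true(all(none$fit$surv == 1))

  # identical groups duplicated: statistic 0
  dupl <- km_logrank(rep(time[1:6], 2), rep(event[1:6], 2),
                     rep(c("low", "high"), each = 6))
  expect_equal(dupl$chisq, 0, tolerance = 1e-12)

  expect_error(km_logrank(rep(0, 4), rep(0, 4), rep(c("a", "b"), 2)), "time 0")
})

test_that("log-rank p is approximately uniform under the null hazard", {
  below <- 0
  for (i in 1:200) {
    set.seed(9000 + i)
    x <- rnorm(100)
    cl <- generate_clinical(100, x, hazard_coef = 0, baseline_hazard = 0.02,
                            censor_month = 60, seed = 9500 + i)
    km <- km_logrank(cl$clinical$follow_up, cl$clinical$status, median_split(x))
    below <- below + (km$p_value < 0.05)
  }
  expect_gte(below / 200, 0.02)
  expect_lte(below / 200, 0.09)
})
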