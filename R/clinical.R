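# Validation-layer statistics: ddCt relative quantification, ROC/AUC,
# dichotomized clinical associations, and Kaplan-Meier/log-rank survival.

#' Relative quantification (2^-ddCt) from triplicate Ct values
#'
#' Per record: the target and reference channels are averaged over their three
#' replicates; records with reference mean Ct >= `ref_ct_max` (default 31) or
#' target mean Ct >= `target_ct_max` (default 35) are excluded. For the rest,
#' dCt = target - reference, ddCt = dCt - calibrator dCt, RQ = 2^(-ddCt).
#' The calibrator defaults to the mean dCt of the included ANT-tissue records
#' of the same target, so ANT averages RQ = 1 by construction.
#'
#' @param ct A data.frame with columns `sample_id`, `tissue` ("tumor"/"ANT"),
#'   `target`, `rep1`..`rep3` (target Ct) and `ref_rep1`..`ref_rep3`
#'   (reference Ct, RNU48 role). Missing replicates are an error naming the
#'   sample.
#' @param calibrator_delta_ct Optional fixed calibrator dCt (cycles); if
#'   `NULL`, computed per target from the ANT records.
#' @param ref_ct_max,target_ct_max Exclusion limits (Ct at or above is
#'   excluded).
#' @return data.frame: input keys plus `target_ct`, `reference_ct`,
#'   `excluded`, `delta_ct`, `delta_delta_ct`, `rq` (NA where excluded).
#' @export
relative_quantity <- function(ct, calibrator_delta_ct = NULL,
                              ref_ct_max = 31, target_ct_max = 35) {
  reps <- c("rep1", "rep2", "rep3")
  ref_reps <- paste0("ref_", reps)
  .check_columns(ct, c("sample_id", "tissue", "target", reps, ref_reps), "ct")
  tmat <- as.matrix(ct[, reps])
  rmat <- as.matrix(ct[, ref_reps])
  bad <- which(rowSums(is.na(tmat)) + rowSums(is.na(rmat)) > 0)
  if (length(bad)) {
    stop("missing Ct replicate(s) for sample(s): ",
         paste(unique(ct$sample_id[bad]), collapse = ", "))
  }
  if (any(tmat <= 0) || any(rmat <= 0)) stop("Ct values must be positive")

  out <- ct[, c("sample_id", "tissue", "target")]
  out$target_ct <- rowMeans(tmat)
  out$reference_ct <- rowMeans(rmat)
  out$excluded <- out$reference_ct >= ref_ct_max | out$target_ct >= target_ct_max
  out$delta_ct <- ifelse(out$excluded, NA_real_, out$target_ct - out$reference_ct)

  cal <- function(target) {
    if (!is.null(calibrator_delta_ct)) return(calibrator_delta_ct)
    ant <- out$delta_ct[out$target == target & out$tissue == "ANT" & !out$excluded]
    if (length(ant) == 0L) {
      stop("no included ANT record to calibrate target ", target,
           "; supply calibrator_delta_ct")
    }
    mean(ant)
  }
  cal_by_target <- vapply(unique(out$target), cal, numeric(1))
  out$delta_delta_ct <- out$delta_ct - cal_by_target[out$target]
  out$rq <- 2^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' Sensitivity is plotted against 1 - specificity over all score thresholds
#' (higher score predicts the positive class); the AUC is the trapezoidal area
#' under that curve, which equals the Mann-Whitney U statistic scaled by
#' 1/(n1*n2) with ties counted 1/2. The 95% CI is a stratified percentile
#' bootstrap.
#'
#' @param scores Numeric vector.
#' @param labels Vector of class labels, two classes.
#' @param positive Label of the positive (e.g. tumor) class; default the
#'   second sorted unique label.
#' @param n_boot Bootstrap replicates for the CI (default 2000); 0 disables.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `roc_result`: list with `auc`, `ci` (length-2 or
#'   NULL), `curve` (data.frame threshold, sensitivity, fpr), `n_positive`,
#'   `n_negative`, `positive`.
#' @export
roc_auc <- function(scores, labels, positive = NULL, n_boot = 2000, seed = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- classes[2]
  if (!positive %in% classes) stop("positive class not present in labels")
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]

  curve <- .roc_curve(scores, labels == positive)
  auc <- .trapezoid_auc(curve$fpr, curve$sensitivity)

  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      p <- sample(pos, length(pos), replace = TRUE)
      n <- sample(neg, length(neg), replace = TRUE)
      cv <- .roc_curve(c(p, n), c(rep(TRUE, length(p)), rep(FALSE, length(n))))
      .trapezoid_auc(cv$fpr, cv$sensitivity)
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  }
  structure(list(auc = auc, ci = ci, curve = curve,
                 n_positive = length(pos), n_negative = length(neg),
                 positive = positive),
            class = "roc_result")
}

# ROC points at every distinct threshold, from (Inf, none called) down.
.roc_curve <- function(scores, is_pos) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[is_pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!is_pos] >= t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, fpr = fpr)
}

.trapezoid_auc <- function(fpr, sens) {
  o <- order(fpr, sens)
  sum(diff(fpr[o]) * (utils::head(sens[o], -1) + utils::tail(sens[o], -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (positive class '%s'; %d vs %d)\n",
              x$auc, x$positive, x$n_positive, x$n_negative))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI: %.4f - %.4f\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("AUC = %.4f", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Combine several miRNA expression vectors into one score
#'
#' Each feature is z-scored across samples, then the unweighted mean of the
#' z-scores is taken per sample. (A logistic combination is a reasonable
#' alternative but is not the deterministic default.)
#'
#' @param x Numeric matrix, samples in rows, features (k >= 2) in columns.
#' @return Numeric vector, one combined score per sample.
#' @export
combine_scores <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need k >= 2 features to combine")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  rowMeans(scale(x))
}

# Default dichotomization cutpoints for the clinical table.
.default_cutpoints <- c(age = 55.5, tumor_size = 1.7, bmi = 28.3,
                        ki67 = 10, p53 = 10)

#' Association of expression with a dichotomized clinical variable
#'
#' The clinical variable is split into two strata (numeric variables at
#' `cutpoint`: above vs at-or-below; logical/two-level variables as they are)
#' and expression is compared between strata by an unpaired two-sample t-test
#' with Welch's correction (pooled-variance optional).
#'
#' @param expression Numeric vector, one value per clinical record.
#' @param clinical data.frame of clinical records.
#' @param variable Column name in `clinical`.
#' @param cutpoint Numeric cutpoint; defaults per variable (age 55.5,
#'   tumor_size 1.7, bmi 28.3, ki67 10, p53 10), required for other numeric
#'   variables.
#' @param welch Use Welch's correction (default `TRUE`).
#' @return list: `variable`, `cutpoint` (NA for categorical), `p_value`,
#'   `means` (named, high/low or level means), `n` (complete pairs used).
#' @export
associate_clinical <- function(expression, clinical, variable, cutpoint = NULL,
                               welch = TRUE) {
  if (!variable %in% names(clinical)) stop("unknown clinical variable: ", variable)
  v <- clinical[[variable]]
  if (length(expression) != nrow(clinical)) {
    stop("expression must align with clinical records")
  }
  ok <- !is.na(expression) & !is.na(v)
  expression <- expression[ok]; v <- v[ok]

  if (is.numeric(v) && length(unique(v)) > 2L) {
    if (is.null(cutpoint)) {
      if (!variable %in% names(.default_cutpoints)) {
        stop("no default cutpoint for '", variable, "'; supply one")
      }
      cutpoint <- .default_cutpoints[[variable]]
    }
    stratum <- factor(ifelse(v > cutpoint, "high", "low"), levels = c("low", "high"))
  } else {
    stratum <- factor(v)
    cutpoint <- NA_real_
    if (nlevels(stratum) != 2L) stop("variable '", variable, "' does not have two levels")
  }
  if (any(table(stratum) < 2L)) {
    stop("a stratum of '", variable, "' has fewer than 2 records")
  }
  tt <- stats::t.test(expression ~ stratum, var.equal = !welch)
  list(variable = variable, cutpoint = cutpoint, p_value = tt$p.value,
       means = tapply(expression, stratum, mean), n = length(expression))
}

#' Multivariate linear association of one miRNA with clinical covariates
#'
#' Ordinary least squares of the expression response on the encoded clinical
#' covariates, with t-tests on the coefficients. A rank-deficient design is an
#' error listing the collinear columns.
#'
#' @param expression Numeric response vector.
#' @param clinical data.frame of clinical records.
#' @param covariates Character vector of column names to include.
#' @return list: `coefficients` (data.frame term, estimate, std_error,
#'   t_value, p_value), `fit` (the `lm` object).
#' @export
multivariate_association <- function(expression, clinical, covariates) {
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov)) {
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  }
  dat <- clinical[, covariates, drop = FALSE]
  dat$.response <- expression
  if (nrow(dat) <= length(covariates) + 1L) {
    stop("need n > number of covariates + 1")
  }
  fit <- stats::lm(.response ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  tab <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(tab),
                                 estimate = tab[, 1], std_error = tab[, 2],
                                 t_value = tab[, 3], p_value = tab[, 4],
                                 stringsAsFactors = FALSE, row.names = NULL),
       fit = fit)
}

#' Split values into high/low at the median
#'
#' "high" is strictly above the median; values at the median go to "low". If
#' all values are equal the split is degenerate (all "low") and a warning is
#' raised.
#'
#' @param values Numeric vector, length >= 2.
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- stats::median(values)
  lab <- factor(ifelse(values > m, "high", "low"), levels = c("low", "high"))
  if (all(lab == "low")) warning("degenerate median split: all values in 'low'")
  lab
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimator per group (an event is `status == "deceased"` at
#' `follow_up`; other records are censored) and the ordinary two-group
#' log-rank chi-square with 1 df. With two groups the "log-rank test for
#' trend" reduces to this ordinary log-rank.
#'
#' @param time Follow-up times (months).
#' @param event Logical or 0/1 event indicator, or a character status vector
#'   where `"deceased"` marks an event.
#' @param group Two-level grouping (e.g. from [median_split()]).
#' @return Object of class `km_result`: list with `fit` (a
#'   `survival::survfit`), `chisq`, `df`, `p_value`, `observed`, `expected`
#'   (per-group event counts).
#' @export
km_logrank <- function(time, event, group) {
  if (is.character(event)) event <- event == "deceased"
  event <- as.integer(event)
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (all(time == 0)) stop("all records censored at time 0")

  surv <- survival::Surv(time, event)
  fit <- survival::survfit(surv ~ group)
  if (sum(event) == 0L) {
    # no events anywhere: both curves constant at 1, statistic 0 by convention
    obs <- exp <- stats::setNames(rep(0, 2), levels(group))
    res <- list(fit = fit, chisq = 0, df = 1L, p_value = 1,
                observed = obs, expected = exp)
  } else {
    sd_ <- survival::survdiff(surv ~ group)
    res <- list(fit = fit, chisq = sd_$chisq, df = 1L,
                p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
                observed = stats::setNames(sd_$obs, levels(group)),
                expected = stats::setNames(sd_$exp, levels(group)))
  }
  class(res) <- "km_result"
  res
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}

#' @export
plot.km_result <- function(x, ...) {
  plot(x$fit, xlab = "months", ylab = "survival probability",
       col = c(1, 2), ...)
  graphics::legend("bottomleft", legend = names(x$observed), col = c(1, 2), lty = 1)
  invisible(x)
}
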