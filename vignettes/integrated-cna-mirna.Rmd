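---
title: "Methods: integrated copy-number and miRNA expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated copy-number and miRNA expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircna)
```

## The analysis this package implements

Triple-negative breast cancer (TNBC) tumours frequently carry large somatic
copy-number alterations (CNAs), and miRNAs are over-represented in regions of
genomic instability. When a miRNA lying inside a recurrently gained region is
also up-regulated (or inside a lost region and down-regulated), the copy-number
change is a plausible mechanism for the expression change. `mircna` implements
that reasoning as a reusable pipeline:

1. **Aberration calling.** Each case's array-CGH probe track (probe interval +
   log2 test/reference intensity ratio) is scanned for maximal runs of at least
   `min_probes = 3` consecutive probes whose ratios all lie at or beyond
   ±0.25 log2. A run of gains (losses) becomes one call spanning the first
   probe's start to the last probe's stop, with the arithmetic mean log2 ratio.
2. **Penetrance and recurrence.** Calls are aggregated per cytoband and
   direction; a case counts at most once per (band, direction). Bands at or
   above a recurrence frequency of 0.19 are retained, and adjacent retained
   bands of the same direction are merged into one region.
3. **Expression and differential expression.** Raw NanoString-style counts are
   background-subtracted (negative-control geometric mean, floored at 1),
   scaled by positive-control geometric means, and content-normalized against
   all endogenous features. DE between case and control groups uses a
   two-sample t-test on `log2(x + 1)` with Benjamini–Hochberg adjustment; the
   significant set is the dual cutoff *p* < 0.01 **and** FDR < 0.05. Samples
   are clustered on the significant submatrix with 1 − Pearson *r* distance and
   unweighted average linkage.
4. **Integration.** Approach 1 joins each significant miRNA to every recurrent
   region its annotation overlaps and classifies concordance (up ∧ gain or
   down ∧ loss). Approach 2 takes the genes predicted as targets by at least 2
   of 3 prediction tables, intersects them with genes residing in recurrent
   regions, and ranks genes by how many miRNAs target them.
5. **Validation statistics.** ΔΔCt relative quantification with Ct exclusion
   (reference ≥ 31, target ≥ 35 excluded, taken literally at the boundary),
   ROC/AUC with a stratified percentile bootstrap CI, dichotomized clinical
   associations (Welch t), an OLS multivariate option, and Kaplan–Meier /
   log-rank survival on a median split of expression.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_probes` | 3 | probes | minimum run length for a CNA call |
| `gain_threshold` / `loss_threshold` | ±0.25 | log2 ratio | per-probe aberration threshold, boundary inclusive |
| `min_frequency` | 0.19 | proportion of cases | recurrence cutoff; the lowest frequency retained in the reference cohort |
| `p_cutoff`, `fdr_cutoff` | 0.01, 0.05 | probability | dual DE significance rule |
| `min_dbs` | 2 | databases | "2-of-3" target consensus |
| `ref_ct_max`, `target_ct_max` | 31, 35 | Ct cycles | qPCR exclusion limits |
| clinical cutpoints | 55.5 y, 1.7 cm, 28.3 kg/m², 10 % (Ki-67, p53) | — | dichotomization of continuous clinical variables |

All of these are arguments, not constants; `pipeline_config()` collects them
and rejects unknown keys.

## Design choices where the procedure was genuinely open

* **Run rule.** "At least 3 consecutive probes beyond ±0.25" is interpreted as
  *every probe in the run* beyond the threshold, runs maximal, a single
  sub-threshold probe terminating the run. This is deterministic and
  reproducible, unlike proprietary segmentation scores; no gap tolerance is
  applied.
* **Ratio orientation.** Positive log2 ratio = gain (test over reference), the
  conventional orientation in penetrance plots.
* **Coordinates.** 1-based inclusive at both ends everywhere internally
  (`size = stop − start + 1`), the convention of cytogenetic tables; BED input
  is converted on read (`start + 1`).
* **Normalization grand mean.** The across-sample "grand mean" of per-sample
  geometric means is itself geometric. With an arithmetic grand mean,
  re-running the scaling steps multiplies the whole matrix by a constant; with
  the geometric grand mean the scaling is an exact fixed point, so
  normalization is idempotent to floating tolerance — a property the test
  suite asserts at 1e-9.
* **t-test flavour.** Pooled-variance Student t for the array DE (the classic
  microarray default), Welch for clinical associations; both exposed via
  `var_equal` / `welch` arguments.
* **log2(x + 1).** Applied after normalization so floored values are defined;
  background flooring is at 1, not 0, for the same reason.
* **ΔΔCt calibrator.** The assay does not dictate a calibrator; the default is
  the mean ΔCt of the included ANT (adjacent non-tumour) records per target,
  so ANT tissue averages RQ = 1. A fixed calibrator can be supplied.
* **Combined biomarker score.** Per-feature z-scores averaged with equal
  weights — deterministic and parameter-free; a logistic combination is a
  reasonable alternative but would make the stage depend on a fitted model.
* **Two-group "log-rank for trend".** With only two groups the trend test
  reduces to the ordinary log-rank, which is what `km_logrank()` computes.
* **Median split.** "High" is strictly above the median; ties go to "low". An
  all-equal vector degenerates to all-"low" with a warning.
* **Multi-region miRNAs.** A DE miRNA overlapping two recurrent regions yields
  one record per region but is counted once; it is counted concordant if at
  least one record is concordant. (Real penetrance profiles essentially never
  produce opposite-direction regions over one miRNA; the synthetic tests can.)
* **Percent reporting** rounds half away from zero to one decimal.

## What the synthetic generators emulate

The generators produce every input the pipeline consumes, with recorded truth:

* `generate_genome()` — a desk-scale genome: by default 2 chromosomes × 10 Mb
  split into equal cytobands, features placed uniformly. This preserves the
  semantics of probe runs, band overlap and merging at roughly 1/300 of
  genome scale, keeping the full test suite in CPU-minutes.
* `generate_acgh_profiles()` — probes every 10 kb; implanted step-shaped
  segments of 8–25 probes at ±0.5 log2 in Gaussian noise (SD 0.1). At that
  noise-to-amplitude ratio a per-probe sub-threshold dip has probability
  ≈ 0.006, and at ≥ 8 probes any single dip still leaves a sub-run covering at
  least half the implant, so implants are recoverable by the run rule with
  ≥ 50 % reciprocal overlap — the margin behind the 100 %-recovery property.
* `generate_expression()` — log-normal counts (Normal on the log2 scale,
  baseline mean 7, SD 1) rather than negative-binomial, because the DE
  statistic in scope is a t-test on normalized log values; a per-sample
  library scale factor, low-level Poisson negative controls and a
  sample-scaled positive-control ladder give the normalization real work.
  Group sizes default to 18 cases vs 32 controls, the profiling arms of the
  reference cohort; recovery calibration uses 20 vs 20.
* `generate_target_dbs()` — each miRNA's candidate genes are either shared by
  all three tables (probability `db_agreement`) or private to one; the
  returned truth is recomputed by exhaustive 2-of-3 counting over the emitted
  tables, never from the assignment shortcut.
* `generate_clinical()` — exponential event times with log-hazard linear in a
  driver miRNA's expression, administrative censoring, and independently drawn
  covariates at ranges typical of a TNBC cohort (age 55 ± 11 y, tumour size
  1.85 ± 1.25 cm, BMI 29 ± 7). The joint distribution of covariates and
  survival beyond the driver link is not modelled.

What passing these tests does **not** show: real FFPE tissue brings probe GC
and wave artefacts, degraded RNA, batch effects between assay runs, and
clinically correlated covariates. The synthetic suite validates the
*algorithms* — run enumeration, normalization arithmetic, join logic,
statistic definitions — not robustness to those artefacts.

## Numerical notes and degenerate inputs

* Geometric means are computed over strictly positive entries; a sample with a
  zero positive-control geometric mean is an error naming the sample.
* Zero within-group variance with equal means gives *p* = 1 by convention
  (*p* = 0 with unequal means).
* A zero-variance sample makes the clustering correlation undefined and is an
  error naming the sample; the same rule applies to zero-variance features in
  the combined score.
* ROC ties are counted ½, making AUC(s) + AUC(−s) = 1 exactly; the curve is
  evaluated at every distinct threshold so the trapezoid equals the
  Mann–Whitney form.
* `bh_fdr()` validates its input and delegates the step-up computation to
  `stats::p.adjust`; the test suite checks it against the definitional
  formula.
* One pipeline seed fans out to per-stage substreams by fixed offsets, so a
  stage can be regenerated independently and a report is bit-reproducible.

## Problem sizes used by the checks

The bundled checks run the generators at 2 chromosomes × 10 Mb, 100–200
miRNAs, 20–40 expression samples, 5–24 aCGH cases, 50 null-DE replicates and
200 null-survival replicates — sizes chosen so each property is measured with
useful statistical resolution while the whole suite stays within a few
CPU-minutes.

## Known limitations

* No segmentation-score reimplementation (ADM-like), wave/GC correction, or
  allele-specific copy number; the run rule is the calling model.
* Target prediction is consumed as tables; no live database queries.
* No Cox regression; survival analysis is KM + log-rank on a median split.
* The expression model has no count-level overdispersion structure, so
  count-model DE methods (negative-binomial GLMs) are out of scope.
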