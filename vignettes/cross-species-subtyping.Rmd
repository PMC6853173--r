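---
title: "Cross-species mapping of mouse intestinal tumor signatures onto human CRC subtypes"
author: "xsubtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species mapping of mouse intestinal tumor signatures onto human CRC subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsubtype)
```

## The analysis this package implements

Genetically engineered mouse models (GEMMs) of intestinal cancer — genotype
codes combining K (*Kras*^G12D^), P (*Trp53*-null), N (Notch1 intracellular
domain) and A (*Apc*-mutant) — produce tumors whose transcriptomes can be
compared with the molecular subtypes of human colorectal cancer: the four
consensus molecular subtypes (CMS1–4, with CMS4 the mesenchymal,
poorest-prognosis group) and the five CRC intrinsic subtypes (CRIS-A–E, with
CRIS-B carrying poor prognosis). `xsubtype` implements that cross-species
comparison as a reusable, fully tested pipeline:

1. **Signatures.** From a per-gene differential-expression (DE) table
   (gene, log2 fold change, p, Benjamini–Hochberg adjusted p), the top *N*
   most significant genes passing a strict logFC threshold are selected.
   The packaged parameterisations are: 75 up-regulated genes per subtype at
   logFC > 0.75 for the CMS/CRIS templates (4 × 75 = 300 and 5 × 75 = 375
   selected genes in total), the top 100 up-regulated genes at logFC > 1
   for the z-sum organoid panel score, and the top 500 most significantly
   regulated genes (either direction) for the survival-stratification
   signature.
2. **Orthology.** Mouse DE profiles are translated into the human gene
   namespace using a Biomart-style homology table; one-to-many mappings are
   resolved by keeping the partner with the highest homology percentage.
3. **Model–subtype correlation.** Each mouse model's logFC vector is
   Pearson-correlated with each subtype's template weight column over the
   template genes present in the model's table, giving the models × subtypes
   correlation matrix; two such correlations are compared with the Fisher
   r-to-z transform, $z = \frac{\operatorname{atanh} r_1 -
   \operatorname{atanh} r_2}{\sqrt{1/(n_1-3) + 1/(n_2-3)}}$.
4. **Patient scoring.** Samples are scored either by a z-sum panel score
   (sum over a fixed gene panel of gene-wise standardized expression; the
   packaged NOTCH and WNT panels, or any signature-derived panel) with
   within-group median stratification, or by the signature-correlation
   score: expression is mean-centred gene-wise and each sample is the
   Pearson correlation of its centred vector with the signature weights,
   classified as high (> 0.1) versus low, or positive / negative /
   unassigned at ±0.1 in the three-group mode.
5. **Survival.** Recurrence-free survival of the score groups is estimated
   with Kaplan–Meier product-limit curves and compared with the unweighted
   log-rank test.
6. **Auxiliaries.** Marker-mean infiltration scores standardized per cell
   type, metastasis incidence summaries with two-sided 2×2 chi-square,
   relative qPCR expression as $2^{-\Delta CT}$, and IUPAC consensus motif
   scanning of promoter sequences on both strands (default motif: the RBPJ
   core site `TGGGAA`).

## Design choices where the procedure was open

Several details of this kind of workflow are conventionally left
underspecified; the package fixes each one explicitly and
deterministically.

* **"Most significantly regulated"** is interpreted as smallest adjusted p
  (regardless of sign for `direction = "both"`); logFC thresholds are
  strict (`>`). Ranking ties are broken by descending |logFC|, then
  ascending gene id, so selections are invariant to input row order.
* **Orthology ties and collisions.** Equal maximal homology is broken by
  ascending partner gene id. When two source genes translate to the same
  target, the row with the smaller adjusted p is kept (then smaller raw p,
  then source id): the most significant evidence survives. Unmapped genes
  are dropped with an exact reported count, never silently.
* **Correlation-score weights.** Sample scoring uses the signature's signed
  logFC values as weights by default; a binary up/down variant
  (`binary_weights = TRUE`) is available for workflows that prefer an
  up/down indicator over effect-size weights.
* **Classification thresholds.** The two-group split at 0.1 (the survival-curve
  stratification) is the default; the three-group ±0.1 variant is an
  explicit mode rather than a silent choice.
* **Standardization** always uses the sample standard deviation (n − 1),
  and zero-variance genes standardize to 0 with a warning. Median
  stratification is strict-above ("high" ⇔ score > median), so an
  all-tied group is entirely "low".
* **Batch handling.** Synthetic batches are additive offsets; the package
  removes them by per-batch gene centering with the global gene mean
  re-added. This is a deliberately transparent substitute for
  empirical-Bayes batch correction and is only claimed to cancel additive
  offsets.
* **Infiltration scores** are marker-set means standardized per cell type.
  No marker lists are bundled; users supply their own GMT, keeping the
  scorer independent of any particular marker catalogue's version.
* **Motif scanning** treats the motif as a parameter (default the RBPJ
  core consensus `TGGGAA`). `N` in a sequence never matches; minus-strand
  hits are reverse-complement matches reported at forward-strand
  coordinates, 1-based.
* **Welch DE engine.** The internal DE method is a vectorised Welch t test
  on log expression with BH adjustment. It is a pluggable engine for
  synthetic data, not a reimplementation of shrinkage-based DE models;
  external DE tables are first-class inputs everywhere.
* **Kaplan–Meier and log-rank** follow the standard product-limit
  conventions (deaths before censorings at tied times; unweighted
  log-rank; no confidence bands). The 2×2 chi-square is two-sided without
  continuity correction by default, with a flag to enable Yates.

## What the synthetic cohorts emulate

The generator produces log-scale Gaussian expression directly — no count
layer — because every downstream operation works on log expression. A
cohort has:

* four (configurable) subtypes with **disjoint blocks** of
  `genes_per_subtype_block = 150` genes whose mean is elevated by
  `block_effect = 1.5` log units in that subtype's samples, over
  per-gene baselines ~ N(7, 1) with residual noise `noise_sd = 1`;
* optional additive gene × batch offsets (`batch_effect_sd`);
* censored survival: event times are exponential with log-hazard
  `hazard_beta` (default 0.5) per standard deviation of the
  hazard-subtype's block score, baseline rate `log(2)/(censor_time/2)`,
  and administrative censoring at `censor_time = 1825` days (five years of
  recurrence-free follow-up, median event at 2.5 years for an average
  patient).

Mouse profiles plant `overlap_fraction` (default 0.7) of the target
subtype's block genes as strongly up-regulated (logFC ≈ 1.5 × `lfc_scale`,
near-zero p), on top of background logFC noise, mapped through a simulated
orthology table in which a chosen fraction of human genes has a second,
lower-homology mouse partner. Effect sizes and noise levels are
calibration choices — a moderate, realistic planted-signal regime — not
estimates of any real cohort. Blocks are disjoint and effects additive, so
template sizes, classifications and power are analytically predictable;
real tumors have correlated programs, impure samples, and non-Gaussian
tails, so passing tests demonstrate correctness of the computations, not
biological validity on real data.

The packaged `kpn_incidence_fixture()` is the one deliberately
data-anchored object: 29 KPN animals, 24 with liver metastases (83%), all
29 with at least one metastatic site (100%). Every non-liver site
assignment and all survival days in it are synthetic placeholders, flagged
by its `synthetic_sites` attribute.

## Numerical conventions

Degenerate inputs are handled by documented rules rather than silence:
zero-variance genes in both DE groups get p = 1; zero-variance rows
standardize to 0 with a warning; missing panel or signature genes are
dropped with counted warnings, never imputed; fewer than 3 overlapping
genes is an error for any correlation. All readers reject invalid data
with the file, row and rule named. Oracle-equivalence tests hold to
1e-12 (1e-14 for BH) against brute-force reimplementations.

## Problem sizes used by the test and acceptance suites

The suites run entirely on generated data: cohorts of 120–500 samples ×
620–1000 genes, 100 simulation seeds for planted-subtype recovery, 40
cohorts of n = 500 for log-rank power, and 2000 replicates for null
calibration of the log-rank test (with the Welch engine calibrated on a
2000-gene null matrix). These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands (e.g. ±0.005 on a 0.05 rejection
rate at 2000 replicates) while keeping a full run in tens of seconds.

## Worked example

```{r example}
cfg <- cohort_sim_config(n_samples = 160, n_genes = 650, seed = 42)
sim <- simulate_cohort(cfg)

clin <- sim$clinical
de <- welch_de(sim$expression,
               clin$sample[clin$subtype == "CMS4"],
               clin$sample[clin$subtype != "CMS4"])
sig <- select_top_signature(de, n = 500, lfc_threshold = 0,
                            direction = "both", name = "risk")

scores <- correlation_score_samples(sim$expression, sig)
groups <- classify_by_correlation(scores)
table(groups)

lr <- logrank_test(clin$time, clin$event, groups)
lr
```

High-scoring samples (correlation > 0.1 with the CMS4-like signature) have
elevated hazard by construction, and the log-rank test recovers the
difference.

## Limitations

* The Welch engine is not a substitute for count-based DE models on real
  RNA-seq; supply external DE tables for real data.
* Batch centering removes only additive offsets.
* Infiltration scores are relative (standardized within cohort), not
  absolute abundances.
* The motif scanner does exact IUPAC consensus matching; it does not score
  degenerate sites by a position weight matrix.
* CMS/CRIS labels are inputs; the package does not reimplement the
  original subtype classifiers.
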