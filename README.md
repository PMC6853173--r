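# xsubtype

Cross-species mapping of mouse intestinal-tumor expression signatures onto
human colorectal cancer (CRC) molecular subtypes, with patient scoring and
survival stratification.

## The problem

Genetically engineered mouse models (GEMMs) of intestinal cancer — genotypes
combining K (*Kras*^G12D), P (*Trp53*-null), N (Notch1 intracellular
domain) and A (*Apc*-mutant) — are only useful as preclinical models if
their tumors transcriptionally resemble the human disease subtypes they are
meant to represent. `xsubtype` provides the computational side of that
question as a tested R package, for computational biologists who have
per-gene differential-expression (DE) tables from mouse models and
expression + clinical data from human cohorts:

* **Signature construction** — top-*N* selection from DE tables under a
  strict logFC threshold, ranked by adjusted p (ties: |logFC|, then gene
  id); per-subtype weight templates for CMS1–4 (75 genes each at
  logFC > 0.75; 300 genes total) and CRIS-A–E (375 total).
* **Orthology translation** — human↔mouse mapping with the
  highest-homology rule for one-to-many Biomart-style mappings.
* **Model–subtype correlation** — Pearson correlation of each model's
  logFC vector with each subtype's template weights; Fisher r-to-z
  comparison of two correlations:
  `z = (atanh r1 − atanh r2) / sqrt(1/(n1−3) + 1/(n2−3))`.
* **Patient scoring** — z-sum panel scores (packaged NOTCH and WNT gene
  panels, or any signature), `score_s = Σ_g z_gs`, with within-group
  median stratification; and signature-correlation scores, the Pearson r
  between a sample's gene-wise mean-centred expression and the signature
  weights, classified high/low at 0.1 (or positive/negative/unassigned at
  ±0.1).
* **Survival statistics** — Kaplan–Meier product-limit curves, unweighted
  log-rank tests, Benjamini–Hochberg adjustment, 2×2 chi-square incidence
  comparisons, `2^-ΔCT` qPCR expression.
* **Promoter motif scanning** — IUPAC consensus matching on both strands
  (default: the RBPJ core site `TGGGAA`), for locating putative
  NOTCH-responsive elements.
* **Synthetic data** — cohorts with subtype expression blocks, batch
  effects and score-linked censored survival; planted mouse profiles;
  orthology tables; and a packaged 29-animal KPN metastasis-incidence
  cohort — so the entire pipeline runs and is tested without any external
  download.

See `vignettes/cross-species-subtyping.Rmd` for the full model
description, parameter defaults, and design decisions.

## Worked example

```r
library(xsubtype)

cfg <- cohort_sim_config(n_samples = 160, n_genes = 650, seed = 42)
sim <- simulate_cohort(cfg)

clin <- sim$clinical
de  <- welch_de(sim$expression,
                clin$sample[clin$subtype == "CMS4"],
                clin$sample[clin$subtype != "CMS4"])
sig <- select_top_signature(de, n = 500, lfc_threshold = 0,
                            direction = "both", name = "risk")

scores <- correlation_score_samples(sim$expression, sig)
groups <- classify_by_correlation(scores)   # high: r > 0.1
table(groups)
#> groups
#> high  low
#>   40  120

logrank_test(clin$time, clin$event, groups)
#> log-rank test: statistic = 22.23, p = 2.42e-06
```

The simulated cohort ties the recurrence hazard to the CMS4-like block
score, so samples correlating with the CMS4-derived 500-gene signature
(r > 0.1, the "high" group) recur earlier, and the log-rank test detects
the separation. Other one-liners:

```r
incidence_summary(kpn_incidence_fixture(), "liver")
#>   genotype  n affected incidence_pct
#> 1      KPN 29       24      82.75862

fisher_rz_compare(0.8, 75, 0.3, 75)
#> Fisher r-to-z comparison: statistic = 4.735, p = 2.2e-06
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "xsub.R", package = "xsubtype")` with subcommands
`run`, `simulate`, `map-orthologs`, `build-signature`, `build-templates`,
`score`, `survival`, `incidence` and `motifscan`.

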