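---
title: "lumishift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lumishift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumishift)
```

# Scope and model

`lumishift` operationalizes a biomarker analysis for response to
next-generation SERDs in ER+ breast cancer. The scientific model is that
therapeutic benefit requires retained ERα dependence, which is itself a
property of luminal lineage identity. The pipeline therefore measures two
per-tumor quantities — an ERα activity score and a luminal TF score, both
mean z-scores of fixed gene panels after normalization to a reference cohort
— and derives a binary Lum-high/Lum-low class that is carried into survival
comparisons. Around that core sit the supporting analyses a translational
study needs: response stratification and log-rank survival tests, RNA-based
hotspot mutation inference, IHC H-scores, paired differential expression,
preranked gene-set enrichment, covariate-adjusted per-gene response
association, TF-target enrichment, and a chromatin arm (differential peak
classes, motif enrichment and co-occurrence, peak-to-gene proximity,
expression trends across a resistance time course).

Upstream read processing (alignment, peak calling, variant calling
internals, PAM50 subtyping) is out of scope: the package consumes the
tabular outputs of those standard pipelines.

# Thresholds

All hard cutoffs live in `threshold_config()` so a run is reproducible from
one object:

| parameter | default | units | role |
|---|---|---|---|
| `pfs_responder_min` | 2 | months | responder landmark (NR iff event with PFS below it) |
| `vaf_mutant_min` | 0.05 | fraction | inclusive mutant-call allele fraction ("at least 5%") |
| `min_depth` | 1 | reads | coverage floor below which a variant is a no-call |
| `de_lfc_cut` / `de_fdr_cut` | 1 / 0.05 | log2 / fraction | significance cutoffs for DE genes and differential peaks |
| `cnv_amp_min` / `cnv_loss_max` | 1 / −1 | log2 ratio | inclusive amplification / loss boundaries |
| `peak_cap` | 60000 | peaks | maximum peak-set size entering motif analyses |
| `gene_window` | 3000 | bp | TSS-to-peak proximity window |
| `min_sites_per_gene` | 2 | sites | "proximal to more than one site" |
| `nes_display_cut` | 2 | NES | display filter for enrichment results |
| `tf_top_k` | 10 | TFs | size of the reported TF ranking |

Boundary semantics are deliberate and pinned by tests: the mutant and
amplification rules are *inclusive* (5.0% is mutant, log2 ratio 1.0 is
amplified), the responder rule is *exclusive below the landmark* (PFS 2.0
with an event is a responder), and the Lum-high rule is *strict* (a
median-tied sample is Lum-low).

# Statistical choices

* **FDR.** Reported FDR is Benjamini–Hochberg step-up everywhere. The
  procedure is a choice of this package; only "FDR" itself is inherited
  from the analysis design. BH is not idempotent, so FDR columns are
  defined as BH applied once to the p column (tests verify this
  reproduction).
* **Rank tests.** The two-group comparison is the Mann–Whitney U test; the
  within-gene-set condition comparison is the paired Wilcoxon signed-rank
  test. "Paired Mann–Whitney" is a contradiction in terms, so the paired
  reading is signed-rank, with the unpaired test available via
  `paired = FALSE` in `expression_trend_test()`. Both tests use exhaustive
  enumeration when the (combined or non-zero) sample size is at most 12 —
  enumeration is cheap there and remains exact under ties — and the
  tie-corrected normal approximation without continuity correction above
  that; the output records which branch ran. Zero paired differences are
  dropped and counted, and an all-zero comparison reports p = 1 with a
  warning rather than an error.
* **Fisher tests.** One-sided (enrichment direction) p-values are upper
  hypergeometric tails; the odds ratio is the sample cross-product ratio,
  with an infinite sentinel for zero-cell tables (a Haldane +0.5 option
  exists for display).
* **Log-rank and HR.** The survival comparison is the standard two-group
  log-rank statistic; the hazard ratio is summarized from observed/expected
  event counts, (O₁/E₁)/(O₂/E₂), rather than a Cox fit, matching the
  convention of attributing the HR to the log-rank test. The Kaplan–Meier
  median is the earliest time with S(t) ≤ 0.5 (an `NA` sentinel when the
  curve never reaches 0.5). Estimation uses the survival package;
  correctness is cross-checked in tests against an independent
  risk-table computation.
* **Differential expression.** Ordinary paired t statistics on mean paired
  log2 differences — a deliberate simplification relative to
  moderated-variance (empirical Bayes) pipelines. The validation surface is
  planted-effect recovery (recall and false-flag rates on synthetic data),
  not numerical identity with any published package. Genes with zero
  difference variance get p = 1 (no shift) or p = 0 (exact constant shift).
* **Preranked GSEA.** Classic weighted running-sum ES (hit increments
  proportional to |metric|, uniform miss decrements; extrema evaluated at
  hit points only, which is exact because the running sum is linear between
  hits). NES divides ES by the mean |ES| of same-sign gene-label
  permutations; the two-sided p is the sign-matched permutation tail,
  doubled and capped at 1, with the +1 correction in numerator and
  denominator. The achievable p floor therefore depends on how many
  permutations fall on the observed sign (roughly 2/(n_same + 1)), not on
  n_perm alone. Default 1000 permutations, seeded.
* **Response association.** Per gene, logistic regression of response on
  expression standardized per gene (so coefficients are per expression SD)
  plus covariates; coefficients are reported in log2-odds units
  (β/ln 2) with two-sided Wald p. Complete separation is detected (glm
  fitted-probability warning together with a divergent coefficient) and
  reported as an `NA` sentinel with a `separated` flag instead of an
  unstable estimate.
* **Luminal classification medians** are computed over whatever sample set
  is passed in — the intended usage is all baseline biopsies. Whether the
  original analysis computed medians per arm is not determinable from the
  design; restricting to an arm is done by subsetting the input, and the
  default (all baseline samples) is the documented convention.

# Chromatin conventions

Coordinates are BED convention: 0-based, half-open. Peak-to-gene distance is
anchored at the gene TSS and measured to the peak *interval* (0 inside), a
choice made because the downstream claims concern promoter-proximal
regulation; the alternative anchors (peak summit, gene body) are not
implemented. With a 3 kb window this makes "TSS 3000 bp from the peak edge"
proximal and 3001 bp not, which the tests pin down. "Proximal to more than
one site" is read literally as ≥ 2 sites; `min_sites_per_gene = 1` covers
the weaker reading. The `unchanged` peak class requires FDR < 1 — an
effectively vacuous FDR filter, kept verbatim because that is how the
reference set for motif enrichment is defined. Peak capping samples
uniformly without replacement under the run seed and preserves input order.
The enrichment reference set is always supplied explicitly by the caller
(down-vs-unchanged, up-vs-unchanged, or opposite-direction motif-matched
peaks); there is no implicit default.

# What the generators emulate

`simulate_cohort()` plants a latent `lum_high`/`lum_low` group per patient
that drives both expression and survival:

* expression: all four signature panels plus background genes; luminal-high
  tumors get a `+sig_effect` shift (in reference-SD units, default 1) on
  ERα-induced and luminal-TF genes, luminal-low tumors on MAPK targets;
  on-treatment matrices remove the ERα-induced shift in luminal-high tumors
  (on-target drug effect in responders); the reference cohort (138 samples,
  the normalization cohort size used in the study design) is effect-free.
* survival: exponential times with median 6 months in the low group and a
  hazard ratio of 6/22 for the high group, so the planted medians are 22 vs
  6 months; exponential was chosen because median = ln2/hazard gives a
  closed-form calibration. Censoring replaces a fraction (default 0.2) of
  times with a uniform draw below the event time.
* defaults: 55 patients (the baseline biopsy cohort scale) and a balanced
  latent split (`frac_nr = 0.5`, the monotherapy biopsy cohort was an even
  NR/Resp split) — balance also matches the double-median classification
  rule, which is centered on the cohort median by construction.

`simulate_pileups()` draws mutant reads binomially at planted VAFs;
`simulate_ihc()` draws intensity percentages from a Dirichlet.
`simulate_peaks_and_motifs()` places non-overlapping peaks on one synthetic
chromosome, assigns classes (default 28% up / 6% down, echoing the several-
fold excess of gained over lost sites in resistant lines), draws per-peak
log2FC/FDR consistent with the planted class, and plants motif structure:
the ERα motif concentrated in down peaks with an ESR1/FOXA1 co-occurrence
profile giving roughly 70% ESR1-without-FOXA1 among down peaks carrying
either motif, and FOXA1/FOXM1/TEAD/MEF2/STAT motifs concentrated in up
peaks. A subset of genes (default 150, ~50 per partner motif, matching the
reported per-pair set sizes) receives two forced FOXA1+partner co-occurring
up-peaks within the 3 kb window of their TSS and a planted expression
increase of `trend_effect` (default 1 log2 unit) per condition step.

What the generators do **not** emulate: gene–gene correlation and realistic
expression covariance, batch structure, informative censoring, read-level
error models, overlapping/nested peaks, and motif positional structure
within peaks. Passing tests therefore demonstrate that the implementations
recover planted effects under idealized independence assumptions — they are
evidence of correctness of the statistics and rules, not of performance on
real cohorts.

# Validation strategy and problem sizes

The test suite has three layers:

1. **Boundary tests** pin every printed rule at its exact boundary (VAF
   4.9% vs 5.0%, log2 ratio 0.99 vs 1.0, PFS 1.9 vs 2.0, distance 3000 vs
   3001 bp, the 60,000-peak cap, the 300-point H-score ceiling over the
   full 1% grid).
2. **Oracle tests** compare each statistic to an independent naive
   computation: exhaustive hypergeometric enumeration for all 2×2 tables
   with total ≤ 30 (tolerance 1e−10), direct O/E risk tables for the
   log-rank statistic (1e−10), full running-sum evaluation for the GSEA ES,
   the literal step-up formula for BH, and `stats::wilcox.test` /
   `fgsea::calcGseaStat` as external cross-checks.
3. **Recovery tests** run the full pipeline on synthetic data: the planted
   1 z-unit signature effect recovered within 20% at n = 200; the log-rank
   HR within 2× of the planted 6/22 with p < 0.05 in at least 18 of 20
   seeds; a perfect mutation-call confusion matrix at depth 10,000 for VAFs
   {0, 0.02, 0.10}; DE recall ≥ 90/100 planted genes with ≤ 5% false flags
   at 15 pairs and SD 0.5; null calibration of association Wald p (2000
   genes, 200 samples, KS distance < 0.05) and GSEA permutation p (200
   random sets, rejection rate in [0.01, 0.10]); and the planted motif
   directions recovered in at least 19 of 20 seeds at 4000 peaks.

These problem sizes (200 patients, a few thousand genes/peaks, hundreds of
permutations) were chosen as the smallest scales at which the planted
effects are statistically decisive, keeping the whole suite fast while
leaving the assertions tight.

# Known limitations

* Differential expression does not moderate variances; at very small pair
  counts it is less powerful than empirical-Bayes approaches.
* The GSEA p-value is a gene-label permutation p, not a sample-permutation
  p; it tests enrichment given the observed ranking.
* The HR is an O/E summary, not a Cox estimate; no covariate adjustment is
  available in the survival comparison (the association module handles
  covariates instead).
* Mutation inference is a threshold rule on pileups; it does not model
  base quality, strand bias, or mapping artifacts.
* Gene symbols are matched case-insensitively after whitespace stripping,
  without alias resolution; supply harmonized annotations.
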