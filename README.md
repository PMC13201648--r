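# lumishift

Biomarker analysis of response to next-generation selective estrogen
receptor-α antagonist/degraders (SERDs) in ER+ HER2− breast cancer.

## The problem

Responses to next-generation SERDs (e.g. giredestrant) in pretreated
metastatic ER+ breast cancer are highly heterogeneous: a substantial fraction
of patients progress by their first on-treatment scan while others benefit
for years, largely independent of *ESR1* mutation status. The working model
is that benefit tracks retained ERα dependence and **luminal lineage
identity**: responding tumors keep high ERα activity and luminal
transcription-factor expression, while intrinsically resistant tumors lose
luminal identity and up-regulate ERα-independent proliferative programs
(EGFR/MAPK, Hippo/TEAD, Wnt, JAK/STAT), with FOXA1/FOXM1 redirected to
ERα-independent chromatin.

`lumishift` implements that analysis as a reusable, tested pipeline for
translational scientists: given a clinical table, expression matrices, read
pileups, IHC intensity tables, peak/motif tables and gene annotations, it
scores and classifies tumors, stratifies survival, infers mutations, and
quantifies the chromatin/motif structure of resistance. Because patient-level
data from such trials cannot be shared, the package ships synthetic-data
generators that emulate every input with planted effects, so the full
pipeline is exercised and validated end-to-end without any download.

## What it computes

* **Signature scoring** — expression is z-normalized per gene against a
  reference cohort (z = (x − μ_ref)/σ_ref); a signature score is the mean z
  over the signature's genes. Four fixed panels ship as constants: 21
  ERα-induced genes (the *ERα activity score*), 17 ERα-repressed genes, 15
  luminal TF genes, 9 MAPK target genes.
* **Lum-high / Lum-low** — a tumor is Lum-high iff it is *strictly* above
  the cohort median on both ERα activity and luminal TF scores.
* **Survival** — non-responders are patients progressing with PFS < 2
  months; Kaplan–Meier product-limit curves, a two-group log-rank test with
  HR = (O₁/E₁)/(O₂/E₂), and NR/Resp × cBOR χ² contingency tests.
* **Mutation inference** — a (sample, gene) is mutant iff any panel variant
  (ESR1/PIK3CA hotspot panels built in) has VAF = mut_reads/depth ≥ 5%
  (inclusive); CNV calls at log₂ ratio ≥ 1 (amplified) / ≤ −1 (loss).
* **IHC H-score** — H = 1·(%1+) + 2·(%2+) + 3·(%3+), range 0–300.
* **Expression association** — paired differential expression (mean paired
  log₂FC, paired t, BH FDR, |log₂FC| ≥ 1 & FDR < 0.05 flags); preranked GSEA
  (weighted running-sum ES, permutation NES and two-sided p); per-gene
  logistic association of response with arm/subtype covariates (log₂-odds
  per expression SD, Wald p); one-sided Fisher TF-target enrichment with a
  top-10 report.
* **Chromatin** — differential peak classification (up/down at |log₂FC| ≥ 1
  & FDR < 0.05; unchanged at |log₂FC| < 1, FDR < 1), a 60,000-peak cap with
  seeded sampling, motif enrichment scored as %TP − %FP with one-sided
  Fisher p, ERα/FOXA1 motif co-occurrence partitions, peak-to-gene mapping
  (TSS within 3 kb of a peak, genes kept at ≥ 2 sites), and paired
  signed-rank expression trend tests across parental / 2-month / resistant
  conditions.

All cutoffs live in a single `threshold_config()` registry.

## Worked example

```r
library(lumishift)
library(dplyr)

sim <- simulate_cohort(cohort_sim_config(n_patients = 55, seed = 1))
z <- zscore_to_reference(sim$expr_baseline, sim$reference)
scores <- score_signatures(z)
head(scores, 3)
#> # A tibble: 3 × 5
#>   sample era_induced era_repressed luminal_tf mapk_target
#>   <chr>        <dbl>         <dbl>      <dbl>       <dbl>
#> 1 P001         0.455        -0.219     0.0670       0.808
#> 2 P002         0.110         0.280    -0.431        0.495
#> 3 P003         1.08          0.164     0.600       -0.176

classified <- classify_luminal(scores)
clin <- bind_cols(sim$clinical, classified["lum_class"]) |> stratify_response()
km_logrank(clin, pfs_months, event, lum_class)
#> <log-rank comparison: Lum-high vs Lum-low>
#>   chisq = 7.963 on 1 df, p = 0.004774, HR = 0.4035
#> # A tibble: 2 × 5
#>   group        n observed expected median
#>   <chr>    <int>    <dbl>    <dbl>  <dbl>
#> 1 Lum-high    26       16    23.1   21.6
#> 2 Lum-low     29       17     9.90   9.03
```

Lum-high tumors (strictly above both score medians) progress at less than
half the hazard of Lum-low tumors in this simulated cohort, with median PFS
21.6 vs 9.0 months — the planted high/low contrast recovered through the
whole scoring → classification → survival path. Mutation inference works the
same way from pileups:

```r
pu <- simulate_pileups(tibble::tibble(sample = c("pt1", "pt2"), gene = "ESR1",
  variant = "ESR1:Y537S", depth = 8000, vaf = c(0.12, 0.01)), seed = 2)
infer_mutation_status(pu)
#> # A tibble: 2 × 5
#>   sample gene  status max_vaf n_covered
#> 1 pt1    ESR1  mutant 0.117           1
#> 2 pt2    ESR1  NMD    0.00887         1
```

`vignettes/lumishift-methods.Rmd` documents the models, parameter choices
and the exact conditions the generators emulate.

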