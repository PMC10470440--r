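# ctdnawatch

Longitudinal, tumor-agnostic monitoring of circulating tumor DNA (ctDNA)
from deep targeted panel sequencing — built for the setting where serial
plasma samples from patients on checkpoint-inhibitor immunotherapy must be
screened for somatic driver mutations *without* a matched tumor biopsy.

## The problem and the model

A 40-gene panel sequenced at ~15 000x sees every position of every plasma
sample as a stranded nucleotide count vector (A, T, G, C, deletion; forward
and reverse strand). True somatic variants at mutant allele frequencies
(MAF) of a few percent or less must be separated from two confounders:

1. **Sequencing error.** Per position and alternative allele, errors are
   modelled beta-binomially with mean fraction μ and overdispersion ρ
   (shapes α = μ(1−ρ)/ρ, β = (1−μ)(1−ρ)/ρ). The error model is estimated
   from the *background* — all samples of other patients — with ρ obtained
   by a method-of-moments estimator truncated to [1e-6, 0.1]. Each sample ×
   position × allele is then scored with a one-sided likelihood-ratio test:
   the sample's two strand observations share one variant mean, the
   background shares one error mean, and the null ties them (df = 1, with
   the one-sided halving p = ½·P(χ²₁ ≥ T)). MAF and p are reported for the
   most significant alteration per position.
2. **Germline polymorphisms.** After retaining variants significant
   (p ≤ 0.05) at any timepoint per patient, SNPs are excluded when MAF
   exceeds 0.4, population frequency (ExAC/gnomAD) exceeds 0.01, or the MAF
   profile is high (> 0.1) and constant over time. Remaining variants are
   kept only when they satisfy a cancer-gene-census driver rule: tumor
   suppressor + ≥ 2 of 3 deleterious predictions (SIFT / PolyPhen /
   MutationTaster, stop-gains filling missing calls), or oncogene + ≥ 3
   exact COSMIC matches.

Downstream analytics track per-patient mean driver MAF and detection status
per timepoint (zero-imputed when nothing is significant), compare groups
with exact Wilcoxon rank-sum / Kruskal–Wallis / Fisher–Freeman–Halton tests,
tabulate per-gene mutation frequencies by response category, and relate
baseline ctDNA detection to overall survival with Kaplan–Meier curves and
log-rank tests. An in-silico spike-in benchmark measures the MAF limit of
detection, and a seeded synthetic cohort generator with truth tables makes
the whole pipeline testable without restricted patient data.

## Worked example

```r
library(ctdnawatch)

cfg <- cohort_config(n_patients = 8,
  group_sizes = c(response = 3, resistance = 3, acquired_resistance = 2),
  baseline_shedders = c(response = 1, resistance = 3, acquired_resistance = 2),
  n_positions = 200, n_genes = 20, depth_mean = 15000, seed = 42)
cohort    <- simulate_cohort(cfg)
calls     <- call_variants(cohort$counts, cohort$sample_info)
variants  <- build_variant_table(calls, cohort$annotation, cohort$drivers)
timelines <- patient_timelines(variants, cohort$clinical)

patient_summary(timelines)[, c("patient_id", "response_category",
                               "baseline_detected", "baseline_maf")]
#>   patient_id   response_category baseline_detected baseline_maf
#> 1        P01            response              TRUE   0.11740124
#> 2        P02            response             FALSE   0.00000000
#> 3        P03            response             FALSE   0.00000000
#> 4        P04          resistance              TRUE   0.08305843
#> 5        P05          resistance              TRUE   0.06676787
#> 6        P06          resistance              TRUE   0.10111088
#> 7        P07 acquired_resistance              TRUE   0.05207828
#> 8        P08 acquired_resistance              TRUE   0.05524393

detection_by_category(timelines)
#> <group_summary> response_category (timepoint day 0)
#>               g
#> det            acquired_resistance resistance response
#>   detected                       2          3        1
#>   not_detected                   0          0        2
#>   test: fisher_freeman_halton, two-sided p = 0.25
```

Reading the output: only one of three responders sheds detectable ctDNA at
baseline while every non-responding patient does, and each detected
patient's baseline mean driver MAF (5–12 % here) is the average MAF of its
significant driver variants. The exact test asks whether baseline detection
differs between the three response categories; at this toy cohort size the
split is not significant (p = 0.25).

The spike-in limit of detection on the default synthetic background
(93 rows, 15 000x, μ = 2e-4, ρ = 1e-3):

```r
lod_benchmark(n_repeats = 20, seed = 7)
#> <lod_summary> median MAF limit of detection 0.0005835 (IQR 0.0005698-0.0006451)
#>   20 repeat(s), 0 never significant, alpha = 0.05
```

i.e. on this clean, model-matched background the caller flags injections
from roughly 0.06 % MAF; real plasma backgrounds are dirtier and yield
higher limits.

File-based workflows use `read_count_matrix()`, `read_clinical_table()`,
`read_annotation_table()`, `read_driver_genes()` and
`write_variant_table()` (TSV or VCF 4.2) with the same objects.

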