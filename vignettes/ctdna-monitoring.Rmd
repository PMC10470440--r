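---
title: "Methods: beta-binomial background calling and longitudinal ctDNA monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-binomial background calling and longitudinal ctDNA monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctdnawatch` implements a tumor-agnostic pipeline for monitoring circulating
tumor DNA (ctDNA) in deep targeted panel sequencing of serial plasma samples,
as used to follow metastatic melanoma patients on checkpoint-inhibitor
immunotherapy. "Tumor-agnostic" means no matched tumor biopsy informs the
caller: somatic variants must be separated from sequencing error and from
germline polymorphisms using the plasma data and annotation alone. This
vignette is the package's account of the statistical model, its tunable
parameters, the numerical choices, and what the synthetic cohort generator
does and does not emulate.

## The data

The caller's sole sequencing input is a stranded nucleotide count matrix: for
each sample and panel position, read counts over 10 channels -- A, T, G, C
and X (deletion) on the forward strand, then the same five on the reverse
strand. Per-strand coverage is the sum of that strand's five channels. The
mutant allele frequency (MAF) of an alteration is its variant count (both
strands) divided by the row sum over all 10 channels, and 0 at zero coverage.
The deletion channel contributes to coverage but is not callable as an
alteration by default (`include_deletions = FALSE`): the panel's substance is
nucleotide substitutions, including those in the *TERT* promoter, which is
analysed with the same caller settings as exonic positions.

Coordinates are 1-based hg38 labels carried as opaque strings; no liftover or
reference genome is needed, because the reference allele at each position is
defined as the nucleotide with the largest strand-summed count across the
background samples (ties broken alphabetically).

## The background error model and site test

Sequencing error at a given position and alternative nucleotide is modelled
as beta-binomial: a binomial draw whose success probability is itself beta
distributed with mean $\mu$ (the error fraction) and overdispersion $\rho$,
via the shapes $\alpha = \mu(1-\rho)/\rho$, $\beta = (1-\mu)(1-\rho)/\rho$.
As $\rho \to 0$ the model collapses to the binomial; larger $\rho$ captures
site-specific error bursts shared across samples. For each tested sample the
background is *every sample of other patients* -- never another timepoint of
the same patient, whose true mutations would otherwise be absorbed into the
error model.

Per (position, alternative allele):

1. $\rho$ is estimated from the background by an ANOVA-type method of
   moments on the per-(sample, strand) variant fractions, truncated to
   $[10^{-6}, 0.1]$. The truncation prevents degenerate fits at low coverage;
   the estimator is deterministic given its inputs.
2. A one-sided likelihood-ratio test of elevation is computed. Under the
   alternative, the background observations (both strands) share one error
   mean and the tested sample's two strand observations share one variant
   mean; under the null all observations share a single mean. Each profile
   likelihood is maximised over the mean by Brent search on
   $(10^{-8}, 0.5)$ at tolerance $10^{-10}$. The statistic
   $T = 2(\ell_1 - \ell_0)$ (clipped at 0) adds one parameter, so it is
   referred to $\chi^2_1$ with the one-sided halving
   $p = \tfrac12 P(\chi^2_1 \ge T)$ when the sample's pooled fraction
   exceeds the background's pooled fraction, and $p = 1$ otherwise.

The single shared elevation parameter expresses the biological alternative --
one mutation elevates both strands together -- and makes the null hypothesis
properly nested (one tied parameter), which is what keeps the test calibrated:
on matched null simulations (depth 5000, $\mu = 2\times10^{-4}$,
$\rho = 10^{-3}$, 50 background samples, $\rho$ re-estimated per site) the
acceptance suite verifies a type-I error within $[0.025, 0.075]$ at
$\alpha = 0.05$. A per-strand-free-parameter variant of this test was
examined during development and rejected: summing two one-parameter strand
statistics yields a $\chi^2_2$ component that a halved $\chi^2_1$ reference
badly understates (measured type-I error $\approx 0.15$).

Per position the caller reports the most significant alteration (smallest p;
ties broken by larger MAF, then alphabetically) together with its MAF, for
every sample and position -- no thresholding happens in the caller itself.
The maximisation and the batch loop over positions are compiled (Rcpp), with
the background fit cached per position across the samples of a patient;
a cohort-scale call (about 115 samples by 1500 positions by 3 alternative
alleles) takes a couple of minutes on one core.

## The filter cascade

`build_variant_table()` applies three stages in a fixed order:

1. **Retention.** A variant is kept for a patient if $p \le \alpha$
   (inclusive, default 0.05) at *any* of that patient's timepoints; the
   retained variant keeps its full per-timepoint MAF/p series. No
   multiple-testing correction is applied by default, mirroring the raw
   retention rule this design follows; `method = "BH"` adds
   Benjamini-Hochberg within patient for users who want it.
2. **SNP exclusion**, in documented rule order: any timepoint MAF above 0.4;
   ExAC or gnomAD frequency above 0.01; or a high-and-constant profile (all
   timepoint MAFs above 0.1 and range at most `constant_tol`). The constancy
   tolerance is a declared convention: `constant_tol = 0.05` spans roughly
   12 binomial standard deviations of a MAF-0.5 site at 15000x, so true
   heterozygous SNPs fall within it while rising or clearing somatic
   trajectories do not. The constancy rule requires at least two timepoints.
3. **Driver classification** against a curated gene role list: a tumor
   suppressor variant qualifies when at least two of SIFT, PolyPhen and
   MutationTaster call it deleterious -- for stop-gain/frameshift
   consequences a predictor with no call counts as deleterious, because
   truncating variants are routinely unscored and the rule could otherwise
   never fire for exactly the class it names; for non-truncating variants a
   missing verdict never counts. An oncogene variant qualifies with at least
   three exact COSMIC matches. Genes listed as `both` qualify under either
   rule; unlisted genes never qualify. Calls at unannotated variant keys are
   flagged and classified non-driver.

The output is exactly the retained, non-SNP driver variants, one row per
(patient, variant, timepoint), with a per-variant audit table attached.

## Longitudinal analytics

Per patient and timepoint, the *mean driver MAF* is the arithmetic mean over
the retained driver variants significant in that sample, and 0 when there are
none -- the zero imputation applies at baseline and at every later timepoint
alike, so undetected samples sit at 0 in trajectory plots. *Detection* at a
timepoint requires per-sample significance of a retained driver variant, not
mere retention: a variant that was significant only in another sample does
not light up this one.

Group comparisons use the two-sided Wilcoxon rank-sum for two independent
patient groups. Because zero-imputed baselines tie heavily,
`compare_maf_groups()` computes the exact permutation p-value on midranks by
full enumeration whenever $\binom{n}{n_1} \le 2\times10^5$, and falls back to
the tie-corrected normal approximation for larger cohorts. Three or more
groups use Kruskal-Wallis. Baseline detection across the three response
categories is tested with the Fisher-Freeman-Halton exact test on the 2xK
table (network algorithm via `stats::fisher.test`; a chi-square alternative
sits behind `method = "chisq"`); the test suite cross-checks it against a
full enumeration over tables with fixed margins. Overall survival is the
time from treatment initiation to death from any cause, right-censored at
the administrative last-follow-up date; curves are Kaplan-Meier and strata
are compared by two-sided log-rank (the `survival` package). Degenerate
inputs (no events anywhere, a zero table margin) return p = 1 with a
warning rather than an error.

## The spike-in limit-of-detection benchmark

`lod_benchmark()` measures the smallest MAF the caller flags at a chosen
position: the reference channels of one target row are fixed at the maximum
reference count observed per strand in the source matrix; the variant
channels sweep a grid of injected counts from 0 to the maximum variant count
observed (split evenly across strands, odd remainder to the forward strand);
every matrix is re-analysed, and the limit of detection (LOD) of a series is
the smallest injected MAF with $p \le \alpha$. Because a single series from
a single target row is one draw of a random quantity, the estimand here is
the median and interquartile range (type-7 linear interpolation -- stated
because the IQR endpoints depend on it) over `n_repeats = 50` independent
draws of the target row and a bootstrap resample of the background rows;
`mode = "single"` recovers the one-series variant. MAF is strictly
increasing along a series and p non-increasing, which the tests assert.

The study design this mirrors used restricted patient count matrices at the
*BRAF* V600E position, which cannot be shipped; `lod_background()` provides
the default synthetic background (93 rows, 15000x, $\mu = 2\times10^{-4}$,
$\rho = 10^{-3}$). Its absolute LOD is therefore a property of that clean
synthetic background, not a reproduction of any published figure; what the
acceptance suite checks instead is that every repeat's LOD agrees with an
independently coded brute-force oracle within one grid step, and that the
median LOD is non-increasing in depth and non-decreasing in $\mu$ across a
3x3 grid (at the one-injected-read resolution at which the LOD is
quantised).

## The synthetic cohort generator

`simulate_cohort()` produces every input the pipeline consumes, plus a truth
table. The defaults are the monitored study design: 24 patients split
11 response / 9 resistance / 4 acquired resistance, 4-6 samples at 21-day
intervals, a 40-gene panel (one promoter-class gene) at mean depth 15000x,
and baseline ctDNA shedding in 4/11, 7/9 and 4/4 patients per group. Panel
width defaults to 1500 positions -- a desk-scale stand-in for 150000 bp that
keeps a full cohort run in minutes; passing `n_positions = 150000` restores
panel scale for cluster runs. Choices the design source does not pin down
are fixed once here:

* per-position error means $\mu$ are lognormal around $2\times10^{-4}$
  (sdlog 0.5, truncated at $5\times10^{-3}$) with $\rho = 10^{-3}$ -- a
  plausible consensus-read error profile;
* depths are lognormal (sdlog 0.15) split binomially across strands;
* driver trajectories are deterministic shapes scaled by a lognormal
  baseline MAF (median 0.08): responders decay to exactly 0 by the last
  sample, resistant patients rise persistently (one resistant patient turns
  positive only under therapy, one never sheds), acquired-resistance
  patients dip after baseline and rise again;
* patients with high metastatic load (at least 3 of 12/12 high/low split)
  shed at twice the baseline MAF, encoding the burden-shedding association;
* three private germline SNPs per patient at MAF 0.5;
* survival is exponential with group medians 639 / 121 / 200 days, censored
  administratively at day 1460;
* annotation records are generated for every injected variant (satisfying
  the driver rule recorded in the truth table, or SNP-like population
  frequencies) plus `n_decoy_annotations = 3` driver-qualifying records at
  uninjected positions. The decoy density is deliberately low: under raw
  any-timepoint retention every qualifying key contributes roughly $\alpha$
  of false detection per sample, and the monitored study's outcome (few
  driver variants per patient, responders largely negative) implies that
  annotation-qualifying artifact sites on a hotspot panel are rare. The
  zero-injection alpha-budget check uses 10 decoys on a 400-position panel
  so the budget has enough trials to be testable.

All randomness flows from one seed through fixed substreams (clinical,
truth, counts, annotation), so identical seeds give identical cohorts
byte for byte.

What the generator does *not* emulate: fragment-length biology, UMI and
trinucleotide error context, copy-number change, tumor-fraction
deconvolution, batch effects between sequencing runs, and sampling
truncated by death (sampling days are generated independently of survival).
Passing tests on synthetic cohorts therefore demonstrate the pipeline's
internal correctness -- calibration, recovery of injected truth, exclusion
of SNP profiles -- not performance on real plasma data, where error
processes are heavier-tailed and annotation is noisier.

## Problem sizes and runtime

The shipped test and acceptance configurations use the desk-scale defaults:
one full 24-patient, 1500-position cohort call; a 50-repeat LOD benchmark
plus a 25-repeat 3x3 monotonicity grid; 2000 null replicates for
calibration; and a 400-position zero-injection cohort for the false-positive
budget. Together they run in a few minutes on one core; all heavier scales
(panel-scale positions, more repeats) are reachable through the same
configuration objects.
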