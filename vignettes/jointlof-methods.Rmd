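---
title: "jointlof: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{jointlof: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointlof)
```

jointlof models a two-arm loss-of-function study of an RNA-binding protein:
a knockout (KO) arm and a mutant arm in which the protein's nuclear
localization signal is disrupted (NLS), each profiled by RNA-seq in several
independent datasets, with wild-type (WT), heterozygous (HET) and homozygous
(HOM) genotypes. The scientific question is whether the NLS mutation behaves
as a *partial* loss of function: the same genes and splicing events should
respond in both arms, in the same direction, with the NLS effect a constant
fraction of the KO effect. That fraction is the attenuation slope; the
analogous heterozygote-on-homozygote slope quantifies gene dosage.

All computation lives in the package; the numbered scripts under `analysis/`
are thin drivers that move data through files, and `run_all()` executes the
same stages in one call.

## Differential expression

`fit_de()` fits, per gene, a negative binomial GLM with a log link:

* design `~ genotype` per dataset, or `~ genotype + dataset` when
  `joint = TRUE` and more than one dataset is present (the "joint model");
  genotype is coded WT vs one non-WT genotype, so HOM and HET are separate
  comparisons;
* offset `log(size factor)`, with median-of-ratios size factors
  (`size_factors()`) rescaled to geometric mean 1;
* dispersion from `estimate_dispersion()`: a pooled method-of-moments
  estimate per gene (`Var = mu + alpha * mu^2` within each
  dataset-by-genotype group), shrunk 50/50 toward a fitted `a/mu + b` trend.
  This replaces Cox–Reid adjusted profile likelihood deliberately: it is an
  order of magnitude simpler and is adequate at the sample sizes tested;
* a Wald test on the genotype coefficient referred to a *t* distribution
  with `n - p` degrees of freedom rather than a normal. With a plug-in
  dispersion the normal reference is anti-conservative at a few samples per
  group; the t reference brings the simulated type-I error at the 0.05 level
  into the 0.03–0.07 band (tested in `test-acceptance.R`).

There is no Bayesian shrinkage of fold changes: acceptance rests on
synthetic parameter recovery, where the MLE is unbiased.

## Differential splicing usage

Events are inclusion/exclusion read-count pairs with a JSON descriptor of
their junction geometry. `classify_event()` assigns exactly one of
`retained_intron`, `cassette_exon`, `alt5`, `alt3`, `complex`, `other` from
that geometry, strand-aware for donor/acceptor distinctions.

`fit_usage()` tests differential usage per event:

1. fit binomial logistic GLMs (full: genotype, plus a dataset covariate in
   the joint model; reduced: without genotype);
2. estimate an intraclass correlation `rho` by method of moments from the
   full model's Pearson statistic;
3. if `rho <= 0`, use the binomial likelihood-ratio test; otherwise
   maximize the fixed-`rho` beta-binomial likelihood for both designs
   (BFGS, binomial coefficients as starting values) and form the LRT;
4. refer the statistic to chi-squared with one degree of freedom; the
   genotype coefficient divided by `log(2)` is reported as
   `log2_usage_fc`, and mean PSI differences as `delta_psi`.

PSI is inclusion over total (`compute_psi()`); totals below `min_total`
(default 10) are flagged, and events with no adequately covered sample are
reported as NA rather than dropped. `classify_cryptic_skiptic()` labels
cassette exons essentially absent in WT that gain inclusion (cryptic) or
constitutively included exons that lose it (skiptic); its thresholds
(0.05 / 0.95 / 0.10) are configurable defaults, not values fixed by the
modelled study.

## Overlap, attenuation and dosage

`classify_overlap()` compares two result tables over their common features:
`shared_strict` (FDR < alpha in both), `shared_relaxed_only` (FDR < alpha
in one, raw p < alpha in the other), `ko_specific` / `nls_specific`, and
`neither`; ties at exactly alpha are non-significant.
`direction_concordance()` counts opposite-signed shared effects.
`fit_attenuation()` is ordinary least squares with intercept of the NLS
effects on the KO effects — the near-zero intercept is itself a sanity
check — and also reports the through-origin slope. `fit_dosage()` applies
the same estimator to heterozygote-on-homozygote effects.
`intersect_sets()` gives the two-sided Fisher test of two feature sets in a
common universe.

A caveat demonstrated by the analysis scripts at small sizes: selecting
shared features by significance before regressing induces selection bias,
and estimation noise in both variables attenuates the OLS slope downward
(regression dilution). The acceptance targets therefore recover the printed
coefficients from paired effects generated directly at the stated sizes and
noise levels (`simulate_paired_effects()`), which is also what the
published regressions describe.

## Enrichment against matched nulls

`match_null()` builds a null feature set with no evidence of an effect
(raw p > 0.05 in both models) whose lengths and expression both lie within
the test set's closed interquartile range — length and abundance are the two
main confounders of cluster overlap. `overlap_test()` compares same-strand
any-base cluster overlap proportions with a two-proportion chi-squared test
without continuity correction; `conservation_test()` does the same for the
proportion of regions with weighted-median per-base conservation strictly
above a threshold (default 0.5; 0 is neutral, above 1 highly conserved),
excluding unscored bases as missing rather than zero. `feature_profile()`
partitions genes (`build_partition()`: CDS > UTR > intron precedence, a 5 kb
3' extension, and a 5 kb antisense promoter flank) and Bonferroni-corrects
over the family of tests actually run. `proximity_flag()` distinguishes
overlapping, within-distance and distant clusters.

## The synthetic generator

`sim_config()` fixes the study: 3 datasets, two arms, three genotypes, NB
counts with `mu = sf * baseline * 2^(dataset_shift + lfc * dose)` where the
HET dose is 0.5, and NLS effects exactly `attenuation` (default 0.76) times
the KO effects for shared genes. Splicing events draw
`Binomial(Poisson(depth), logistic(logit(base_psi) + shift * dose))` totals,
with regulated events always retained introns (`psi_shift` on the logit
scale, default -1.5). Clusters are placed in introns with odds multiplied by
`clip_enrichment` (default 5) over regulated introns; conservation is
`N(conservation_shift * regulated, conservation_sd)` in 25 bp bins. Each
stage derives its seed as `seed + offset`, so stages are independently
reproducible, and `write_fixture_bundle()` is byte-stable for a fixed
configuration.

The generator's defaults are the study conditions used by the acceptance
suite; they were not adjusted to test outcomes. Scope limits: one synthetic
contig, non-overlapping genes, no simulated alignment noise or unannotated
transcription, and equal library depth up to the simulated size factors.

## Problem sizes and numerical choices

The test suite runs at desk scale: 2,000 genes / 1,000 events for type-I
calibration, 500 replicates of 300-vs-300 introns for the null-uniformity
check, 100 bundles of 500 events for enrichment power, and regression
recovery at n = 1,300 / 405 / 115 / 34 pairs. Tables serialize through
`write_results()` at `%.12g` so fixed-seed runs are byte-reproducible
(acceptance criterion 8). Coordinates are 0-based half-open (BED
convention) everywhere inside the package; GTF input is converted on read
and back on write, and `intervals_to_granges()` is the single conversion
point to Bioconductor's 1-based ranges.

## Limitations

* No read-level event discovery: events are given as count pairs, not
  derived from alignments.
* No outlier handling or independent filtering in the NB model.
* The beta-binomial uses a shared, plug-in `rho` per event rather than
  profiling it; at very low coverage the test falls back to binomial.
* Matched-null construction needs enough unaffected features; small runs
  warn when the null set is smaller than the test set.
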