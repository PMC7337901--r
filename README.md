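# jointlof

Joint multi-dataset differential expression and splicing analysis with
loss-of-function quantification, for two-arm perturbation studies of an
RNA-binding protein.

## The question

ALS-causing mutations in the RNA-binding protein FUS cluster in its nuclear
localization signal (NLS) and reduce its nuclear concentration. Is such a
mutation a *partial loss of function* at the transcriptome level? The
package operationalizes that question: analyze a knockout (KO) arm and an
NLS-mutant arm, each profiled by RNA-seq in several independent datasets
with WT/HET/HOM genotypes, and ask whether

1. the same genes and splicing events respond in both arms
   (strict/relaxed overlap classification),
2. they respond in the same direction (concordance), and
3. the NLS effect sizes are a constant fraction of the KO effect sizes —
   the OLS **attenuation slope**, with the analogous heterozygote-on-
   homozygote slope quantifying gene **dosage**.

Supporting evidence comes from enrichment of retained introns in
protein-binding (iCLIP-style) clusters and in evolutionary conservation
(phyloP-style scores), always against length- and expression-matched null
sets.

## What is implemented

* `core I/O`: counts + sample sheets, BED, bedGraph, GTF (0-based
  half-open internally), result TSVs — with line-level validation errors.
* `diffexpr`: median-of-ratios size factors, method-of-moments NB
  dispersion with trend shrinkage, per-gene NB GLM Wald tests with a
  dataset covariate (the "joint model") and a small-sample t reference.
* `splicing`: PSI, descriptor-based event classification (retained intron,
  cassette exon, alt 5'/3', complex), beta-binomial usage LRT with
  binomial fallback, cryptic/skiptic cassette-exon labels.
* `joint_overlap`: strict/relaxed overlap labels, direction concordance,
  attenuation and dosage regressions, Fisher set intersections.
* `enrichment`: matched nulls, two-proportion chi-squared cluster-overlap
  and conservation tests, genomic feature partition and binding profile,
  proximity flags.
* `synthetic_data`: a fully seeded generator of multi-dataset fixtures
  (counts, events, GTF, clusters, conservation track) with known ground
  truth, so every stage is testable end to end.
* `pipeline`: `run_all()` / `report()` and the numbered drivers under
  `analysis/`.

See `vignettes/jointlof-methods.Rmd` for the modelling assumptions and
design decisions.

## Worked example

```r
library(jointlof)
cfg <- run_config(sim = sim_config(n_genes = 600, n_events = 400, seed = 1),
                  out_dir = "results/run", force = TRUE)
run_all(cfg)
writeLines(report("results/run"))
```

Output from this exact configuration (seed 1):

```
jointlof run summary
====================

Overlap label counts:
        set               label   n
 expression         ko_specific  31
 expression             neither 503
 expression        nls_specific   5
 expression shared_relaxed_only  13
 expression       shared_strict  48
   splicing         ko_specific   3
   splicing             neither 357
   splicing       shared_strict  40

Direction concordance:
        set n_concordant n_discordant
 expression           59            2
   splicing           40            0

Attenuation / dosage regressions:
                    fit     slope  intercept slope_origin r_squared
 attenuation_expression 0.6988971 -0.1166368    0.6944715 0.8883095
   attenuation_splicing 0.3519330 -0.8484231    0.7411333 0.1579568
     dosage_splicing_KO 0.3850372 -0.2582867    0.5044602 0.6140425
    dosage_splicing_NLS 0.3336183 -0.2561913    0.4915519 0.1163224
          f_p  n
 9.036134e-30 61
 1.110179e-02 40
 8.484062e-10 42
 3.126391e-02 40
```

The generator's true expression attenuation is 0.76; the estimate from 61
significance-selected genes (0.70) illustrates the selection bias and
regression dilution discussed in the vignette, which is why the acceptance
targets regress paired effects generated directly at the stated sizes.

The same stages can be run file-by-file:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_splicing.R
Rscript analysis/04_overlap.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_report.R
```

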