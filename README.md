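# exonDCCA

Analysis of paired (baseline vs. 24h post-treatment) blood exon-array
expression profiles, built for translational substudies where each patient
is profiled twice and the question is which genes a therapy dysregulates
within the first day — and whether expression predicts the clinical course.

The package implements four connected pieces:

1. **Dually constrained correspondence analysis (DCCA).** Correspondence
   analysis of the stacked baseline/24h table with linear constraints on
   both sides: the per-patient effect is partialled out of the rows
   (within-patient constraint), the remainder is projected onto the
   baseline-vs-24h contrast (between-time constraint), and column profiles
   are projected onto the within-gene exonic grouping, so every probe set
   of a gene shares one signed score. With two time levels a single axis
   remains; genes ranked by |score| give the most dysregulated list, signs
   giving the direction of the 24h shift. All projections are computed as
   mass-weighted group averages — never as dense projector matrices — so
   the fit scales to exon-array-sized tables.
2. **Hypergeometric gene-set enrichment** of candidate lists against GMT
   collections (upper-tail P(X ≥ k), universe = genes on the filtered
   array).
3. **Per-gene predictive screening** of clinical endpoints — logistic
   (disease stabilization), linear (tumor shrinkage), Cox proportional
   hazards (time-to-progression, overall survival) — adjusted for EGFR
   mutation status, selecting markers at raw p < 0.001.
4. **Metagene survival classifier.** Selected genes are combined by
   unscaled (covariance) PCA into one score per patient; the median splits
   the cohort into low/high risk; Kaplan–Meier curves, log-rank test and a
   (mutation-adjusted) Cox hazard ratio quantify the separation.

A synthetic-data generator reproduces the design's statistical structure —
dominant within-patient correlation, small consistent planted 24h shifts,
exonic grouping, censored proportional-hazards endpoints — so the entire
pipeline is testable against known ground truth without any external data.

## Worked example

```r
library(exonDCCA)

sim <- simulate_dataset(sim_config(
  n_patients = 40, n_genes = 500, exons_per_gene = c(3, 6),
  n_dysregulated = 50, effect_size_log2 = 0.15,
  patient_sd = 0.5, noise_sd = 0.2, seed = 1))

fit <- dcca_fit(sim$expr)
fit
#> dcca_result: 500 genes, constrained inertia 1.396e-05 (1.63% of total)
#> top genes:
#>    gene_id       score direction
#> 1 gene0415 -0.01445046      down
#> 2 gene0395 -0.01348159      down
#> 3 gene0298 -0.01343109      down
#> 4 gene0411 -0.01314677      down
#> 5 gene0389  0.01297906        up

top <- top_dysregulated(fit, 50)
mean(names(sim$truth$dysregulated_genes) %in% top$gene_id)
#> [1] 1
```

The constrained axis carries ~2% of the table's total inertia — the 24h
effect is small against between-patient variation, exactly the regime the
design targets — yet all 50 planted genes are recovered in the top 50, each
with the planted sign. Downstream:

```r
g24 <- gene_level_matrix(sim$expr, "h24")
scr <- screen(g24, sim$clinical, "ttp_be")     # Cox + mutation adjustment
mg  <- fit_metagene(g24[, scr$selected, drop = FALSE])
evaluate_survival(mg, sim$clinical, "ttp_be", adjust_mutation = TRUE)
```

which prints the hazard ratio of the high- vs low-risk median split with
its 95% CI, the log-rank p-value and the per-class median
time-to-progression. `run_pipeline(pipeline_config(...))` chains all stages
(filter → DCCA → top-k → enrichment → screening → metagene → survival) and
writes every intermediate table plus a JSON manifest.

Two published reference lists ship as plain-text fixtures:
`ref_top100_genes()` (100 genes, 54 up / 46 down at 24h) and
`ref_predictive_ttpbe_24h()` (the 91 genes of the time-to-progression
metagene). They are provided for annotation and comparison, not consumed by
any computation.

A thin command-line wrapper with `simulate`, `filter`, `dcca`, `enrich`,
`screen`, `metagene` and `run` subcommands is installed at
`inst/cli/exondcca`.

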