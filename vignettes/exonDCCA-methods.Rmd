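---
title: "Constrained ordination of paired exon-array profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained ordination of paired exon-array profiles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonDCCA)
```

## The problem

A blood sample is profiled on a whole-genome exon array at baseline and again
24h after a patient starts a targeted therapy. Across a cohort this yields a
pair of fully matched tables — exon-level intensities per patient at two time
points. Two questions drive the analysis:

1. Which genes shift consistently within the first 24h of treatment
   (early pharmacodynamic dysregulation)?
2. Do expression levels (at baseline, at 24h, or their change) predict the
   clinical course — disease stabilization, tumor shrinkage,
   time-to-progression, overall survival?

The within-patient correlation dominates this design: differences between
patients are far larger than the 24h shift inside any patient, and the exonic
probe sets of one gene are strongly dependent. Both structures must be
encoded in the ordination, not left to chance.

## Dually constrained correspondence analysis

Let $X$ be the stacked nonnegative table (rows: patient-by-time observations;
columns: exonic probe sets), $P = X / n$ with $n$ the grand total, row masses
$r = P\mathbf{1}$, column masses $c = P^\top\mathbf{1}$, and standardized
residuals
$$ S_{ij} = \frac{p_{ij} - r_i c_j}{\sqrt{r_i c_j}}. $$
Plain correspondence analysis is the SVD of $S$; the total inertia
$\sum_k \sigma_k^2$ equals the table's $\chi^2/n$.

The constrained fit applies three projections to $S$, in this order:

* **(a) within-patient partialling** — the span of the per-patient indicator
  design is removed under the $r$-weighted inner product, deleting all
  between-patient variation;
* **(b) between-time constraint** — the residual is projected *onto* the span
  of the two time-level indicators; with two levels at most one axis remains;
* **(c) within-gene constraint** — column profiles are projected onto the
  span of the per-gene indicators under the $c$-weighted inner product, so
  every exon of a gene receives the same score.

For disjoint indicator groups each projection is exactly a mass-weighted
group average (per patient, per time level, per gene). The implementation
computes them that way and extracts the single axis from the compressed
$2 \times G$ core table (time levels by genes), so no dense projector is
ever formed and the cost is linear in the number of table entries. A
brute-force reference that does materialize the dense weighted projectors is
kept in the test suite and the acceptance script; the two routes agree to
$10^{-10}$ on randomized instances, which pins the optimized code to the
operator chain above.

Because the SVD sign is arbitrary, the axis is oriented so that the 24h
class score is nonnegative: a positive gene score means up-regulation at
24h. Genes are ranked by the absolute value of their constrained coordinate
(ties broken alphabetically); a `ranking = "contribution"` option ranks by
mass-weighted squared coordinate instead, as a sensitivity analysis. Singular
values below $10^{-12}$ of the total-inertia scale are treated as zero, so a
dataset whose 24h block equals its baseline block yields an exactly null
axis rather than numerical noise.

Inputs must be nonnegative (they are RMA-type log2 intensities, which are
essentially always positive); negative values are rejected rather than
clipped, since a negative entry indicates a preprocessing error rather than
a value to repair.

## The synthetic-data generator

Every downstream stage is exercised on simulated cohorts with known ground
truth. The generator emulates the study conditions rather than idealized
ones: 43 patients by default, paired baseline/24h observations whose
between-patient spread (SD 0.5 on the log2 scale) dominates the planted 24h
shifts (0.15 by default — small against the patient effect, consistent
across exons of a planted gene), within-gene exonic structure (4–18 probe
sets per gene genome-wide; desk-scale runs use 1–6), a mutation covariate at
5/43 prevalence, and censored time-to-event endpoints. Intensities sit
around a log2 mean of 7 and are clipped at 0.01 to respect the
nonnegativity precondition of correspondence analysis.

Survival follows an exponential proportional-hazards model: the linear
predictor sums, over the planted predictive genes, a common log-hazard
coefficient times the centered 24h gene-level expression. Baseline medians
are anchored at realistic values for this population (4.0 months for
progression under therapy, 2.6 under subsequent chemotherapy, 11.1 for
overall survival). Censoring is an independent exponential whose rate is
calibrated so that the requested fraction (default 30%) is censored under
the null. The binary stabilization endpoint is Bernoulli with a logit
decreasing in the same predictor (53% prevalence at null); the continuous
shrinkage endpoint is Gaussian around a decreasing linear function of it
(centered at 15.8%).

The random stream is split into deterministic per-block sub-streams (gene
effects, exon structure, patients, expression noise, endpoints), so adding
patients never perturbs the gene-level draws and identical configurations
reproduce byte-identical datasets.

What the generator does *not* emulate: probe-level hybridization and RMA,
batch effects, exon-specific (splicing-like) treatment effects, and
correlation between genes beyond the shared patient effect. Passing the
planted-recovery tests therefore shows that the machinery isolates a paired
time effect of realistic size under realistic within-patient correlation —
not that any particular biological list in real data is correct.

## Enrichment, screening, metagene

**Enrichment.** Candidate lists are tested for over-representation in GMT
gene sets by the upper-tail hypergeometric probability $P(X \ge k)$, with
the universe defaulting to all genes on the filtered expression matrix (the
background actually available to the experiment). Only over-representation
is tested, and raw p-values are reported by default with an optional
Benjamini–Hochberg column — matching the convention of reporting unadjusted
enrichment p-values for candidate lists of this size.

**Screening.** Each gene is tested one at a time against each endpoint with
the model family the endpoint dictates — logistic for binary, linear for
continuous, Cox proportional hazards (Efron ties) for time-to-event — with
mutation status as an adjustment covariate. Wald tests are used throughout:
at genome scale the per-gene likelihood-ratio refit roughly doubles the
cost for negligible gain at these sample sizes. Selection uses the raw
threshold $p < 0.001$ with no multiplicity correction, which is the
discovery convention this screening design follows; the BH column is
informational. Degenerate fits (zero-variance genes, separation,
non-convergence) are flagged and reported with $p = 1$ rather than dropped,
so the output table always has one row per gene. A mixed-effects variant
(random intercept per patient, both time points stacked) is exposed for
patient-level endpoints analyzed jointly across time; the default for
change analyses is the simpler change-score model.

**Metagene.** A candidate list is combined into one score per patient by
*unscaled* PCA — column-centered, never variance-scaled, because the genes
share a measurement scale and their variances are informative. The first
right singular vector (unit norm) gives the loadings; scores are the
projections of centered profiles. The median of the scores splits the
cohort into two near-equal classes, ties going to the low class for
determinism. Since the PCA axis sign is arbitrary, risk labels are anchored
to outcome: after computing Kaplan–Meier curves per class, the class with
the shorter median event time is called high-risk. This makes every
reported statistic invariant to a global sign flip of the loadings, which a
dedicated test asserts. Survival separation is summarized by the two-sample
log-rank test, per-class KM medians with log-log 95% confidence intervals
("not reached" encoded as `NA` when a curve never crosses 0.5), and the
hazard ratio of the binary class from a Cox fit, optionally
mutation-adjusted. A class with zero events leaves the hazard ratio
non-estimable while the log-rank test is still returned.

## Numerical and design choices

* **Order of row-side projections**: patient removal precedes the time
  projection. The two spans share the constant vector, so projecting onto
  time first would leak between-patient variation into the time axis.
* **Tie-breaks**: gene ranking ties break lexicographically by gene id;
  score-equal-to-median goes to the low class. Both rules are arbitrary but
  deterministic, which matters more.
* **Zero handling**: all-zero rows or columns are an error naming the
  offender (a zero column has no chi-square profile); exact-zero scores are
  excluded from top-$k$ lists because they carry no direction.
* **Tolerances**: $10^{-12}$ relative for treating singular values as zero;
  $10^{-10}$ for the dense-oracle equivalence bound (dominated by the dense
  reference's own conditioning, not the optimized path).
* **Problem sizes**: the test and acceptance simulations use 12–80 patients
  and 60–2000 genes with 1–6 exons per gene — large enough that recovery,
  calibration and coverage are measured with useful precision, small enough
  to keep the whole suite interactive. The calibration checks that compare
  empirical p-value distributions to the uniform use generator settings
  with no shared patient effect, since those comparisons assume approximate
  independence across genes.

## Reference lists

Two published gene lists are shipped as plain-text fixtures: the 100 genes
most dysregulated at 24h (54 up, 46 down) and the 91 genes whose 24h
expression predicted time-to-progression under therapy (the members of the
91-gene metagene). They are provided for annotation and comparison — no
computation in this package consumes them, and reproducing their exact
identities from raw public data would additionally require the original
array annotation vintage, which is out of scope.

## Known limitations

* The clinical-cohort hazard ratios and enrichment p-values of the original
  study depend on its deposited raw data and 2016-era pathway databases;
  this package reproduces the method, and validates it on synthetic ground
  truth, not those exact numbers.
* The permutation null for the constrained inertia flips time labels within
  patients; it is exact for exchangeable pairs but does not address
  exon-level dependence beyond what the constraint structure encodes.
* The generator's endpoints share a single linear predictor; differential
  predictive structure across endpoints is not simulated.
* `screen_mixed` covers patient-level endpoints only; a repeated-measures
  survival formulation (time-varying expression) is not implemented.
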