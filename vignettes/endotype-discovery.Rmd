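---
title: "Serum proteomics endotyping with proteoclust: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum proteomics endotyping with proteoclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoclust)
```

## The problem

Aptamer panels (SOMAscan-style assays) quantify ~1300 serum proteins per
patient as relative fluorescence units (RFU). In chronic obstructive
pulmonary disease (COPD), such profiles can stratify patients into
molecular subtypes — *endotypes* — that align with clinical burden
(emphysema, exacerbations, comorbidities). `proteoclust` packages the full
analysis path for this kind of study: intensity standardization,
unsupervised two-cluster discovery, moderated differential expression
(DE), a per-patient protein score, pathway over-representation, a short
biomarker signature, clinical association statistics, and two forms of
validation — agnostic re-clustering of an independent cohort and
paired-visit cluster-switching analysis. A synthetic cohort generator with
planted ground truth makes every stage testable end to end.

## The pipeline and its assumptions

### Standardization

Raw RFU intensities carry per-sample hybridization drift and per-plate
scale effects. `standardize()` removes them with four median-ratio steps:

1. *Hybridization normalization.* Each sample is divided by the median
   ratio of its hybridization-control probes to the probes' run-wide
   medians, iterated to the fixed point where all ratios are 1. The
   hybridization columns are left untouched afterwards, so this per-sample
   correction is final.
2. *Plate scaling* and 3. *median signal normalization.* Per-plate and
   per-sample median-ratio scalings of the assay columns, alternated until
   both constraints hold simultaneously: every plate's assay median and
   every sample's assay median equal the respective run-wide reference.
   With an odd number of assay proteins the alternation reaches the joint
   fixed point in about two passes, to machine precision — once every
   sample median equals $m$, each plate's pooled median is $m$ as well.
4. *Calibration.* Each calibrator probe is scaled, per plate, to the
   per-probe reference (its run-wide median, or the medians of an external
   reference run). A calibrator-derived correction for the assay columns
   would be a plate scalar, which step 2 has already fixed; calibration
   therefore reconciles the plate-alignment standards without disturbing
   the assay fixed points.

This arrangement is deliberate. Naively re-estimating every step from the
full matrix sets up conflicting exact median constraints (the
hybridization and sample-median steps share one degree of freedom per
sample; per-plate and per-protein-per-plate constraints are
over-determined), and the sequence then oscillates at about the residual
noise level instead of converging. Partitioning the constraints as above
makes the composite map a *projection*: `standardize()` applied to its own
output is the identity (within `tol`, default 1e-10), which the test suite
checks at 1e-9.

The attribute `sample_factors` returns each sample's recovered technical
scale factor. On biology-free simulated cohorts with pronounced technical
effects it correlates with the planted factors at r > 0.99; under the
default disease scenario the correlation is closer to 0.98 because the
sample-median step inevitably absorbs some subject-level median jitter,
including a small shift induced by the 90-protein up-regulation itself.

All downstream analysis uses `log2_transform()`ed values.

### Cluster discovery

`select_variable_proteins()` ranks assay proteins by their log2 standard
deviation across subjects (log2 is already variance-stabilized, so plain
SD rather than CV) and keeps the top `floor(fraction * panel)` — 130 of
1305 at the default 10%. `hierarchical_cluster()` z-scores the selected
proteins, clusters subjects with Euclidean distance and Ward linkage, and
cuts the tree at k = 2. Distance, linkage and standardization are the
standard heatmap-clustering defaults and are configurable; nothing in the
method requires them specifically, but they recover planted balanced
groups reliably (adjusted Rand index ≥ 0.9 across seeds in the test
suite).

Raw group numbers from a dendrogram are arbitrary, so
`canonicalize_labels()` fixes the identity: the group with more
significantly *up*-regulated proteins becomes **Cluster 2** (the
broad-up-regulation endotype); a tie falls back to the higher mean protein
score. All reported results use canonical labels.

### Differential expression

`moderated_ttest()` implements the empirical-Bayes moderated t: per
protein, the pooled two-group residual variance $s_g^2$ (with $d$ degrees
of freedom) is shrunk towards a prior $s_0^2$ with $d_0$ prior degrees of
freedom estimated from all proteins by matching the first two moments of
$\log s_g^2$ to its scaled-F sampling distribution ($d_0$ solves a
trigamma equation by Newton iteration). The moderated statistic

$$ t_g = \frac{\bar{x}_{2g} - \bar{x}_{1g}}
{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}}, \qquad
\tilde{s}_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d} $$

is referred to $t_{d_0 + d}$. Setting `prior_df = 0` recovers the ordinary
equal-variance t-test exactly; `prior_df = Inf` gives the fully pooled
z-like statistic. In the finite-prior regime the implementation agrees
with the established empirical-Bayes fit to ~1e-12 (cross-checked against
an independent implementation in the test suite).

Significance follows the magnitude-plus-FDR rule used throughout:
fold change $2^{|\mathrm{log2FC}|} > 1.5$ **and** Benjamini–Hochberg
q < 0.05, both strict. Testing spans all assay proteins, not just the
clustering panel (a `proteins` argument restricts it if desired).

### Protein score and signature

The **protein score** of a subject is the median log2 expression over a
designated up-regulated set — canonically the proteins up in Cluster 2 of
the learning cohort. Medians make the score insensitive to any single
aptamer. Score separation between clusters is tested with a two-sided
Wilcoxon rank-sum (exact for small tie-free groups); the method reports
medians and a p-value, and the rank-sum is the natural test for that
summary.

`select_signature()` distills the DE table into a short fingerprint
(default 11 Cluster-2 + 4 Cluster-1 members). The Cluster-2 side takes the
top 10% of up-regulated proteins by |log2FC|, maps each candidate to its
most-enriched annotated pathway family, ranks candidates within a family
by their strongest clinical odds ratio, and collects one representative
per family per round, families visited in enrichment order, until the
target size is reached — a deterministic operationalization of "most
differentially expressed, representative of enriched pathways, highest OR
within pathway". The Cluster-1 side drops an exclusion list (markers that
failed external replication) and keeps the top 4 by |log2FC|. Every
decision lands in a selection log; the whole procedure is a pure function
of its input tables, with ties broken by protein id. When fewer candidates
exist than requested (e.g. 9 = top 10% of 90 candidates against a target
of 11), all are returned and the shortfall is logged rather than padded
silently.

### Enrichment and clinical statistics

`enrich()` is upper-tail hypergeometric over-representation against a
term → protein annotation, BH-adjusted across terms, with the universe
defaulting to all assayed proteins (the panel defines the sampling frame).
`overlap_enrichment()` reports the intersection of two protein sets, the
integer percentage of the second set, and the hypergeometric tail p.
Because real GO mappings of aptamer targets are out of scope, a
`synthetic_annotation()` builder ships for exercising these paths.

`compare_clinical()` reproduces clinical baseline tables: equal-variance
two-sided t for continuous variables, two-tailed Fisher exact
(probability-mass rule) for categorical ones, per-variable missing-value
handling with reported n. `fisher_exact()` reports the sample odds ratio
ad/bc (flagging infinities) rather than the conditional-ML estimate, with
the exact two-sided p. `protein_outcome_or()` fits univariable logistic
models of a binary outcome on standardized expression, so odds ratios are
**per SD of log2 expression** — the unit matters for magnitudes and is
configurable (`unit = "log2"` for per-log2-unit ORs); Wald 95% intervals,
BH across proteins within outcome, and complete-separation flagging are
included. No covariate adjustment is done, matching the univariable
design.

### Validation and switching

`transfer_validate()` re-runs the *entire* discovery stage on a new cohort
alone — the learned results enter only afterwards, as the score set and
the overlap reference — so validation is agnostic to the learning cohort.
`switching_analysis()` cross-tabulates independently clustered visits and
adds a third destination, *mixed*, for subjects whose visit-2 score falls
in the central band of the gap between the two visit-2 cluster score
medians (band fractions (0.25, 0.75) of the gap by default). A
quantile-based zone tied to the clusters' own score distributions was
rejected: a cluster's lower quartile always leaves a quarter of its
members beyond it, so such a rule labels ~25% of *every* cluster mixed
even when no mixed profiles exist. The band rule is explicitly an
operational definition — the underlying notion of a "mixed profile" has no
unique definition — and a zero-width band (`band = c(0.5, 0.5)`) reduces
the analysis to a plain 2×2 transition table. Concordance counts
non-mixed identities preserved across visits; a Fisher exact test runs on
the 2×2 collapse with mixed folded into Cluster 1 (the origin of mixed
profiles).

## The synthetic cohorts

`generator_config()` plants: two clusters of fixed sizes; `up_in_c2` /
`up_in_c1` proteins shifted additively on the log2 scale by per-protein
effects drawn once from `effect_log2fc_range`; Gaussian within-group noise;
per-plate and per-sample multiplicative technical effects on the raw
scale; control probes carrying technical signal only; and
cluster-conditional binary covariates. Paired designs add a transition
structure; mixed-profile subjects keep their Cluster-1 profile and gain
50% of every Cluster-2 effect (the natural reading of "combining both
signatures"; the fraction is a parameter).

Defaults were fixed once, before any tuning against outcomes:

| parameter | default | why |
|---|---|---|
| `noise_sd` | 0.5 log2 | typical within-group spread of serum aptamer data |
| `baseline_log2_mean`, `sd` | 10.6, 1.5 | matches the ~10.6 median log2 signal of healthy serum panels |
| `effect_log2fc_range` | [0.8, 1.5] | clears the 1.5-fold (0.585 log2) call threshold with DE power ≈ 1 at ~120/group |
| `plate_shift_sd`, `hyb_drift_sd` | 0.2, 0.15 log2 | moderate, realistic technical effects |
| `n_plates` | 3 | ~80 samples/plate for a 241-subject run |
| control probe noise | 0.05 log2 | spiked controls vary far less than analytes |

Named scenarios pin the study designs: `cobra_v1` (241 × 1305, clusters
126/115, up-sets 90/6, five Table-2-style covariates), `mlcc` (47, 34/13,
114 up-C2 of which 71 re-planted from the cobra up-set, 6 disjoint
up-C1), `paired_visits` (163; stay-1 = 68, stay-2 = 40, mixed = 29,
switch = 26, hence 97/66 at visit 1), `healthy` (50, nothing planted).
Each scenario has a fixed default seed so the test suite is deterministic;
`scripts/acceptance.R` re-derives seeds from its `--seed` argument.

What the generator does *not* emulate: aptamer chemistry, detection
limits, missingness, heavy-tailed or correlated noise, batch-by-biology
confounding, dilution-group structure beyond a single group. Passing
recovery tests therefore demonstrates that the pipeline's inference is
correct *under its own model*, not that real cohorts will behave as
cleanly; on real data the recovered structure is weaker and the clustering
panel noisier.

## Numerical choices and degenerate inputs

- Median-based normalization iterates to `tol = 1e-10` with a 100-pass
  cap; zero control/plate/sample medians raise errors, as does
  re-normalizing an already-normalized matrix (override with `force`).
- Variance selection uses `floor()` and breaks SD ties by protein id;
  clustering is deterministic for fixed input.
- Constant proteins under `prior_df = 0` get p = 1 and a `degenerate`
  flag instead of NaN; a zero-variance clustering panel errors.
- Logistic fits run IRLS to relative tolerance 1e-8 (≤ 100 iterations);
  |coefficient| > 15 or non-convergence is flagged as separation.
- Signature selection, enrichment and overlap routines are pure functions
  of their inputs; all orderings are tie-broken by id.

## Problem sizes in the test suite

Property-style simulations use a reduced cohort (120 × 600, clusters
64/56, up-sets 40/3) over 20 seeds, which preserves the signal-to-noise
regime of the full scenarios at a fraction of the cost; end-to-end checks
run the full 241 × 1305, 47 × 1305 and 163 × 1305 scenarios once each.
The healthy-cohort type-I simulation uses 100 replicates: the measured
rejection rate of the score test under forced null splits is ~5%, and at
20 replicates the binomial noise of the estimate (sd ≈ 5%) would
occasionally cross the 10% bound that the property asserts.

## Known limitations

- The four standardization steps are a self-consistent reinterpretation of
  a vendor pipeline whose exact formulas are proprietary; they are
  reproducible and idempotent but not bit-compatible with any vendor
  output.
- The mixed-profile rule and the per-SD odds-ratio unit are explicit
  conventions; results quoting them should say so.
- The signature's family-quota procedure resolves a narrative ranking into
  an algorithm; other faithful operationalizations exist and would pick
  different representatives when families are large.
- k = 2 is assumed throughout the acceptance surface; the clustering
  function accepts other k but the canonicalization logic is two-cluster.
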