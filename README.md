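# proteoclust

Serum proteomics endotype discovery and cross-cohort validation.

`proteoclust` is an R package for stratifying patients into molecular
subtypes ("endotypes") from aptamer-based serum proteomics (SOMAscan-style
panels reporting relative fluorescence units for ~1300 proteins), built
around the analysis design used in COPD endotyping studies. It covers the
whole path from raw intensities to validated clusters:

- **Standardization** — the four-step intensity pipeline (hybridization
  normalization, plate scaling, median signal normalization, calibration)
  implemented as median-ratio scalings iterated to a joint fixed point, so
  normalization is an exact projection; then log2 transformation.
- **Cluster discovery** — top-10%-variance protein filter, Ward/Euclidean
  hierarchical clustering of subjects into two groups, and canonical
  labeling: the cluster with more significantly up-regulated proteins is
  *Cluster 2*.
- **Differential expression** — an empirical-Bayes moderated t-test
  (method-of-moments prior on log residual variances, posterior variance
  shrinkage, t on augmented degrees of freedom), with the significance
  rule *fold change > 1.5 and BH FDR q < 0.05*.
- **Protein score** — each patient's median log2 expression over the
  Cluster-2 up-regulated set; rank-sum comparisons across clusters.
- **Enrichment** — upper-tail hypergeometric over-representation of
  protein sets against pathway annotations, and set-overlap enrichment.
- **Signature selection** — a deterministic, logged procedure distilling
  the DE table into a short biomarker fingerprint (default 11 Cluster-2 +
  4 Cluster-1 proteins) by |log2FC|, pathway-family representativeness and
  within-family clinical odds ratios.
- **Clinical associations** — Student t / Fisher exact comparison tables,
  per-protein logistic odds ratios (per SD of expression) with Wald CIs
  and per-outcome FDR, Pearson/Spearman correlations.
- **Validation** — agnostic re-clustering of an independent cohort with
  score transfer and up-set overlap, and paired-visit cluster-switching
  analysis with an explicit mixed-profile zone.
- **Synthetic cohorts** — a generator that plants cluster structure,
  technical effects, covariates and visit-to-visit transitions, so every
  stage is testable without access to patient data.

The moderated statistic for protein *g* between clusters of sizes
*n1*, *n2* is

    t_g = (mean2_g - mean1_g) / ( s~_g * sqrt(1/n1 + 1/n2) ),
    s~_g^2 = (d0 * s0^2 + d * s_g^2) / (d0 + d),

with the prior `(d0, s0^2)` estimated from all proteins by moment-matching
on `log s_g^2`; q-values are Benjamini–Hochberg, and a protein is called
significant when `2^|log2FC| > 1.5` and `q < 0.05` (both strict).

## Worked example

Discover endotypes in the packaged learning scenario (241 subjects × 1305
proteins with planted clusters of 126/115 and 90 + 6 up-regulated
proteins), then validate them in the independent 47-subject scenario:

```r
library(proteoclust)

coh <- generate_cohort(scenario_config("cobra_v1"))
X   <- preprocess(coh$matrix, coh$meta)     # standardize + log2
res <- discover_endotypes(X, coh$meta)

res$clusters
#> ClusterResult: canonical Cluster 1/2; sizes 126/115; panel of 130 proteins

up2 <- up_set(res$de, "up_in_2"); up1 <- up_set(res$de, "up_in_1")
c(total = sum(res$de$significant), up_c2 = length(up2), up_c1 = length(up1))
#>  total  up_c2  up_c1
#>     96     90      6

cmp <- compare_scores(protein_score(X, up2), res$clusters$labels)
cmp$median_by_cluster                        # per-cluster protein score
#> cluster1 cluster2
#> 10.55621 11.69662
cmp$p
#> [1] 5.916094e-41

ml <- generate_cohort(scenario_config("mlcc"))
tv <- transfer_validate(preprocess(ml$matrix, ml$meta), up2, ml$meta)
tv$clusters
#> ClusterResult: canonical Cluster 1/2; sizes 34/13; panel of 130 proteins
tv$overlap$k                                 # learned proteins re-detected
#> [1] 69
```

The pipeline recovers the planted 126/115 split exactly, calls 96
significant proteins (90 up in Cluster 2, 6 in Cluster 1), separates the
protein score by ~1.1 log2 units between clusters, re-finds the 34/13
structure in the second cohort from its own data alone, and re-detects 69
of the 90 learned Cluster-2 proteins there (71 were re-planted).

See the vignette (`vignettes/endotype-discovery.Rmd`) for the models,
parameter choices and limitations, including what the synthetic cohorts do
and do not emulate.

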