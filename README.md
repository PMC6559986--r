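# gliastate

Reactive astrocytes in glioblastoma undergo a transcriptional
re-programming that shifts them along two axes: differentiation (fetal /
progenitor versus adult / mature programs) and reactivity (the
inflammatory "A1" versus the alternative "A2" program), with the
tumor-associated state marked by JAK/STAT activation, proliferation and
CD274 expression. Characterizing that state from bulk expression of
purified astrocytes — and from FACS readouts of slice-culture experiments —
requires a chain of standard but fiddly computations. `gliastate`
implements that chain as a tested R package for computational biologists
who want each step exercisable, seedable and verifiable against planted
ground truth:

- **Normalization and differential expression** — median-of-ratios size
  factors (`s_j = median_g k_gj / (prod_j k_gj)^(1/n)`, rescaled to
  geometric mean 1) and a simplified negative-binomial Wald test: per-gene
  moment dispersions `alpha_g = max(alpha_0, (s² - m)/m²)` pooled within
  conditions, delta-method standard errors, BH-adjusted q-values, plus the
  fold-change rank-shift comparison of the top 30 genes between two
  experimental contexts and one-way-ANOVA/BH group statistics.
- **Subgroup discovery** — partitioning around medoids (exact by
  enumeration on small problems, BUILD+SWAP beyond), silhouette widths
  `s_i = (b_i - a_i)/max(a_i, b_i)` for choosing k and for removing
  negative-silhouette non-core samples, subsampled consensus matrices, and
  marker genes by nearest shrunken centroids
  (`d_ik = (x̄_ik - x̄_i)/(m_k (s_i + s_0))`, soft-thresholded at a
  cross-validated delta) or one-vs-rest logistic Wald scores.
- **Pre-ranked permutation GSEA** — weighted Kolmogorov–Smirnov running
  sum, membership-permutation null with the +1-corrected p, sign-matched
  NES, leading-edge genes, BH FDR across sets.
- **Astrocyte state map** — mean z-score over four signature sets (A1, A2,
  fetal, adult), projected to differentiation `x = fetal - adult` and
  reactivity `y = A2 - A1`, with margin-based state labels and per-cohort
  reports.
- **FACS post-processing** — arcsinh transform, threshold gating with
  attrition reports, per-cell over-dispersion (var/mean, CV², Fano),
  distance-based clustering and t-SNE on post-gating channels, cluster ×
  condition marker summaries.
- **Synthetic data** — NB count matrices with planted fold changes,
  signature injection, and a four-condition FACS preset, all pure functions
  of (parameters, seed).

## Worked example

Simulate a three-group cohort with 10% planted markers (log2 fold change
±2, NB dispersion 0.2), then run the full subgroup pipeline —
normalization, variance filtering, silhouette-selected PAM, core-sample
filtering, shrunken-centroid markers:

```r
library(gliastate)
sim <- simulate_counts(n_genes = 2000, groups = c(g1 = 20, g2 = 20, g3 = 20),
                       de_fraction = 0.1, lfc_magnitude = 2,
                       dispersion = 0.2, seed = 21)
pip <- subgroup_pipeline(sim$counts, seed = 21)
pip$model
#> cluster_model: k = 3, cost = 808.7, mean silhouette = 0.363
#> cluster sizes: 20, 20, 20
head(pip$markers, 3)
#>   class      gene    score sign   delta
#> 1     1 gene_0570 1.191211 down 2.44828
#> 2     1 gene_0037 1.175177 down 2.44828
#> 3     1 gene_1450 1.067207   up 2.44828
mean(sim$truth$de_genes %in% pip$fit$selected)
#> [1] 0.995
```

The three planted groups are recovered exactly (20/20/20, adjusted Rand
index 1.0 on core samples) and 199 of the 200 planted markers survive the
cross-validated shrinkage threshold. Differential expression between two
of the groups puts the planted genes on top:

```r
de <- nb_wald_de(sim$counts, contrast = c("g2", "g1"))
head(de[order(de$padj), c("gene", "log2fc", "pvalue", "padj")], 3)
#>           gene    log2fc       pvalue         padj
#> 968  gene_0968 -2.154838 3.152267e-37 6.304535e-34
#> 1450 gene_1450 -2.712310 3.800214e-27 3.800214e-24
#> 1873 gene_1873  2.034330 8.832584e-26 5.888389e-23
```

A complete narrated run — two-context DE with the rank-shift table, GSEA
against planted sets, the astrocyte state map, and FACS gating through
cluster summaries — lives in the numbered scripts under `analysis/`
(`Rscript analysis/01_simulate.R`, then `02` … `06`); each writes its
tables under `results/`.

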