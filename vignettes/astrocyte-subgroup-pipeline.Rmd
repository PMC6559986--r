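---
title: "Methods: reactive-astrocyte state scoring and subgroup discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactive-astrocyte state scoring and subgroup discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliastate)
```

# Scope

`gliastate` re-implements, as a tested pipeline over synthetic data with
planted ground truth, the computational workflow used to characterize
tumor-associated reactive astrocytes in glioblastoma: median-of-ratios
normalization with a simplified negative-binomial (NB) Wald test,
fold-change rank-shift comparison between experimental contexts,
unsupervised subgroup discovery (PAM, silhouette model selection,
core-sample filtering, nearest-shrunken-centroid markers), pre-ranked
permutation GSEA, four-signature astrocyte state scoring onto a
differentiation/reactivity plane, and FACS post-processing. The numbered
scripts under `analysis/` narrate one full run; every computation lives in
the package so tests can exercise it.

Throughout, expression matrices are genes-as-rows, samples-as-columns.

# Synthetic data: what it emulates, what it does not

`simulate_counts()` draws `counts[g, j] ~ NB(mu = s_j * q_g * 2^(beta_g
x_gj), alpha)` with variance `mu + alpha mu^2` — the same NB family the DE
test assumes. Library factors `s_j` are log-uniform on `[0.5, 2]` (a
realistic bulk depth spread); baselines `q_g` are log-normal (meanlog 4,
sdlog 1.5 in natural log), giving the heavy-tailed abundance distribution
of transcriptome counts; a planted fraction of genes (default 10%) carries
`beta_g = +/-2` in one non-reference group. `dispersion = 0` degenerates to
Poisson, which the tests use to check the variance/mean limit.

`inject_state_signature()` plants a state program by resampling the
signature genes' counts in the target samples from a Poisson law at
`2^effect` times the observed count — integer counts, approximately the
intended fold change, exact identity at effect 0.

`simulate_facs()` draws per-channel log-normal intensities. The default
preset (`facs_preset()`) encodes the four-condition slice design as five
populations over four condition labels: both non-tumor conditions share one
low-STAT3-P/low-KI67 mode; the tumor-injected, microglia-depleted condition
splits into two KI67 levels with low STAT3-P; tumor plus microglia is high
in both markers. The moderate KI67 level (meanlog 5.3) sits midway between
the low (2.0) and high (6.5) levels *on the arcsinh readout scale*, so the
four modes the design implies are actually resolvable; marker shifts span
roughly 30–100x raw intensity with sdlog 0.4, typical for a strong
phospho/proliferation stain.

None of the generators emulate: gene–gene correlation, batch effects,
sample swaps, FACS spectral spillover or doublets, or read-level artifacts.
Passing tests therefore demonstrate correctness of the algorithms under the
assumed models, not robustness to those real-data pathologies.

# Normalization and differential expression

`size_factors()` is the median-of-ratios estimator (per-sample median of
counts over the per-gene geometric mean across samples, computed on genes
positive in every sample), rescaled to geometric mean 1. Note one
consequence of the moving reference: rescaling a single sample's depth by
`c` changes its factor by `c^((n-1)/n)`, not `c`, so per-sample normalized
values are equalized across samples only up to one global constant — the
tests assert exactly that invariant.

The DE test is deliberately *simplified*: per-gene method-of-moments
dispersion pooled within conditions, `alpha_g = max(1e-8, (var - mean) /
mean^2)`; the log2 fold change is the ratio of condition means of
normalized counts (a mean of exactly zero is stabilized to
`pseudocount / n`, so noise-free ratios are reported exactly); the standard
error comes from the delta method under `NB(mu, alpha_g)`; p-values use the
two-sided normal reference and BH adjustment over tested genes (all-zero
genes are flagged, not dropped, and excluded from the BH denominator). No
dispersion shrinkage, no LFC moderation: the target is calibrated type-I
error (the suite checks the 5% rate within [0.03, 0.07] and
Kolmogorov–Smirnov uniformity at distance < 0.05 on 2,000 null genes with
10 samples per group), not numerical identity with any heavier tool.

`fold_change_rank_shift()` ranks genes by decreasing fold change in each of
two contexts (ties broken by gene ID) and reports, for the top 30 genes of
context A, the rank difference in context B. The 12-fold coloring threshold
used in such displays is a flag column, never a filter.

`group_compare()` is the figure-legend statistic: one-way ANOVA per
measurement, BH across measurements; a measurement with identical values
everywhere is defined to give `F = 0, p = 1` (the lm/anova route returns
NaN there).

# Subgroup discovery

`pam_cluster()` implements PAM with greedy BUILD seeding and
steepest-descent SWAP. Because SWAP is a local search, it can stall above
the optimum on small adversarial configurations; when `choose(n, k) <= 200`
the implementation instead enumerates all medoid sets, so small problems
are solved exactly (the suite proves equality with brute force for every
`n <= 8` and every `k`). Silhouette widths follow the classic definition
with singleton clusters assigned width 0; `select_k()` maximizes the mean
width, ties to the smallest k; `core_sample_filter()` drops samples with
negative width before marker fitting. `consensus_cluster()` reports
pairwise co-assignment frequencies over subsampled PAM runs, normalized by
co-sampling counts.

`subgroup_pipeline()` clusters on the 200 most variable genes (Euclidean
distance on log-normalized expression, with a correlation option).
Filtering is essential, not cosmetic: with thousands of genes the distance
is dominated by noise and the silhouette profile flattens toward small k —
on the three-group benchmark, clustering on all 2,000 genes merged two
groups, while any filter in the 100–500 range recovered all three in every
seeded replicate. Aggressive gene filtering before clustering is standard
practice in transcriptome subtype discovery.

## Nearest shrunken centroids

The marker model is written from first principles: standardized contrasts
`d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` with pooled within-class SD
`s_i`, fudge `s0 = median(s_i)` and `m_k = sqrt(1/n_k - 1/n)`; soft
thresholding `d'_ik = sign(d_ik) max(|d_ik| - delta, 0)`; shrunken
centroids `xbar_i + m_k (s_i + s0) d'_ik`; classification by the
diagonal-covariance discriminant with `-2 log pi_k`; tie to the first
class. Genes with zero pooled SD rely on `s0` to stay finite. A 2-class,
4-gene toy with fully hand-computed quantities pins every formula down in
the tests.

The threshold grid is 30 evenly spaced values in `[0, max |d_ik|]`, chosen
by stratified 10-fold cross-validation. The 0-1 CV error saturates at zero
over a wide threshold range whenever classes separate well, and "sparsest
zero-error model" then keeps only a handful of genes — useless as a marker
catalog. Error ties are therefore broken by the cross-validated multinomial
likelihood of the held-out labels (the reference implementation of the
method reports exactly this curve): the likelihood keeps improving while
pure-noise genes are shrunk away and starts degrading once genuinely
informative genes go, so the chosen threshold lands at the boundary of the
informative set. Remaining ties still go to the largest threshold. Classes
with fewer than three members cannot be cross-validated at all; the fit
then falls back to the most permissive threshold and reports an empty CV
table.

`glm_marker_score()` is the alternative marker score: per gene and class, a
one-vs-rest binomial GLM; the score is the signed Wald z of the slope.
Complete separation makes the Wald z collapse while the slope diverges
(Hauck–Donner), and glm may converge silently in that state; separation is
therefore detected from the fitted probabilities and reported as the capped
score (default 10) in the slope's direction, flagged.

t-SNE (via Rtsne, exact mode below 1,000 items, seeded) is used only for
visualization/validation, never inference.

# Pre-ranked GSEA

`gsea_preranked()` implements the weighted running sum: hits add
`|score|^p / sum_hits |score|^p`, misses subtract `1 / (N - |S|)`; the
enrichment score is the maximum-magnitude deviation, with magnitude ties
resolved to the deviation reached first in the walk. The null permutes set
membership over the gene universe (with only a ranking available,
phenotype permutation is undefined); `p = (1 + #{|ES_perm| >= |ES|}) /
(1 + n_perm)`; `NES = ES / mean(|ES_perm| of the same sign)`; BH across
testable sets, with empty-overlap sets reported but excluded from the BH
denominator. Defaults `weight_p = 1`, `n_perm = 1000` (the classic
pre-ranked defaults). An exhaustive enumeration
oracle (all 56 memberships at N = 8, |S| = 3) validates the Monte-Carlo p
against the exact null in the suite.

Because several ranking metrics are equally defensible inputs to
enrichment (fold changes, marker scores, model-based importance
rankings), `make_ranking()` requires an explicit metric
(`log2fc`, `nsc_score`, `glm_score`, `custom`) and bundles no random-forest
ranker; the analysis scripts use `log2fc`.

# Astrocyte state map

Four signature sets named `A1`, `A2`, `fetal`, `adult` (nominally top-50
lists) are loaded from GMT; the published lists are not redistributable
here, so the package ships a clearly labeled synthetic fixture
(`synthetic_state_signatures()`,
`inst/extdata/synthetic_state_signatures.gmt`) and accepts user GMTs.

Scores are mean z-scores: genes are standardized across samples first
(plain means would be dominated by high-abundance genes; `z_score = FALSE`
restores raw means for sensitivity analysis), then averaged within each
set's genes present in the matrix (`min_genes` default 10, below which the
score is flagged). The two axes are score differences — differentiation
`x = fetal - adult`, reactivity `y = A2 - A1` — the minimal construction
consistent with a two-axis state plane; no canonical construction exists
for combining four scores into two axes, so this is a documented
interpretation. Labels take the axis of
largest absolute coordinate when it reaches the margin (0.25 z units,
roughly a quarter of a typical planted shift; below it samples are
`unclassified`), with the differentiation axis winning exact ties. The
construction makes two symmetries exact — exchanging A1 and A2 negates `y`,
and any gene-wise affine transform of expression leaves the map unchanged —
and both are asserted in the tests.

# FACS post-processing

Intensities are arcsinh-transformed (`cofactor` 150, conventional for this
instrument class). Gates are ordered threshold
predicates combined by intersection (order-independent by construction),
with per-predicate attrition reported; thresholds live in configuration;
no automatic threshold learning is attempted. Per-cell over-dispersion defaults
to the variance/mean of a cell's transformed channel intensities (n-1
variance; mean floored at 1e-8); because per-cell over-dispersion admits
several readings, CV² and a raw-scale Fano variant are computed
alongside.

Cell–cell distances are Euclidean on channel-standardized transformed
intensities — but only over channels not consumed by gating.
Standardization would otherwise inflate the gating channels, which carry
pure selection noise after their gate, to unit variance and drown the
functional readouts: with ZsGreen and HepaCAM included, the four-mode
preset is unresolvable at any realistic separation. Excluding spent gating
channels mirrors standard cytometry practice (cluster on functional
markers); a `channels` argument overrides the default. Clusters come from
`select_k()` + PAM on the same distance matrix, the embedding from the
shared t-SNE contract, and `cluster_condition_summary()` reports cell
counts and marker means/medians per cluster and condition.

# Problem sizes and numerical constants

The suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical claims are stable: 2,000 genes for
DE calibration (2 x 10 samples, dispersion 0.2), 2,000 genes / 3 x 20
samples for subgroup recovery, 50-gene signatures with 20 samples per state
(effect 1 log2 unit) for the state map, 100 cells per population and 20
seeded runs for the FACS preset, and 10,000 permutations against the exact
56-membership GSEA null. Constants: `alpha_floor = 1e-8`, `pseudocount =
1`, NSC grid of 30 thresholds, classification margin 0.25, arcsinh cofactor
150, PAM exact-enumeration bound `choose(n, k) <= 200`.

# Known limitations

- The DE test is mildly liberal at very small n (type-I near 0.06–0.07 at
  n = 10 per group): moment dispersions are noisy and plug-in Wald tests do
  not account for that. Within its design (no shrinkage, normal reference)
  this is expected; treat q-values near the threshold accordingly.
- PAM beyond the exact-enumeration bound is a local search; its optimum is
  certified only against separated structure and the reference
  implementation, not globally.
- The state axes are an interpretation of a two-axis figure, not a fitted
  model; absolute coordinates are in z units and not comparable across
  cohorts normalized separately.
- Synthetic signatures and the FACS preset are stand-ins with the right
  statistical shape, not biological content; results on them validate
  algorithms, not biology.
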