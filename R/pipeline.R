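#' Top variable genes of an expression matrix
#'
#' Expression clustering is dominated by noise when every gene enters the
#' distance; subgroup discovery therefore runs on the most variable
#' genes, the standard filter in transcriptome subtype analysis.
#'
#' @param expr genes x samples matrix.
#' @param n how many genes to keep (capped at the number of rows).
#' @return character vector of gene IDs, by decreasing variance.
#' @export
top_variable_genes <- function(expr, n = 500) {
  rv <- apply(as.matrix(expr), 1, stats::var)
  names(sort(rv, decreasing = TRUE))[seq_len(min(n, length(rv)))]
}

#' Unsupervised subgroup discovery pipeline
#'
#' The full chain: median-of-ratios normalization, variance filtering,
#' silhouette-based choice of k with PAM, negative-silhouette core-sample
#' removal, and nearest-shrunken-centroid marker fitting on the core
#' samples.
#'
#' @param counts a [count_matrix()].
#' @param k_range candidate cluster numbers (default 2:6).
#' @param top_genes genes kept for the dissimilarity (default 200).
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @param pseudocount for [normalize_log()].
#' @param seed integer seed (clustering tie provenance + NSC folds).
#' @return list: `expr` (normalized matrix), `k`, `model` (the selected
#'   `cluster_model`), `core` (mask), `fit` (the `nsc_fit` on core
#'   samples), `markers` (the [marker_table()]), `profile` (mean silhouette
#'   per k).
#' @export
subgroup_pipeline <- function(counts, k_range = 2:6, top_genes = 200,
                              distance = "euclidean", pseudocount = 1,
                              seed = 1L) {
  expr <- normalize_log(counts, pseudocount = pseudocount)
  keep <- top_variable_genes(expr, top_genes)
  D <- expr_dissimilarity(expr[keep, , drop = FALSE], method = distance)
  sel <- select_k(D, k_range = k_range, seed = seed)
  model <- sel$models[[as.character(sel$k)]]
  core <- core_sample_filter(model)
  fit <- fit_nsc(expr[, core, drop = FALSE], model$assignment[core],
                 seed = seed)
  list(expr = expr, k = sel$k, model = model, core = core, fit = fit,
       markers = marker_table(fit), profile = sel$profile)
}
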