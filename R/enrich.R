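## Pre-ranked permutation GSEA: weighted running-sum enrichment score with a
## gene-label permutation null, +1-corrected p-values and BH FDR across sets.

#' Build a ranked gene list from a DE result or marker scores
#'
#' Descending score order, ties broken lexicographically by gene ID, so the
#' ranking is deterministic and idempotent.
#'
#' @param source a `de_result` (metric `"log2fc"`), an `nsc_fit` (metric
#'   `"nsc_score"`, requires `class`), a `glm_marker_score` table (metric
#'   `"glm_score"`, requires `class`), or NULL with `scores` given directly
#'   (metric `"custom"`).
#' @param metric one of `"log2fc"`, `"nsc_score"`, `"glm_score"`,
#'   `"custom"`. There is no default across marker metrics: the caller must
#'   state which ranking feeds enrichment.
#' @param class class label, for the per-class marker metrics.
#' @param scores named numeric vector for `metric = "custom"`.
#' @return object of class `ranked_list`: `data.frame` with columns `gene`,
#'   `score`, ordered; attribute `metric`.
#' @export
make_ranking <- function(source = NULL,
                         metric = c("log2fc", "nsc_score", "glm_score",
                                    "custom"),
                         class = NULL, scores = NULL) {
  metric <- match.arg(metric)
  sc <- switch(metric,
    log2fc = {
      if (!inherits(source, "de_result"))
        stop("metric 'log2fc' needs a de_result")
      stats::setNames(source$log2fc[source$tested],
                      source$gene[source$tested])
    },
    nsc_score = {
      if (!inherits(source, "nsc_fit"))
        stop("metric 'nsc_score' needs an nsc_fit")
      if (is.null(class) || !class %in% source$classes)
        stop("metric 'nsc_score' needs a valid class")
      # signed pre-shrinkage contrasts: every gene keeps a rank
      stats::setNames(source$d_ik[, match(class, source$classes)],
                      rownames(source$d_ik))
    },
    glm_score = {
      if (!is.data.frame(source) || !all(c("gene", "class", "score") %in%
                                           names(source)))
        stop("metric 'glm_score' needs a glm_marker_score table")
      if (is.null(class) || !class %in% source$class)
        stop("metric 'glm_score' needs a valid class")
      sub <- source[source$class == class, ]
      stats::setNames(sub$score, sub$gene)
    },
    custom = {
      if (is.null(scores) || is.null(names(scores)))
        stop("metric 'custom' needs a named scores vector")
      scores
    })
  sc <- sc[is.finite(sc)]
  if (anyDuplicated(names(sc))) stop("duplicate genes in ranking source")
  o <- order(-sc, names(sc))
  structure(data.frame(gene = names(sc)[o], score = unname(sc)[o],
                       stringsAsFactors = FALSE),
            metric = metric, class = c("ranked_list", "data.frame"))
}

# running-sum extremum given sorted hit positions and their weights
.gsea_es_core <- function(pos_sorted, w_sorted, N, n_s) {
  miss_step <- 1 / (N - n_s)
  hit_cum <- cumsum(w_sorted)
  i <- seq_len(n_s)
  at_hit <- hit_cum - (pos_sorted - i) * miss_step        # just after hit i
  before_hit <- c(0, hit_cum[-n_s]) - (pos_sorted - i) * miss_step
  # extrema occur just before or just after hits (the sum falls linearly in
  # between); candidates in walk order so magnitude ties resolve to the
  # deviation reached first
  cand <- as.vector(rbind(before_hit, at_hit))
  cand[which.max(abs(cand))]
}

#' Pre-ranked GSEA for a single gene set
#'
#' Walking down the ranked list, hits increment the running sum by
#' `|score|^p / sum_hits |score|^p` and misses decrement it by
#' `1 / (N - |S|)`; the enrichment score is the maximum-magnitude deviation.
#' The null is `n_perm` random reassignments of the set membership over the
#' gene universe; `p = (1 + #{|ES_perm| >= |ES|}) / (1 + n_perm)` and
#' `NES = ES / mean(|ES_perm|` of the same sign`)`.
#'
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of gene IDs.
#' @param weight_p score weighting exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm number of membership permutations (>= 1, default 1000).
#' @param seed integer seed.
#' @param set_name label recorded in the `set` column.
#' @return one-row `data.frame` of class `enrichment_result`: `set`, `size`
#'   (overlap with the universe), `es`, `nes`, `pvalue`, `padj` (NA here;
#'   filled by [gsea_batch()]), `leading_edge` (slash-separated genes),
#'   `testable`, `n_perm`, `seed`.
#' @export
gsea_preranked <- function(ranked, gene_set, weight_p = 1, n_perm = 1000,
                           seed = 1L, set_name = "set") {
  stopifnot(inherits(ranked, "ranked_list"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  N <- nrow(ranked)
  hits <- which(ranked$gene %in% gene_set)
  n_s <- length(hits)
  if (n_s == N) stop("gene set equals the whole universe")
  if (n_s == 0) {
    return(structure(data.frame(set = set_name, size = 0, es = NA_real_,
                                nes = NA_real_, pvalue = NA_real_,
                                padj = NA_real_, leading_edge = "",
                                testable = FALSE, n_perm = n_perm,
                                seed = seed, stringsAsFactors = FALSE),
                     class = c("enrichment_result", "data.frame")))
  }
  w_abs <- abs(ranked$score)
  weight_of <- function(pos) {
    w <- w_abs[pos]^weight_p
    s <- sum(w)
    if (s == 0) rep(1 / length(pos), length(pos)) else w / s
  }
  es <- .gsea_es_core(hits, weight_of(hits), N, n_s)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  es_perm <- vapply(seq_len(n_perm), function(r) {
    p <- sort.int(sample.int(N, n_s))
    .gsea_es_core(p, weight_of(p), N, n_s)
  }, numeric(1))
  p <- (1 + sum(abs(es_perm) >= abs(es))) / (1 + n_perm)
  same <- es_perm[sign(es_perm) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_

  # leading edge: hits up to (positive ES) / from (negative ES) the extremum
  w <- weight_of(hits)
  hit_cum <- cumsum(w)
  i <- seq_len(n_s)
  at_hit <- hit_cum - (hits - i) / (N - n_s)
  before_hit <- c(0, hit_cum[-n_s]) - (hits - i) / (N - n_s)
  if (es >= 0) {
    peak <- which.max(at_hit)
    le <- ranked$gene[hits[seq_len(peak)]]
  } else {
    trough <- which.min(before_hit)
    le <- ranked$gene[hits[hits >= hits[trough]]]
  }
  structure(data.frame(set = set_name, size = n_s, es = es, nes = nes,
                       pvalue = p, padj = NA_real_,
                       leading_edge = paste(le, collapse = "/"),
                       testable = TRUE, n_perm = n_perm, seed = seed,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Pre-ranked GSEA over a gene-set collection with BH FDR
#'
#' Each set is tested by [gsea_preranked()] with an independent seeded
#' permutation stream; q-values are Benjamini-Hochberg across testable sets
#' only (untestable sets — empty overlap — are reported but excluded from
#' the BH denominator).
#'
#' @param ranked a `ranked_list`.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param weight_p,n_perm,seed as in [gsea_preranked()].
#' @return `enrichment_result` `data.frame`, one row per set.
#' @export
gsea_batch <- function(ranked, collection, weight_p = 1, n_perm = 1000,
                       seed = 1L) {
  if (!length(collection)) {
    out <- data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), pvalue = numeric(), padj = numeric(),
                      leading_edge = character(), testable = logical(),
                      n_perm = integer(), seed = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  rows <- lapply(seq_along(collection), function(i) {
    gsea_preranked(ranked, collection[[i]], weight_p = weight_p,
                   n_perm = n_perm, seed = (seed + i) %% .Machine$integer.max,
                   set_name = names(collection)[i])
  })
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  out$padj[out$testable] <- stats::p.adjust(out$pvalue[out$testable],
                                            method = "BH")
  class(out) <- c("enrichment_result", "data.frame")
  out
}
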