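## Median-of-ratios normalization and a deliberately simplified
## negative-binomial Wald test: method-of-moments dispersions, delta-method
## standard errors, no shrinkage. The fidelity target is calibrated
## statistical behavior, not numeric identity with heavier DE machinery.

#' Median-of-ratios size factors
#'
#' `s_j = median_g counts[g, j] / geomean_g` over genes with all-positive
#' counts, then rescaled so the geometric mean of the factors is 1.
#'
#' @param x a [count_matrix()] or plain genes x samples matrix.
#' @return named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable))
    stop("no gene has positive counts in every sample; ",
         "median-of-ratios is undefined (consider a pseudo-reference)")
  lm_ <- log(m[usable, , drop = FALSE])
  logref <- rowMeans(lm_)                     # log geometric mean per gene
  s <- exp(apply(lm_ - logref, 2, stats::median))
  s <- s / exp(mean(log(s)))                  # geometric mean 1
  stats::setNames(s, colnames(m))
}

#' Log2 normalized expression
#'
#' `log2(counts[g, j] / s_j + pseudocount)`.
#'
#' @param x a [count_matrix()] or matrix.
#' @param sf size factors (default computed from `x`); names must match the
#'   sample IDs.
#' @param pseudocount positive stabilizer, default 1.
#' @return genes x samples numeric matrix with attribute `scale = "log2"`.
#' @export
normalize_log <- function(x, sf = size_factors(x), pseudocount = 1) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (!is.null(names(sf))) {
    if (!setequal(names(sf), colnames(m)))
      stop("size factor sample set disagrees with the matrix")
    sf <- sf[colnames(m)]
  } else if (length(sf) != ncol(m)) {
    stop("size factor sample set disagrees with the matrix")
  }
  out <- log2(sweep(m, 2, sf, "/") + pseudocount)
  attr(out, "scale") <- "log2"
  out
}

#' Method-of-moments NB dispersion estimates
#'
#' Per gene, on normalized counts, pooled within conditions:
#' `alpha_g = max(alpha_floor, (var_g - mean_g) / mean_g^2)` where `var_g`
#' is the pooled within-condition variance and `mean_g` the pooled mean.
#' Genes with zero mean get `NA` and are flagged.
#'
#' @param x a [count_matrix()] or matrix.
#' @param condition per-sample condition labels (>= 2 samples per level).
#' @param sf size factors, default computed from `x`.
#' @param alpha_floor lower bound for the estimate, default `1e-8`.
#' @return named numeric vector of dispersions (NA where undefined).
#' @export
estimate_dispersions <- function(x, condition, sf = size_factors(x),
                                 alpha_floor = 1e-8) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  condition <- as.character(condition)
  if (length(condition) != ncol(m))
    stop("condition must have one label per sample")
  if (any(table(condition) < 2))
    stop("every condition needs >= 2 samples")
  norm <- sweep(m, 2, sf, "/")
  levs <- unique(condition)
  n_tot <- ncol(norm)
  # pooled within-condition moments
  var_p <- 0; mean_all <- rowMeans(norm)
  df_tot <- n_tot - length(levs)
  ss <- 0
  for (l in levs) {
    sub <- norm[, condition == l, drop = FALSE]
    mu <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu)^2)
  }
  var_p <- ss / df_tot
  alpha <- (var_p - mean_all) / mean_all^2
  alpha <- pmax(alpha, alpha_floor)
  alpha[mean_all == 0] <- NA_real_
  stats::setNames(alpha, rownames(m))
}

#' Simplified negative-binomial Wald differential expression
#'
#' For a two-level contrast, the log2 fold change is the log ratio of
#' condition-mean normalized counts (a mean of exactly zero is stabilized to
#' `pseudocount / n`); its standard error comes from the delta method under
#' `NB(mu, alpha_g)` with the method-of-moments dispersion; the two-sided
#' p-value uses the normal reference; q-values are Benjamini-Hochberg over
#' tested genes. Genes with all-zero counts in both conditions are flagged
#' (`tested = FALSE`) and excluded from the BH denominator, not dropped.
#'
#' @param x a [count_matrix()] (its `sample_meta$condition` is used when
#'   `condition` is missing) or matrix.
#' @param condition per-sample labels.
#' @param contrast character of length 2, `c(numerator, denominator)`;
#'   positive log2 fold change means higher in the numerator level.
#' @param sf size factors, default computed from `x`.
#' @param alpha_floor,pseudocount estimator constants.
#' @return `data.frame` of class `de_result` with columns `gene`,
#'   `base_mean`, `log2fc`, `dispersion`, `stat`, `pvalue`, `padj`, `tested`;
#'   attribute `contrast` records the comparison.
#' @export
nb_wald_de <- function(x, condition = NULL, contrast, sf = NULL,
                       alpha_floor = 1e-8, pseudocount = 1) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.null(condition)) {
    if (!inherits(x, "count_matrix") || is.null(x$sample_meta$condition))
      stop("condition labels are required")
    condition <- x$sample_meta$condition
  }
  condition <- as.character(condition)
  if (length(contrast) != 2 || length(unique(contrast)) != 2)
    stop("contrast must name two distinct condition levels")
  if (!all(contrast %in% condition))
    stop("contrast level(s) absent from condition: ",
         paste(setdiff(contrast, condition), collapse = ", "))
  keep <- condition %in% contrast
  m <- m[, keep, drop = FALSE]
  condition <- condition[keep]
  if (any(table(condition) < 2)) stop("need >= 2 samples per contrast level")
  if (is.null(sf)) sf <- size_factors(m)
  if (!is.null(names(sf))) sf <- sf[colnames(m)]
  norm <- sweep(m, 2, sf, "/")

  alpha <- estimate_dispersions(m, condition, sf = sf,
                                alpha_floor = alpha_floor)
  jB <- condition == contrast[1]   # numerator
  jA <- condition == contrast[2]   # denominator
  nB <- sum(jB); nA <- sum(jA)
  muB <- rowMeans(norm[, jB, drop = FALSE])
  muA <- rowMeans(norm[, jA, drop = FALSE])
  tested <- muB + muA > 0
  muBs <- ifelse(muB == 0, pseudocount / nB, muB)
  muAs <- ifelse(muA == 0, pseudocount / nA, muA)
  log2fc <- log2(muBs / muAs)
  # delta method: var(log mu-hat) ~= (mu + alpha mu^2) / (n mu^2)
  a <- ifelse(is.na(alpha), alpha_floor, alpha)
  v <- (muBs + a * muBs^2) / (nB * muBs^2) +
       (muAs + a * muAs^2) / (nA * muAs^2)
  stat <- log2fc * log(2) / sqrt(v)
  p <- 2 * stats::pnorm(-abs(stat))
  p[!tested] <- NA_real_
  stat[!tested] <- NA_real_
  log2fc[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(gene = rownames(m),
                    base_mean = (muB * nB + muA * nA) / (nB + nA),
                    log2fc = log2fc, dispersion = alpha, stat = stat,
                    pvalue = p, padj = q, tested = tested,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

#' Fold-change rank-shift table between two contexts
#'
#' Genes are ranked by decreasing log2 fold change within each context (ties
#' broken lexicographically by gene ID). For each of the `top_n` genes of
#' context A the table reports its rank in A, its rank in B and the rank
#' difference, the comparison conventionally drawn as connecting lines
#' between the two ordered fold-change columns.
#'
#' @param deA,deB `de_result` tables sharing (part of) a gene universe; ranks
#'   are computed on the genes tested in both.
#' @param top_n how many top-A genes to report (default 30).
#' @param highlight_fold display threshold: genes with `|fold change| >=`
#'   this value (on the linear scale) are marked in the `highlight` column;
#'   default 12. A display aid, not a filter.
#' @return `data.frame` of class `rank_shift` with columns `gene`, `rank_a`,
#'   `rank_b`, `delta`, `log2fc_a`, `log2fc_b`, `highlight`.
#' @export
fold_change_rank_shift <- function(deA, deB, top_n = 30,
                                   highlight_fold = 12) {
  ga <- deA$gene[deA$tested]; gb <- deB$gene[deB$tested]
  shared <- intersect(ga, gb)
  if (!length(shared)) stop("disjoint gene universes")
  if (top_n > length(shared))
    stop("top_n exceeds the ", length(shared), " shared tested genes")
  fa <- stats::setNames(deA$log2fc[match(shared, deA$gene)], shared)
  fb <- stats::setNames(deB$log2fc[match(shared, deB$gene)], shared)
  ord_a <- shared[order(-fa, shared)]
  ord_b <- shared[order(-fb, shared)]
  rank_a <- stats::setNames(seq_along(ord_a), ord_a)
  rank_b <- stats::setNames(seq_along(ord_b), ord_b)
  top <- ord_a[seq_len(top_n)]
  out <- data.frame(gene = top,
                    rank_a = unname(rank_a[top]),
                    rank_b = unname(rank_b[top]),
                    delta = unname(rank_b[top] - rank_a[top]),
                    log2fc_a = unname(fa[top]),
                    log2fc_b = unname(fb[top]),
                    highlight = abs(fa[top]) >= log2(highlight_fold),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("rank_shift", "data.frame")
  out
}

#' Per-measurement one-way ANOVA with BH adjustment
#'
#' The figure-legend statistic: each measurement (e.g. a cytokine, a cell
#' density) is tested across groups by one-way ANOVA; p-values are adjusted
#' by Benjamini-Hochberg across measurements. A measurement whose values are
#' all identical gets `F = 0, p = 1` by convention.
#'
#' @param values samples x measurements numeric matrix or data.frame.
#' @param groups per-sample group labels; >= 2 groups, >= 2 observations per
#'   group.
#' @return `data.frame` with columns `measurement`, `F`, `pvalue`, `padj`.
#' @export
group_compare <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("m", seq_len(ncol(values)))
  groups <- as.factor(groups)
  if (length(groups) != nrow(values))
    stop("groups must have one label per sample (row)")
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group(s) with < 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  res <- t(apply(values, 2, function(y) {
    if (stats::var(y) == 0) return(c(0, 1))
    a <- stats::anova(stats::lm(y ~ groups))
    c(a[["F value"]][1], a[["Pr(>F)"]][1])
  }))
  data.frame(measurement = colnames(values), F = res[, 1], pvalue = res[, 2],
             padj = stats::p.adjust(res[, 2], method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
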