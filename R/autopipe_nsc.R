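## Nearest-shrunken-centroid (PAMR-style) marker discovery, written from
## first principles: per-gene standardized centroid contrasts d_ik, soft
## thresholding at delta, cross-validated choice of delta, and the
## diagonal-covariance discriminant for classification.

.nsc_quantities <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  n_k <- table(labels)
  if (any(n_k < 2))
    stop("class(es) with a single sample: ",
         paste(names(n_k)[n_k < 2], collapse = ", "))
  n <- ncol(x); K <- nlevels(labels)
  xbar <- rowMeans(x)
  cent <- vapply(levels(labels), function(l)
    rowMeans(x[, labels == l, drop = FALSE]), numeric(nrow(x)))
  ss <- 0
  for (l in levels(labels)) {
    sub <- x[, labels == l, drop = FALSE]
    ss <- ss + rowSums((sub - cent[, l])^2)
  }
  s_i <- sqrt(ss / (n - K))                 # pooled within-class SD
  s0 <- stats::median(s_i)
  m_k <- sqrt(1 / as.numeric(n_k) - 1 / n)
  names(m_k) <- levels(labels)
  d_ik <- sweep(cent - xbar, 2, m_k, "/") / (s_i + s0)
  list(xbar = xbar, centroids = cent, s_i = s_i, s0 = s0, m_k = m_k,
       d_ik = d_ik, priors = as.numeric(n_k) / n, classes = levels(labels),
       n_k = as.numeric(n_k))
}

.nsc_shrink <- function(q, delta) {
  dprime <- sign(q$d_ik) * pmax(abs(q$d_ik) - delta, 0)
  shrunken <- q$xbar +
    sweep(dprime, 2, q$m_k, "*") * (q$s_i + q$s0)
  list(dprime = dprime, shrunken_centroids = shrunken,
       selected = rownames(q$d_ik)[rowSums(dprime != 0) > 0])
}

.nsc_predict <- function(q, shr, x_new) {
  genes <- if (length(shr$selected)) shr$selected else rownames(q$d_ik)
  xs <- as.matrix(x_new)[genes, , drop = FALSE]
  cen <- shr$shrunken_centroids[genes, , drop = FALSE]
  w <- (q$s_i[match(genes, rownames(q$d_ik))] + q$s0)^2
  disc <- vapply(seq_along(q$classes), function(k) {
    colSums((xs - cen[, k])^2 / w) - 2 * log(q$priors[k])
  }, numeric(ncol(xs)))
  if (ncol(xs) == 1) disc <- matrix(disc, nrow = 1)
  colnames(disc) <- q$classes
  rownames(disc) <- colnames(xs)
  lab <- q$classes[apply(disc, 1, which.min)]   # ties -> class order
  # class posteriors from the discriminant, for likelihood-based CV
  ex <- exp(-(disc - apply(disc, 1, min)) / 2)
  post <- ex / rowSums(ex)
  list(labels = stats::setNames(lab, colnames(xs)), scores = disc,
       posterior = post)
}

#' Fit a nearest-shrunken-centroid classifier
#'
#' For gene i and class k the standardized contrast is
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with `s_i` the pooled
#' within-class SD, `s0` the median of the `s_i` (fudge), and
#' `m_k = sqrt(1/n_k - 1/n)`. Soft thresholding at `delta` gives
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)` and shrunken centroids
#' `xbar'_ik = xbar_i + m_k * (s_i + s0) * d'_ik`. The threshold is chosen
#' by stratified cross-validated misclassification error. Because the 0-1
#' error saturates at zero over wide threshold ranges on well-separated
#' classes, error ties are broken by the cross-validated multinomial
#' likelihood of the held-out labels (which keeps falling once genuinely
#' informative genes are shrunk away); any remaining ties go to the largest
#' delta (sparsest model). Genes with zero pooled SD get `s_i = 0` and are
#' kept finite by `s0`.
#'
#' @param x genes x samples log-expression matrix.
#' @param labels per-sample class labels, >= 2 samples per class.
#' @param delta_grid thresholds to scan; default `n_delta` evenly spaced
#'   values in `[0, max |d_ik|]`.
#' @param n_delta grid size when `delta_grid` is NULL (default 30).
#' @param cv_folds number of stratified folds (default 10, capped at the
#'   smallest class size).
#' @param seed seed for the fold split.
#' @return object of class `nsc_fit`: the quantities above plus `delta`
#'   (chosen threshold), `dprime`, `shrunken_centroids`, `selected`
#'   (marker genes at the chosen delta) and `cv_table`
#'   (delta, cv errors, genes selected).
#' @export
fit_nsc <- function(x, labels, delta_grid = NULL, n_delta = 30,
                    cv_folds = 10, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  q <- .nsc_quantities(x, labels)
  dmax <- max(abs(q$d_ik))
  if (is.null(delta_grid))
    delta_grid <- seq(0, dmax, length.out = n_delta)
  delta_grid <- sort(unique(delta_grid))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  min_cls <- min(table(labels))
  if (min_cls < 3) {
    # leaving any sample out would strand a training class with one member;
    # fall back to the most permissive threshold and report no CV
    shr <- .nsc_shrink(q, delta_grid[1])
    n_sel <- vapply(delta_grid, function(d)
      length(.nsc_shrink(q, d)$selected), integer(1))
    return(structure(c(q, shr,
                       list(delta = delta_grid[1],
                            cv_table = data.frame(delta = delta_grid,
                                                  cv_errors = NA_integer_,
                                                  cv_loglik = NA_real_,
                                                  n_selected = n_sel),
                            cv_folds = 0L, seed = seed)),
                     class = "nsc_fit"))
  }
  folds <- integer(ncol(x))
  nf <- max(2L, min(cv_folds, min_cls))
  for (l in levels(labels)) {
    idx <- sample(which(labels == l))
    folds[idx] <- rep_len(seq_len(nf), length(idx))
  }
  errs <- matrix(0L, length(delta_grid), nf)
  loglik <- matrix(0, length(delta_grid), nf)
  for (f in seq_len(nf)) {
    tr <- folds != f
    qf <- .nsc_quantities(x[, tr, drop = FALSE], droplevels(labels[tr]))
    truth_f <- as.character(labels[!tr])
    for (di in seq_along(delta_grid)) {
      shr <- .nsc_shrink(qf, delta_grid[di])
      pred <- .nsc_predict(qf, shr, x[, !tr, drop = FALSE])
      errs[di, f] <- sum(pred$labels != truth_f)
      pr <- pred$posterior[cbind(seq_along(truth_f),
                                 match(truth_f, qf$classes))]
      loglik[di, f] <- sum(log(pmax(pr, 1e-12)))
    }
  }
  cv_err <- rowSums(errs)
  cv_ll <- rowSums(loglik)
  tied <- which(cv_err == min(cv_err))
  best_ll <- tied[cv_ll[tied] >= max(cv_ll[tied]) - 1e-9]
  best <- max(best_ll)                         # remaining ties -> largest delta
  delta <- delta_grid[best]
  shr <- .nsc_shrink(q, delta)
  n_sel <- vapply(delta_grid, function(d)
    length(.nsc_shrink(q, d)$selected), integer(1))
  structure(c(q, shr,
              list(delta = delta,
                   cv_table = data.frame(delta = delta_grid,
                                         cv_errors = cv_err,
                                         cv_loglik = cv_ll,
                                         n_selected = n_sel),
                   cv_folds = nf, seed = seed)),
            class = "nsc_fit")
}

#' @export
print.nsc_fit <- function(x, ...) {
  cat(sprintf("nsc_fit: %d classes, delta = %.4g, %d marker gene(s)\n",
              length(x$classes), x$delta, length(x$selected)))
  invisible(x)
}

#' Classify samples with a fitted NSC model
#'
#' Discriminant `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2
#' - 2 log pi_k` over the selected genes (all genes when none survive the
#' threshold); the label is the argmin, ties resolved by class order.
#'
#' @param fit an `nsc_fit`.
#' @param x_new genes x samples matrix containing all genes of the fit.
#' @param delta threshold to apply (default the fit's chosen one).
#' @return list: `labels` (named character) and `scores` (samples x classes
#'   discriminant matrix; smaller is closer).
#' @export
nsc_classify <- function(fit, x_new, delta = fit$delta) {
  stopifnot(inherits(fit, "nsc_fit"))
  x_new <- as.matrix(x_new)
  miss <- setdiff(rownames(fit$d_ik), rownames(x_new))
  if (length(miss))
    stop("genes missing from new data: ", paste(miss, collapse = ", "))
  shr <- .nsc_shrink(fit, delta)
  .nsc_predict(fit, shr, x_new)
}

#' Per-class marker table ranked by shrunken score
#'
#' Genes with nonzero `d'_ik` per class, sorted by decreasing `|d'_ik|`
#' (the PAMR-style marker score), with the direction of regulation.
#'
#' @param fit an `nsc_fit`.
#' @param delta threshold (default the fit's chosen one).
#' @return `data.frame` with columns `class`, `gene`, `score`, `sign`
#'   (`"up"`/`"down"`), `delta`.
#' @export
marker_table <- function(fit, delta = fit$delta) {
  stopifnot(inherits(fit, "nsc_fit"))
  shr <- .nsc_shrink(fit, delta)
  out <- do.call(rbind, lapply(seq_along(fit$classes), function(k) {
    dk <- shr$dprime[, k]
    keep <- dk != 0
    if (!any(keep)) return(NULL)
    g <- names(dk)[keep]; v <- dk[keep]
    o <- order(-abs(v), g)
    data.frame(class = fit$classes[k], gene = g[o], score = abs(v[o]),
               sign = ifelse(v[o] > 0, "up", "down"), delta = delta,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(class = character(), gene = character(),
                      score = numeric(), sign = character(),
                      delta = numeric(), stringsAsFactors = FALSE)
  out
}

#' Per-gene one-vs-rest logistic marker scores
#'
#' For every gene and class, a binomial GLM of class membership on the gene's
#' expression; the score is the signed Wald z of the slope. Constant genes
#' score 0 and are flagged; non-converged or separable fits are flagged and
#' the score capped at `+/- cap`.
#'
#' @param x genes x samples matrix.
#' @param labels per-sample class labels.
#' @param cap absolute score bound (default 10).
#' @return `data.frame` with columns `gene`, `class`, `score`, `flagged`.
#' @export
glm_marker_score <- function(x, labels, cap = 10) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  res <- do.call(rbind, lapply(levels(labels), function(l) {
    y <- as.integer(labels == l)
    t(vapply(seq_len(nrow(x)), function(i) {
      xi <- x[i, ]
      if (stats::var(xi) == 0) return(c(0, 1))
      flagged <- FALSE
      fit <- withCallingHandlers(
        stats::glm(y ~ xi, family = stats::binomial()),
        warning = function(w) {
          flagged <<- TRUE
          invokeRestart("muffleWarning")
        })
      z <- summary(fit)$coefficients["xi", "z value"]
      slope <- stats::coef(fit)[["xi"]]
      fitted_ <- stats::fitted(fit)
      # complete/quasi-separation: the Wald z collapses while the slope
      # diverges (glm may even converge without warning); report the capped
      # score in the slope's direction
      separated <- all(fitted_[y == 1] > 1 - 1e-6) &&
        all(fitted_[y == 0] < 1e-6)
      if (separated) { z <- sign(slope) * cap; flagged <- TRUE }
      if (!is.finite(z)) { z <- 0; flagged <- TRUE }
      if (abs(z) > cap) { z <- sign(z) * cap; flagged <- TRUE }
      c(z, as.numeric(flagged))
    }, numeric(2)))
  }))
  data.frame(gene = rep(rownames(x), nlevels(labels)),
             class = rep(levels(labels), each = nrow(x)),
             score = res[, 1], flagged = res[, 2] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}
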