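## Subgroup discovery: partitioning around medoids with greedy BUILD and
## steepest-descent SWAP, silhouette-based model selection, negative-
## silhouette core-sample filtering, and subsampled consensus validation.

#' Dissimilarity between samples of an expression matrix
#'
#' Samples are the columns. `"euclidean"` is the default;
#' `"correlation"` uses `1 - Pearson r` between sample profiles.
#'
#' @param x genes x samples numeric matrix.
#' @param method `"euclidean"` or `"correlation"`.
#' @return a symmetric zero-diagonal dissimilarity matrix (samples x samples).
#' @export
expr_dissimilarity <- function(x, method = c("euclidean", "correlation")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  d <- switch(method,
    euclidean = as.matrix(stats::dist(t(x))),
    correlation = 1 - stats::cor(x))
  diag(d) <- 0
  d
}

.as_diss <- function(d) {
  if (inherits(d, "dist")) return(as.matrix(d))
  d <- as.matrix(d)
  if (nrow(d) == ncol(d) &&
      !is.null(rownames(d)) && !is.null(colnames(d)) &&
      identical(rownames(d), colnames(d))) {
    if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix is not symmetric")
    if (any(d < 0)) stop("dissimilarity matrix has negative entries")
    diag(d) <- 0
    return(d)
  }
  # otherwise interpret rows as feature vectors of the items
  as.matrix(stats::dist(d))
}

#' Partitioning around medoids (BUILD + SWAP, exact for tiny problems)
#'
#' Greedy BUILD seeding followed by steepest-descent SWAP: at each pass the
#' medoid/non-medoid exchange with the largest cost reduction is applied;
#' the total dissimilarity to assigned medoids is non-increasing and the
#' algorithm stops when no improving swap exists. Ties are broken by the
#' first candidate in item order, so the result is deterministic. When the
#' medoid search space is small (`choose(n, k) <= exact_limit`) the global
#' optimum is found by full enumeration instead — SWAP is a local search
#' and can stall above the optimum on adversarial small fixtures, where
#' exact search is essentially free.
#'
#' @param d a `dist`, a symmetric dissimilarity matrix with matching
#'   dimnames, or an items x features matrix (converted by Euclidean
#'   distance).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed retained on the model for provenance; the algorithm itself is
#'   deterministic.
#' @param exact_limit enumerate all medoid sets when `choose(n, k)` is at
#'   most this bound (default 200).
#' @return object of class `cluster_model`: list with `k`, `medoids` (item
#'   IDs), `assignment` (named integer cluster per item), `silhouette`,
#'   `core` (silhouette >= 0 mask), `cost`, `seed`.
#' @export
pam_cluster <- function(d, k, seed = 1L, exact_limit = 200) {
  D <- .as_diss(d)
  n <- nrow(D)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("item_", seq_len(n))
  }
  ids <- rownames(D)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")

  if (choose(n, k) <= exact_limit) {
    best_cost <- Inf; med <- seq_len(k)
    sets <- utils::combn(n, k)
    for (ci in seq_len(ncol(sets))) {
      m <- sets[, ci]
      cost <- sum(do.call(pmin, as.data.frame(D[, m, drop = FALSE])))
      if (cost < best_cost - 1e-12) { best_cost <- cost; med <- m }
    }
    return(.pam_finish(D, ids, med, k, seed))
  }

  ## BUILD: greedy cost-reduction seeding
  med <- which.min(colSums(D))
  dn <- D[, med]
  while (length(med) < k) {
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% med) return(-Inf)
      sum(pmax(dn - D[, h], 0))
    }, numeric(1))
    med <- c(med, which.max(gain))
    dn <- pmin(dn, D[, med[length(med)]])
  }

  ## SWAP: steepest descent over all (medoid, candidate) exchanges
  repeat {
    Dm <- D[, med, drop = FALSE]
    nearest <- max.col(-Dm, ties.method = "first")
    dn <- Dm[cbind(seq_len(n), nearest)]
    if (k == 1) break
    ds <- apply(Dm, 1, function(r) sort(r, partial = 2)[2])
    cand <- setdiff(seq_len(n), med)
    best <- list(delta = -1e-12, i = NA, h = NA)
    S_groups <- function(v) {
      out <- numeric(k)
      agg <- rowsum(v, nearest)
      out[as.integer(rownames(agg))] <- agg
      out
    }
    for (h in cand) {
      dh <- D[, h]
      base <- pmin(dh - dn, 0)
      own <- pmin(dh, ds) - dn
      a <- S_groups(base); b <- S_groups(own)
      delta <- sum(base) - a + b          # vector over medoid slots
      i <- which.min(delta)
      if (delta[i] < best$delta) best <- list(delta = delta[i], i = i, h = h)
    }
    if (is.na(best$i)) break
    med[best$i] <- best$h
  }
  .pam_finish(D, ids, med, k, seed)
}

.pam_finish <- function(D, ids, med, k, seed) {
  n <- nrow(D)
  Dm <- D[, med, drop = FALSE]
  assignment <- max.col(-Dm, ties.method = "first")
  # medoids must sit in their own cluster even under distance ties
  assignment[med] <- seq_len(k)
  cost <- sum(Dm[cbind(seq_len(n), assignment)])
  sil <- silhouette_widths(D, stats::setNames(assignment, ids))
  structure(list(k = k, medoids = ids[med],
                 assignment = stats::setNames(assignment, ids),
                 silhouette = sil, core = sil >= 0, cost = cost,
                 seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, cost = %.4g, mean silhouette = %.3f\n",
              x$k, x$cost, mean(x$silhouette)))
  cat("cluster sizes:", paste(table(x$assignment), collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample silhouette widths
#'
#' `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean dissimilarity to
#' the sample's own cluster (self excluded) and `b_i` the smallest mean
#' dissimilarity to any other cluster. Members of singleton clusters get
#' `s_i = 0` by convention; with a single cluster all widths are 0.
#'
#' @param d dissimilarity (as in [pam_cluster()]).
#' @param assignment named integer/factor cluster assignment covering all
#'   items of `d`.
#' @return named numeric vector in `[-1, 1]`.
#' @export
silhouette_widths <- function(d, assignment) {
  D <- .as_diss(d)
  ids <- rownames(D)
  if (!is.null(names(assignment))) {
    unknown <- setdiff(names(assignment), ids)
    if (length(unknown))
      stop("assignment references unknown sample(s): ",
           paste(unknown, collapse = ", "))
    if (!setequal(names(assignment), ids))
      stop("assignment must cover every item")
    assignment <- assignment[ids]
  } else if (length(assignment) != nrow(D)) {
    stop("assignment must cover every item")
  }
  cl <- as.integer(as.factor(assignment))
  ks <- sort(unique(cl))
  if (length(ks) < 2)
    return(stats::setNames(rep(0, nrow(D)), ids))
  sizes <- tabulate(cl)
  # mean dissimilarity from every item to every cluster
  sums <- t(rowsum(t(D), cl))           # items x clusters sums
  means <- sweep(sums, 2, sizes[ks], "/")
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[own] == 1) { s[i] <- 0; next }
    a <- sums[i, match(own, ks)] / (sizes[own] - 1)
    b <- min(means[i, ks != own])
    s[i] <- (b - a) / max(a, b)
  }
  stats::setNames(s, ids)
}

#' Choose the number of clusters by mean silhouette
#'
#' Runs [pam_cluster()] for each `k` and picks the `k` maximizing the mean
#' silhouette width; ties go to the smallest `k`.
#'
#' @param d dissimilarity (as in [pam_cluster()]).
#' @param k_range candidate k values, all in `[2, n - 1]`.
#' @param seed forwarded to [pam_cluster()].
#' @return list: `k` (the optimum), `profile` (`data.frame` k x mean
#'   silhouette), `models` (the fitted `cluster_model`s, named by k).
#' @export
select_k <- function(d, k_range = 2:6, seed = 1L) {
  D <- .as_diss(d)
  n <- nrow(D)
  if (!length(k_range)) stop("k_range is empty")
  if (any(k_range < 2 | k_range >= n))
    stop("k_range must lie within [2, n-1] = [2, ", n - 1, "]")
  models <- lapply(k_range, function(k) pam_cluster(D, k, seed = seed))
  names(models) <- k_range
  msil <- vapply(models, function(m) mean(m$silhouette), numeric(1))
  best <- k_range[which.max(msil)]   # which.max takes the first = smallest k
  list(k = best,
       profile = data.frame(k = k_range, mean_silhouette = unname(msil)),
       models = models)
}

#' Core-sample mask (negative-silhouette removal)
#'
#' Samples with negative silhouette width are flagged as non-core and are
#' excluded from downstream marker fitting.
#'
#' @param model a `cluster_model`.
#' @return named logical mask, `TRUE` for core samples (`s_i >= 0`).
#' @export
core_sample_filter <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  model$silhouette >= 0
}

#' Subsampled consensus clustering
#'
#' Repeatedly subsamples the items, reruns PAM, and reports the pairwise
#' co-assignment frequency normalized by the number of times each pair was
#' co-sampled.
#'
#' @param d dissimilarity (as in [pam_cluster()]).
#' @param k number of clusters per run.
#' @param n_resample number of subsampling rounds (>= 1).
#' @param subsample_frac fraction of items per round, in `(0, 1]`.
#' @param seed integer seed.
#' @return object of class `consensus_result`: list with `consensus`
#'   (symmetric matrix in `[0, 1]`, NA for never co-sampled pairs),
#'   `n_resample`, `subsample_frac`, `seed`, `mean_within` (mean consensus
#'   within the full-data PAM clusters).
#' @export
consensus_cluster <- function(d, k, n_resample = 100, subsample_frac = 0.8,
                              seed = 1L) {
  D <- .as_diss(d)
  n <- nrow(D)
  if (n_resample < 1) stop("n_resample must be >= 1")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must be in (0, 1]")
  m <- max(1L, round(subsample_frac * n))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  co <- matrix(0, n, n); tog <- matrix(0, n, n)
  done <- 0L
  for (r in seq_len(n_resample)) {
    idx <- sort(sample.int(n, m))
    if (m < k) { warning("subsample smaller than k; round skipped"); next }
    fit <- pam_cluster(D[idx, idx, drop = FALSE], k)
    tog[idx, idx] <- tog[idx, idx] + 1
    same <- outer(fit$assignment, fit$assignment, "==")
    co[idx, idx] <- co[idx, idx] + same
    done <- done + 1L
  }
  if (done == 0L) stop("all resampling rounds were skipped (subsample < k)")
  cons <- ifelse(tog > 0, co / tog, NA_real_)
  dimnames(cons) <- dimnames(D)
  full <- pam_cluster(D, k)
  within <- outer(full$assignment, full$assignment, "==")
  mw <- mean(cons[within & upper.tri(cons)], na.rm = TRUE)
  structure(list(consensus = cons, n_resample = n_resample,
                 subsample_frac = subsample_frac, seed = seed,
                 mean_within = mw),
            class = "consensus_result")
}
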