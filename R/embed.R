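#' Two-dimensional t-SNE embedding
#'
#' Thin seeded wrapper around the Rtsne implementation, used for validation
#' and visualization of cluster structure (never for inference). Exact
#' t-SNE (`theta = 0`) is used below 1000 items so small runs are fully
#' reproducible across platforms.
#'
#' @param x items x features matrix, or a `dist` / symmetric dissimilarity
#'   matrix (detected as in [pam_cluster()]).
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (n - 1) / 3`.
#' @param seed integer seed; the same seed gives identical coordinates.
#' @param n_iter iterations (default 500).
#' @return object of class `embedding`: list with `coords` (items x 2, named
#'   rows), `method`, `perplexity`, `seed`, `diagnostic` (final KL
#'   divergence).
#' @export
embed_2d <- function(x, perplexity = 10, seed = 1L, n_iter = 500) {
  is_dist <- inherits(x, "dist") ||
    (is.matrix(x) && nrow(x) == ncol(x) &&
       !is.null(rownames(x)) && identical(rownames(x), colnames(x)) &&
       max(abs(x - t(x))) < 1e-8)
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(x)
  ids <- if (inherits(x, "dist")) attr(x, "Labels") else rownames(x)
  if (is.null(ids)) ids <- paste0("item_", seq_len(n))
  if (perplexity >= (n - 1) / 3)
    stop("perplexity must be < (n - 1) / 3 = ", (n - 1) / 3)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- Rtsne::Rtsne(if (inherits(x, "dist")) as.matrix(x) else as.matrix(x),
                      dims = 2, perplexity = perplexity,
                      is_distance = is_dist,
                      theta = if (n < 1000) 0 else 0.5,
                      max_iter = n_iter, check_duplicates = FALSE,
                      pca = !is_dist, verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- ids
  colnames(coords) <- c("dim1", "dim2")
  structure(list(coords = coords, method = "tsne", perplexity = perplexity,
                 seed = seed,
                 diagnostic = utils::tail(fit$itercosts, 1)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d items, method = %s, perplexity = %g, KL = %.4g\n",
              nrow(x$coords), x$method, x$perplexity, x$diagnostic))
  invisible(x)
}
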