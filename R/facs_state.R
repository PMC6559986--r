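## Flow-cytometry post-processing: arcsinh transform, threshold gating with
## attrition reporting, per-cell over-dispersion, distance-based clustering
## and embedding, and cluster-by-condition marker summaries.

#' Arcsinh-transform FACS intensities
#'
#' `value -> asinh(value / cofactor)`: monotone, maps 0 to 0, linear near
#' zero and logarithmic for bright signal, the standard variance-stabilizer
#' for cytometry intensities.
#'
#' @param f a [facs_matrix()] on the raw scale.
#' @param cofactor positive scale cofactor (default 150, conventional for
#'   this instrument class).
#' @return a transformed [facs_matrix()].
#' @export
transform_intensities <- function(f, cofactor = 150) {
  stopifnot(inherits(f, "facs_matrix"))
  if (cofactor <= 0) stop("cofactor must be > 0")
  if (f$transformed) stop("intensities are already transformed")
  out <- facs_matrix(asinh(f$intensities / cofactor), condition = f$condition,
                     transformed = TRUE, cofactor = cofactor)
  out$gated_channels <- f$gated_channels
  out
}

#' Build a gate specification
#'
#' An ordered set of threshold predicates on transformed intensities,
#' combined by intersection.
#'
#' @param channel character vector of channel names.
#' @param direction `"above"` or `"below"` per predicate (cells are kept if
#'   strictly above / below the threshold).
#' @param threshold finite numeric thresholds on the transformed scale.
#' @return `data.frame` of class `gate_spec`.
#' @export
gate_spec <- function(channel, direction, threshold) {
  direction <- match.arg(direction, c("above", "below"), several.ok = TRUE)
  if (any(!is.finite(threshold))) stop("thresholds must be finite")
  out <- data.frame(channel = channel, direction = direction,
                    threshold = threshold, stringsAsFactors = FALSE)
  class(out) <- c("gate_spec", "data.frame")
  out
}

#' Apply gates to a FACS matrix
#'
#' Cells satisfying every predicate are retained; the report records
#' per-predicate attrition in application order (intersection semantics, so
#' the final subset is order-independent). A gate retaining zero cells is a
#' warning, not an error.
#'
#' @param f a [facs_matrix()] (transform first; thresholds are on the
#'   transformed scale).
#' @param gates a [gate_spec()].
#' @return list: `gated` (subset [facs_matrix()]), `report` (`data.frame`
#'   with columns `channel`, `direction`, `threshold`, `removed`,
#'   `remaining`).
#' @export
apply_gates <- function(f, gates) {
  stopifnot(inherits(f, "facs_matrix"), inherits(gates, "gate_spec"))
  unknown <- setdiff(gates$channel, colnames(f$intensities))
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(f$intensities))
  report <- gates
  report$removed <- NA_integer_; report$remaining <- NA_integer_
  for (i in seq_len(nrow(gates))) {
    v <- f$intensities[, gates$channel[i]]
    ok <- if (gates$direction[i] == "above") v > gates$threshold[i]
          else v < gates$threshold[i]
    report$removed[i] <- sum(keep & !ok)
    keep <- keep & ok
    report$remaining[i] <- sum(keep)
  }
  if (!any(keep)) warning("gate retained zero cells")
  gated <- structure(list(
    intensities = f$intensities[keep, , drop = FALSE],
    condition = f$condition[keep],
    transformed = f$transformed, cofactor = f$cofactor,
    gated_channels = union(f$gated_channels, unique(gates$channel))),
    class = "facs_matrix")
  list(gated = gated, report = report)
}

#' Per-cell over-dispersion of channel intensities
#'
#' The default reading of per-cell over-dispersion: the variance/mean ratio
#' of a cell's transformed channel intensities (mean floored at `eps`).
#' Because per-cell over-dispersion admits several readings, two
#' variants are provided:
#' `"cv2"` (variance / mean^2) and `"fano"` (variance/mean on the raw
#' scale). Variance is the n-1 sample variance.
#'
#' @param f a [facs_matrix()] with >= 2 channels.
#' @param method `"var_mean"` (default), `"cv2"`, or `"fano"`.
#' @param eps mean floor (default 1e-8).
#' @return named numeric vector, one statistic per cell.
#' @export
cell_overdispersion <- function(f, method = c("var_mean", "cv2", "fano"),
                                eps = 1e-8) {
  stopifnot(inherits(f, "facs_matrix"))
  method <- match.arg(method)
  m <- f$intensities
  if (ncol(m) < 2) stop("need >= 2 channels")
  if (method == "fano") {
    if (f$transformed) {
      if (!is.finite(f$cofactor)) stop("cannot undo transform: cofactor unknown")
      m <- sinh(m) * f$cofactor
    }
  } else if (!f$transformed) {
    stop("methods var_mean / cv2 expect transformed intensities")
  }
  mu <- pmax(rowMeans(m), eps)
  v <- apply(m, 1, stats::var)
  out <- switch(method, var_mean = v / mu, fano = v / mu, cv2 = v / mu^2)
  stats::setNames(out, rownames(m))
}

#' Cluster and embed cells by transformed-intensity distance
#'
#' Channels are standardized (unit variance across cells) on the transformed
#' scale, cell-cell distances are Euclidean, the 2D embedding follows the
#' [embed_2d()] contract, and clusters come from [select_k()] + PAM on the
#' same distance matrix. Channels already consumed by gating (recorded by
#' [apply_gates()]) are excluded by default: a gating channel carries only
#' selection noise after its gate and, once standardized, would drown the
#' functional readout channels.
#'
#' @param f a transformed [facs_matrix()] with >= 10 cells.
#' @param channels channels to use; default all channels not used in a gate.
#' @param perplexity t-SNE perplexity (default 30; must satisfy the
#'   [embed_2d()] bound).
#' @param k_range candidate cluster numbers (default 2:6).
#' @param seed integer seed.
#' @return list: `embedding` (an `embedding`), `model` (the selected
#'   `cluster_model`), `k`, `clusters` (named integer per cell),
#'   `silhouette_profile` (the [select_k()] profile), `channels` (the ones
#'   used).
#' @export
cell_distance_embedding <- function(f, channels = NULL, perplexity = 30,
                                    k_range = 2:6, seed = 1L) {
  stopifnot(inherits(f, "facs_matrix"))
  if (!f$transformed) stop("transform intensities first")
  if (is.null(channels))
    channels <- setdiff(colnames(f$intensities), f$gated_channels)
  unknown <- setdiff(channels, colnames(f$intensities))
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  if (!length(channels)) stop("no channels left after gating exclusion")
  n <- nrow(f$intensities)
  if (n < 10) stop("need >= 10 cells")
  z <- scale(f$intensities[, channels, drop = FALSE])
  z[, attr(z, "scaled:scale") == 0] <- 0
  D <- as.matrix(stats::dist(z))
  emb <- embed_2d(D, perplexity = perplexity, seed = seed)
  sel <- select_k(D, k_range = k_range, seed = seed)
  model <- sel$models[[as.character(sel$k)]]
  list(embedding = emb, model = model, k = sel$k,
       clusters = model$assignment, silhouette_profile = sel$profile,
       channels = channels)
}

#' Cluster x condition cell-state summary
#'
#' Cell counts and per-marker mean/median transformed intensity for every
#' cluster x condition combination. Counts over the table sum to the number
#' of gated cells; an empty combination yields an NA row with a warning
#' only when a whole cluster is empty (cannot happen for PAM output, but
#' guarded for externally supplied labels).
#'
#' @param f a transformed [facs_matrix()].
#' @param clusters named integer cluster per cell.
#' @param markers marker channels to summarize (default `STAT3-P`, `KI67`).
#' @return `data.frame` of class `cell_state_summary`: `cluster`,
#'   `condition`, `n_cells`, then `mean_<marker>` and `median_<marker>`
#'   columns.
#' @export
cluster_condition_summary <- function(f, clusters,
                                      markers = c("STAT3-P", "KI67")) {
  stopifnot(inherits(f, "facs_matrix"))
  unknown <- setdiff(markers, colnames(f$intensities))
  if (length(unknown))
    stop("unknown marker channel(s): ", paste(unknown, collapse = ", "))
  cells <- rownames(f$intensities)
  if (!is.null(names(clusters))) clusters <- clusters[cells]
  if (length(clusters) != length(cells) || anyNA(clusters))
    stop("clusters must cover every cell")
  ks <- sort(unique(clusters))
  conds <- unique(f$condition)
  rows <- list()
  for (k in ks) {
    in_k <- clusters == k
    if (!any(in_k)) { warning("cluster ", k, " is empty"); next }
    for (cd in conds) {
      idx <- in_k & f$condition == cd
      row <- data.frame(cluster = k, condition = cd, n_cells = sum(idx),
                        stringsAsFactors = FALSE)
      for (mk in markers) {
        v <- f$intensities[idx, mk]
        row[[paste0("mean_", mk)]] <- if (length(v)) mean(v) else NA_real_
        row[[paste0("median_", mk)]] <- if (length(v)) stats::median(v) else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cell_state_summary", "data.frame")
  out
}
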