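# Independent oracles used across tests. These re-derive expected values
# from first principles (enumeration, explicit walks, hand formulas) and
# never call the package internals they check.

# exhaustive k-medoids optimum: try every medoid set
brute_force_pam_cost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  sets <- utils::combn(n, k)
  for (ci in seq_len(ncol(sets))) {
    cost <- sum(apply(D[, sets[, ci], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# explicit weighted running-sum walk over the whole list (O(N) reference)
walk_es <- function(n_genes, hit_pos, scores = NULL, weight_p = 0) {
  inset <- rep(FALSE, n_genes); inset[hit_pos] <- TRUE
  if (is.null(scores)) scores <- rep(1, n_genes)
  w <- abs(scores[hit_pos])^weight_p
  w <- if (sum(w) == 0) rep(1 / length(hit_pos), length(hit_pos)) else w / sum(w)
  hit_w <- numeric(n_genes); hit_w[hit_pos] <- w
  run <- 0; best <- 0
  for (i in seq_len(n_genes)) {
    run <- run + if (inset[i]) hit_w[i] else -1 / (n_genes - length(hit_pos))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# two-class, four-gene toy with fully hand-computed NSC quantities
nsc_toy <- function() {
  x <- rbind(g1 = c(1, 3, 9, 11),
             g2 = c(5, 5, 5, 5),
             g3 = c(4, 6, 4, 6),
             g4 = c(0, 2, 1, 3))
  colnames(x) <- c("a1", "a2", "b1", "b2")
  labels <- c("a", "a", "b", "b")
  # hand arithmetic: s_i = sqrt(((2) + (2)) / (4 - 2)) = sqrt(2) for g1,g3,g4;
  # g2 constant -> 0. s0 = median = sqrt(2). m_k = sqrt(1/2 - 1/4) = 1/2.
  # d_ik = (class mean - overall) / (0.5 * (s_i + s0))
  sq2 <- sqrt(2)
  list(x = x, labels = labels,
       s_i = c(g1 = sq2, g2 = 0, g3 = sq2, g4 = sq2),
       s0 = sq2, m_k = c(a = 0.5, b = 0.5),
       d_ik = cbind(a = c(g1 = -4 / (0.5 * 2 * sq2), g2 = 0, g3 = 0,
                          g4 = -0.5 / (0.5 * 2 * sq2)),
                    b = c(g1 = 4 / (0.5 * 2 * sq2), g2 = 0, g3 = 0,
                          g4 = 0.5 / (0.5 * 2 * sq2))),
       centroids = cbind(a = c(g1 = 2, g2 = 5, g3 = 5, g4 = 1),
                         b = c(g1 = 10, g2 = 5, g3 = 5, g4 = 2)))
}

# well-separated Gaussian blobs in 2D, as a named feature matrix
make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  rownames(X) <- sprintf("pt_%03d", seq_len(nrow(X)))
  attr(X, "truth") <- rep(seq_len(nrow(centers)), each = n_per)
  X
}

# count_matrix wrapper for hand-built matrices
cm <- function(m, condition = NULL) {
  meta <- if (is.null(condition)) NULL else
    data.frame(condition = condition, row.names = colnames(m))
  count_matrix(m, sample_meta = meta)
}
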