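test_that("NSC quantities match the hand-computed toy exactly", {
  toy <- nsc_toy()
  fit <- fit_nsc(toy$x, toy$labels, delta_grid = c(0, 0.2, 1), cv_folds = 2,
                 seed = 1)
  expect_equal(fit$s_i, toy$s_i)
  expect_equal(fit$s0, toy$s0)
  expect_equal(unname(fit$m_k), unname(toy$m_k))
  expect_equal(fit$d_ik[, "a"], toy$d_ik[, "a"])
  expect_equal(fit$d_ik[, "b"], toy$d_ik[, "b"])
  expect_equal(fit$centroids, toy$centroids)

  # delta = 0: shrunken centroids equal the raw class centroids
  shr0 <- marker_table(fit, delta = 0)
  fit0 <- nsc_classify(fit, toy$x, delta = 0)
  expect_equal(unname(fit0$labels), toy$labels)

  # hand soft-threshold at delta = 1: only g1 survives
  mt1 <- marker_table(fit, delta = 1)
  expect_setequal(unique(mt1$gene), "g1")
  expect_equal(mt1$score[mt1$class == "b"], 2 * sqrt(2) - 1)
  expect_equal(mt1$sign[mt1$class == "b"], "up")
  expect_equal(mt1$sign[mt1$class == "a"], "down")

  # hand shrunken centroid at delta = 1:
  # xbar + m_k (s+s0) d' = 6 +/- 0.5 * 2 sqrt(2) * (2 sqrt(2) - 1)
  q <- fit$d_ik["g1", "b"]
  expect_equal(q, 2 * sqrt(2))
  shrunken_b <- 6 + 0.5 * 2 * sqrt(2) * (2 * sqrt(2) - 1)
  cls <- nsc_classify(fit, toy$x, delta = 1)
  expect_equal(unname(cls$labels), toy$labels)
})

test_that("shrinkage is monotone and degenerates as forced by the formula", {
  toy <- nsc_toy()
  fit <- fit_nsc(toy$x, toy$labels, delta_grid = seq(0, 4, length.out = 12),
                 cv_folds = 2, seed = 1)
  nsel <- fit$cv_table$n_selected
  expect_true(all(diff(nsel) <= 0))
  # delta 0 keeps every gene with a nonzero contrast (g2, g3 have d = 0)
  expect_equal(nsel[1], 2L)

  # delta beyond max |d| selects nothing; classifier falls back to priors
  mt_big <- marker_table(fit, delta = max(abs(fit$d_ik)) + 1)
  expect_equal(nrow(mt_big), 0)
  pred <- nsc_classify(fit, toy$x, delta = max(abs(fit$d_ik)) + 1)
  # equal priors: discriminant collapses to the overall centroid for both
  # classes, ties resolved by class order
  expect_true(all(pred$labels == "a"))
})

test_that("classification respects priors, ties and missing genes", {
  toy <- nsc_toy()
  fit <- fit_nsc(toy$x, toy$labels, delta_grid = c(0, 1), cv_folds = 2,
                 seed = 1)
  # a sample exactly on the overall centroid is equidistant -> first class
  mid <- matrix(rowMeans(toy$x), ncol = 1,
                dimnames = list(rownames(toy$x), "mid"))
  expect_equal(unname(nsc_classify(fit, mid, delta = 0)$labels), "a")

  expect_error(nsc_classify(fit, toy$x[1:2, , drop = FALSE]), "missing")

  # doubling a prior strictly lowers that class's discriminant
  fit2 <- fit
  d1 <- nsc_classify(fit2, mid, delta = 0)$scores[, "b"]
  fit2$priors <- c(0.2, 0.8)
  d2 <- nsc_classify(fit2, mid, delta = 0)$scores[, "b"]
  expect_lt(d2, d1)

  expect_error(fit_nsc(toy$x, c("a", "b", "b", "b")), "single sample")
})

test_that("separable training data is recovered and markers are planted genes", {
  set.seed(40)
  n_per <- 10
  x <- matrix(rnorm(60 * 3 * n_per, sd = 1), 60)
  colnames(x) <- paste0("s", seq_len(3 * n_per))
  rownames(x) <- paste0("g", 1:60)
  labels <- rep(c("k1", "k2", "k3"), each = n_per)
  # plant 5 strong markers per class
  for (i in 1:3)
    x[(i - 1) * 5 + 1:5, labels == paste0("k", i)] <-
      x[(i - 1) * 5 + 1:5, labels == paste0("k", i)] + 4
  fit <- fit_nsc(x, labels, seed = 2)
  pred <- nsc_classify(fit, x)
  expect_equal(unname(pred$labels), labels)
  expect_true(all(paste0("g", 1:15) %in% fit$selected))
  # markers rank by |d'| within class
  mt <- marker_table(fit)
  k1 <- mt[mt$class == "k1", ]
  expect_equal(k1$score, sort(k1$score, decreasing = TRUE))
})

test_that("GLM marker scores flag degenerate fits and find markers", {
  set.seed(41)
  x <- rbind(flat = rep(3, 20),
             noise = rnorm(20),
             marker = c(rnorm(10, 0), rnorm(10, 3)))
  colnames(x) <- paste0("s", 1:20)
  labels <- rep(c("a", "b"), each = 10)
  sc <- glm_marker_score(x, labels, cap = 10)
  flat_b <- sc[sc$gene == "flat" & sc$class == "b", ]
  expect_equal(flat_b$score, 0)
  expect_true(flat_b$flagged)
  marker_b <- sc[sc$gene == "marker" & sc$class == "b", ]
  noise_b <- sc[sc$gene == "noise" & sc$class == "b", ]
  expect_gt(abs(marker_b$score), abs(noise_b$score))

  # perfect separation attains the cap and ranks top
  x2 <- rbind(sep = c(rep(0, 10), rep(10, 10)), noise = rnorm(20))
  colnames(x2) <- paste0("s", 1:20)
  sc2 <- glm_marker_score(x2, labels, cap = 10)
  sep_b <- sc2[sc2$gene == "sep" & sc2$class == "b", ]
  expect_equal(abs(sep_b$score), 10)
  expect_true(sep_b$flagged)

  # label permutation null: informative score exceeds permuted quantile
  perm_scores <- replicate(20, {
    pl <- sample(labels)
    s <- glm_marker_score(x, pl, cap = 10)
    abs(s$score[s$gene == "marker" & s$class == "b"])
  })
  expect_gt(abs(marker_b$score), quantile(perm_scores, 0.95))
})

test_that("the embedding is seeded, collapses duplicates, separates blobs", {
  X <- make_blobs(rbind(c(0, 0), c(15, 0), c(0, 15)), n_per = 12, seed = 8)
  e1 <- embed_2d(X, perplexity = 5, seed = 3)
  e2 <- embed_2d(X, perplexity = 5, seed = 3)
  expect_identical(e1$coords, e2$coords)
  expect_equal(nrow(e1$coords), nrow(X))

  # true labels remain separated in 2D
  sil <- silhouette_widths(as.matrix(dist(e1$coords)),
                           setNames(attr(X, "truth"), rownames(X)))
  expect_gt(mean(sil), 0.5)

  # duplicated rows land together
  Xd <- rbind(X, X[1, , drop = FALSE])
  rownames(Xd)[nrow(Xd)] <- "dup"
  ed <- embed_2d(Xd, perplexity = 5, seed = 3)
  d_dup <- sqrt(sum((ed$coords["dup", ] - ed$coords[rownames(X)[1], ])^2))
  d_typ <- median(dist(ed$coords))
  expect_lt(d_dup, d_typ / 10)

  expect_error(embed_2d(X, perplexity = 20), "perplexity")
})

test_that("the subgroup pipeline recovers planted groups end to end", {
  sim <- simulate_counts(800, c(g1 = 12, g2 = 12, g3 = 12),
                         de_fraction = 0.1, lfc_magnitude = 2,
                         dispersion = 0.2, seed = 15)
  pip <- subgroup_pipeline(sim$counts, seed = 15)
  expect_equal(pip$k, 3)
  core_ids <- names(pip$model$assignment)[pip$core]
  ari <- mclust::adjustedRandIndex(pip$model$assignment[core_ids],
                                   sim$truth$group[core_ids])
  expect_gte(ari, 0.9)
})
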