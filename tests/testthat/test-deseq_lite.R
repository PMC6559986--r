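test_that("size factors follow the median-of-ratios definition", {
  # all samples identical -> all factors 1
  m <- matrix(rep(c(5, 9, 2), 3), 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m)), rep(1, 3))

  # elementwise doubling -> factors (1/sqrt(2), sqrt(2))
  m2 <- cbind(A = c(10, 4, 7), B = c(20, 8, 14))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # documented 3x3 toy against a brute-force oracle
  toy <- rbind(g1 = c(2, 4, 8), g2 = c(10, 10, 10), g3 = c(1, 2, 1))
  colnames(toy) <- paste0("s", 1:3)
  geo <- apply(toy, 1, function(r) prod(r)^(1 / length(r)))
  brute <- apply(toy / geo, 2, median)
  brute <- brute / prod(brute)^(1 / 3)
  expect_equal(size_factors(toy), brute)

  # no gene positive everywhere -> advisory error
  z <- rbind(g1 = c(0, 3), g2 = c(2, 0)); colnames(z) <- c("a", "b")
  expect_error(size_factors(z), "pseudo-reference")
})

test_that("size factors are scale-equivariant", {
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(rpois(60, 40) + 1, 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    sf <- size_factors(m)
    c_ <- 3.7
    m2 <- m; m2[, 2] <- m[, 2] * c_
    sf2 <- size_factors(m2)
    # before geometric-mean rescaling the factor scales by c; the common
    # rescale divides every factor by c^(1/n)
    expect_equal(unname(sf2[2] / sf[2]), c_ / c_^(1 / 6), tolerance = 1e-10)
    expect_equal(unname(sf2[-2] / sf[-2]), rep(c_^(-1 / 6), 5),
                 tolerance = 1e-10)
  }
})

test_that("log normalization matches its closed form", {
  m <- rbind(g1 = c(0, 7), g2 = c(3, 3)); colnames(m) <- c("a", "b")
  e <- normalize_log(m, sf = c(a = 1, b = 1), pseudocount = 1)
  expect_equal(e["g1", "a"], 0)   # log2(0/1 + 1)
  expect_equal(e["g1", "b"], 3)   # log2(7/1 + 1)
  expect_error(normalize_log(m, sf = c(x = 1, y = 1)), "sample")
  expect_error(normalize_log(m, sf = c(a = 1, b = 1), pseudocount = 0),
               "pseudocount")

  # arbitrary per-sample depth scaling is equalized by refreshed factors:
  # normalized matrices agree up to a single global constant
  toy <- rbind(g1 = c(2, 4, 8), g2 = c(10, 10, 10), g3 = c(1, 2, 1))
  colnames(toy) <- paste0("s", 1:3)
  n1 <- sweep(toy, 2, size_factors(toy), "/")
  depth <- c(2, 5, 1)
  toy2 <- sweep(toy, 2, depth, "*")
  n2 <- sweep(toy2, 2, size_factors(toy2), "/")
  ratio <- n2 / n1
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("dispersion estimation floors and recovers", {
  # var < mean -> floor
  m <- matrix(rep(c(50, 51), 4), 2, 4, byrow = FALSE)
  m <- rbind(g1 = rep(c(50, 51), 2), g2 = rep(c(7, 7), 2))
  colnames(m) <- paste0("s", 1:4)
  al <- estimate_dispersions(m, c("a", "a", "b", "b"), sf = rep(1, 4))
  expect_equal(unname(al["g2"]), 1e-8)

  # zero-mean gene flagged NA
  mz <- rbind(g1 = c(5, 6, 4, 7), g0 = c(0, 0, 0, 0))
  colnames(mz) <- paste0("s", 1:4)
  alz <- estimate_dispersions(mz, c("a", "a", "b", "b"), sf = rep(1, 4))
  expect_true(is.na(alz["g0"]))

  # NB alpha = 0.5 recovered at n = 50 per group
  sim <- simulate_counts(2000, c(a = 50, b = 50), de_fraction = 0,
                         dispersion = 0.5, seed = 3)
  ah <- estimate_dispersions(sim$counts, sim$counts$sample_meta$condition)
  expect_gt(median(ah, na.rm = TRUE), 0.35)
  expect_lt(median(ah, na.rm = TRUE), 0.65)

  # Poisson data: median estimate collapses towards the floor
  simp <- simulate_counts(2000, c(a = 50, b = 50), de_fraction = 0,
                          dispersion = 0, seed = 4)
  ap <- estimate_dispersions(simp$counts, simp$counts$sample_meta$condition)
  expect_lt(median(ap, na.rm = TRUE), 0.01)
})

test_that("the NB Wald test recovers exact fold changes on noise-free data", {
  m <- rbind(g_de = c(10, 10, 20, 20),
             g2 = rep(100, 4), g3 = rep(40, 4), g4 = rep(7, 4),
             g0 = rep(0, 4))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  de <- nb_wald_de(cm(m, c("a", "a", "b", "b")), contrast = c("b", "a"))
  expect_equal(de$log2fc[de$gene == "g_de"], 1)
  expect_false(de$tested[de$gene == "g0"])
  expect_true(is.na(de$padj[de$gene == "g0"]))
  # BH denominator excludes the untested gene
  expect_equal(sum(de$tested), 4)
  expect_error(nb_wald_de(cm(m, rep("a", 4)), contrast = c("a", "a")),
               "contrast")
})

test_that("null p-values are calibrated and approximately uniform", {
  sim <- simulate_counts(2000, c(a = 10, b = 10), de_fraction = 0,
                         dispersion = 0.2, seed = 11)
  de <- nb_wald_de(sim$counts, contrast = c("b", "a"))
  p <- de$pvalue[de$tested]
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
  expect_lt(suppressWarnings(ks.test(p, "punif"))$statistic, 0.05)
})

test_that("rank shift tables match hand computation and are antisymmetric", {
  mk_de <- function(genes, fc) {
    structure(data.frame(gene = genes, log2fc = fc,
                         tested = TRUE, stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  genes <- paste0("g", 1:6)
  a <- mk_de(genes, c(5, 4, 3, 2, 1, 0))
  b <- mk_de(genes, c(0, 1, 2, 3, 4, 5))    # exact reversal

  same <- fold_change_rank_shift(a, a, top_n = 6)
  expect_true(all(same$delta == 0))

  rev_ <- fold_change_rank_shift(a, b, top_n = 6)
  expect_equal(rev_$delta[rev_$gene == "g1"], 5)  # n - 1

  # 6-gene toy with hand-assigned fold changes
  h_a <- mk_de(genes, c(2.0, 1.5, 3.0, -1.0, 0.5, 0.0))
  h_b <- mk_de(genes, c(0.5, 2.5, 1.0, 3.0, -2.0, 0.0))
  # hand ranks A: g3=1 g1=2 g2=3 g5=4 g6=5 g4=6
  #            B: g4=1 g2=2 g3=3 g1=4 g6=5 g5=6
  tab <- fold_change_rank_shift(h_a, h_b, top_n = 3)
  expect_equal(tab$gene, c("g3", "g1", "g2"))
  expect_equal(tab$rank_a, 1:3)
  expect_equal(tab$rank_b, c(3, 4, 2))
  expect_equal(tab$delta, c(2, 2, -1))

  # antisymmetry on the shared top set
  ab <- fold_change_rank_shift(h_a, h_b, top_n = 6)
  ba <- fold_change_rank_shift(h_b, h_a, top_n = 6)
  expect_equal(ab$delta[match(genes, ab$gene)],
               -ba$delta[match(genes, ba$gene)])

  # display threshold is a flag, not a filter
  big <- mk_de(genes, c(4, 3.7, 1, 0, -1, -4))
  tb <- fold_change_rank_shift(big, big, top_n = 6, highlight_fold = 12)
  expect_equal(sum(tb$highlight), 3)
  expect_equal(nrow(tb), 6)

  expect_error(fold_change_rank_shift(mk_de("x", 1), mk_de("y", 1), 1),
               "disjoint")
})

test_that("group comparison runs ANOVA per measurement with BH", {
  vals <- cbind(m1 = c(1, 1, 1, 1, 1, 1),
                m2 = c(1, 2, 1.5, 8, 9, 8.5),
                m3 = c(5, 6, 5.5, 5.2, 6.1, 5.4))
  g <- c("x", "x", "x", "y", "y", "y")
  res <- group_compare(vals, g)
  expect_equal(res$F[res$measurement == "m1"], 0)
  expect_equal(res$pvalue[res$measurement == "m1"], 1)
  # oracle: plain one-way ANOVA for m2
  ref <- anova(lm(vals[, "m2"] ~ factor(g)))
  expect_equal(res$F[res$measurement == "m2"], ref[["F value"]][1])
  expect_equal(res$pvalue[res$measurement == "m2"], ref[["Pr(>F)"]][1])
  # BH by its step-up definition
  p <- res$pvalue
  brute_bh <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * n / (n:1)))[ro]
  }
  expect_equal(res$padj, brute_bh(p))

  single <- group_compare(vals[, "m2", drop = FALSE], g)
  expect_equal(single$padj, single$pvalue)

  expect_error(group_compare(vals, c("x", "x", "x", "x", "x", "y")),
               "< 2 observations")
})
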