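test_that("signature loading enforces the four reserved set names", {
  sigs <- synthetic_state_signatures(50)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sigs, gmt)
  loaded <- load_signatures(gmt)
  expect_setequal(names(loaded), c("A1", "A2", "fetal", "adult"))
  expect_true(all(lengths(loaded) == 50))
  ov <- attr(loaded, "overlap")
  expect_equal(unname(diag(ov)), rep(50L, 4))
  expect_true(all(ov[upper.tri(ov)] == 0))

  # bundled fixture file loads identically
  fixture <- system.file("extdata", "synthetic_state_signatures.gmt",
                         package = "gliastate")
  expect_true(nzchar(fixture))
  expect_equal(lengths(load_signatures(fixture)), lengths(loaded))

  # missing set is named in the error
  write_gmt(sigs[c("A1", "fetal", "adult")], gmt)
  expect_error(load_signatures(gmt), "A2")

  # duplicated genes collapse with a warning, size reported after dedup
  lines <- readLines(system.file("extdata", "synthetic_state_signatures.gmt",
                                 package = "gliastate"))
  lines[1] <- paste(lines[1], "SYN0001", sep = "\t")
  writeLines(lines, gmt)
  expect_warning(dup <- load_signatures(gmt), "duplicated")
  expect_equal(lengths(dup)[["A1"]], 50L)
})

test_that("state scores are zero on flat data and detect planted elevation", {
  sigs <- synthetic_state_signatures(10)
  genes <- unlist(sigs, use.names = FALSE)
  flat <- matrix(5, length(genes), 6,
                 dimnames = list(genes, paste0("s", 1:6)))
  sc <- score_states(flat, sigs, min_genes = 5)
  expect_true(all(abs(as.matrix(sc[, -1])) < 1e-12))

  # elevate A1 genes in one sample
  up <- flat + matrix(rnorm(length(flat), 0, 0.05), nrow(flat))
  up[sigs$A1, "s3"] <- up[sigs$A1, "s3"] + 2
  sc2 <- score_states(up, sigs, min_genes = 5)
  expect_equal(sc2$sample[which.max(sc2$score_A1)], "s3")
  expect_gt(sc2$score_A1[sc2$sample == "s3"],
            max(abs(sc2$score_A2[sc2$sample == "s3"]),
                abs(sc2$score_fetal[sc2$sample == "s3"])))

  # gene-wise affine rescaling leaves scores untouched (z-scoring)
  scale_ <- runif(nrow(up), 0.5, 3); shift <- rnorm(nrow(up), 0, 4)
  aff <- up * scale_ + shift
  sc3 <- score_states(aff, sigs, min_genes = 5)
  expect_equal(as.matrix(sc3[, -1]), as.matrix(sc2[, -1]), tolerance = 1e-10)

  # min_genes flags small overlaps; zero overlap is an error
  tiny <- flat[c(sigs$A1, sigs$A2, sigs$fetal, sigs$adult[1:3]), ]
  sc4 <- score_states(tiny, sigs, min_genes = 5)
  expect_true(attr(sc4, "flagged")[["adult"]])
  expect_error(score_states(flat[sigs$A1, ], sigs), "no genes")
})

test_that("coordinates and labels follow the declared axis rule", {
  mk <- function(a1, a2, f, ad) {
    structure(data.frame(sample = paste0("s", seq_along(a1)),
                         score_A1 = a1, score_A2 = a2,
                         score_fetal = f, score_adult = ad,
                         stringsAsFactors = FALSE),
              flagged = setNames(rep(FALSE, 4),
                                 c("A1", "A2", "fetal", "adult")),
              class = c("signature_scores", "data.frame"))
  }
  # all four equal -> origin, unclassified
  eq <- state_coordinates(mk(0.3, 0.3, 0.3, 0.3))
  expect_equal(eq$x, 0); expect_equal(eq$y, 0)
  expect_equal(eq$state, "unclassified")

  sc <- mk(c(0.1, 0.8), c(0.9, 0.1), c(0.2, 0.1), c(0.1, 0.9))
  co <- state_coordinates(sc)
  expect_equal(co$state, c("alternative", "mature"))

  # swapping fetal and adult negates x, leaves y unchanged
  sw <- state_coordinates(mk(c(0.1, 0.8), c(0.9, 0.1),
                             c(0.1, 0.9), c(0.2, 0.1)))
  expect_equal(sw$x, -co$x)
  expect_equal(sw$y, co$y)

  # exchanging A1 and A2 negates y for every sample (equivariance)
  ex <- state_coordinates(mk(c(0.9, 0.1), c(0.1, 0.8),
                             c(0.2, 0.1), c(0.1, 0.9)))
  expect_equal(ex$y, -co$y)
  expect_equal(ex$x, co$x)

  # margin rule
  m <- state_coordinates(mk(0, 0.2, 0, 0), margin = 0.25)
  expect_equal(m$state, "unclassified")
  m2 <- state_coordinates(mk(0, 0.3, 0, 0), margin = 0.25)
  expect_equal(m2$state, "alternative")
})

test_that("planted-state cohorts are recovered on NB count data", {
  sigs <- synthetic_state_signatures(50)
  pool <- unlist(sigs, use.names = FALSE)
  states <- c("A1", "A2", "fetal", "adult")
  truth_label <- c(A1 = "inflammatory", A2 = "alternative",
                   fetal = "progenitor", adult = "mature")
  sim <- simulate_counts(1000, c(c1 = 40, c2 = 40), de_fraction = 0,
                         dispersion = 0.2, seed = 31)
  counts <- sim$counts$counts
  rownames(counts)[1:200] <- pool
  x <- count_matrix(counts)
  planted <- setNames(rep(states, each = 20), colnames(counts))
  for (st in states)
    x <- inject_state_signature(x, sigs[[st]],
                                names(planted)[planted == st],
                                effect_log2 = 1, seed = 100 + match(st, states))
  co <- state_coordinates(score_states(normalize_log(x), sigs))
  acc <- mean(co$state[match(names(planted), co$sample)] ==
                truth_label[planted])
  expect_gte(acc, 0.9)

  # double-planted samples (fetal + A2) land in the upper-right quadrant
  x2 <- count_matrix(counts)
  both <- names(planted)[1:20]
  x2 <- inject_state_signature(x2, sigs$fetal, both, 1, seed = 7)
  x2 <- inject_state_signature(x2, sigs$A2, both, 1, seed = 8)
  co2 <- state_coordinates(score_states(normalize_log(x2), sigs))
  ur <- co2$x[match(both, co2$sample)] > 0 & co2$y[match(both, co2$sample)] > 0
  expect_gte(mean(ur), 0.95)
})

test_that("cohort reports conserve counts and track planted shifts", {
  co <- structure(data.frame(sample = paste0("s", 1:5),
                             x = c(1, 2, -1, -2, 0.1),
                             y = c(0.5, 0.4, -0.3, -0.2, 0),
                             state = c("progenitor", "progenitor", "mature",
                                       "mature", "unclassified"),
                             stringsAsFactors = FALSE),
                  class = c("state_coordinates", "data.frame"))
  rep_ <- state_report(co, c("t", "t", "c", "c", "c"))
  expect_equal(rep_$n, c(2, 3))
  cnt_cols <- grep("^n_", names(rep_), value = TRUE)
  cnt_cols <- setdiff(cnt_cols, "n")
  expect_equal(rowSums(rep_[, cnt_cols]), rep_$n, ignore_attr = TRUE)
  # opposite planted shifts -> opposite centroid signs
  expect_gt(rep_$centroid_x[rep_$cohort == "t"], 0)
  expect_lt(rep_$centroid_x[rep_$cohort == "c"], 0)

  single <- state_report(co[1, ], "solo")
  expect_equal(single$centroid_x, co$x[1])
  expect_error(state_report(co[0, ], character()), "empty")
})
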