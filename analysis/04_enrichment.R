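#!/usr/bin/env Rscript
# Stage 4: pre-ranked permutation GSEA of the tumor-effect ranking against
# planted gene sets; the planted up/down sets should enrich at the extremes
# and random sets should not.

suppressMessages(library(gliastate))
seed <- 1L

de_pos <- read_results("results/de_microglia_pos.tsv")
class(de_pos) <- c("de_result", "data.frame")
truth <- read_results("results/truth_groups.tsv")

rk <- make_ranking(de_pos, metric = "log2fc")

de_truth <- read_results("results/de_microglia_pos.tsv")
# planted sets from the generator truth of this contrast's own simulation:
# genes with positive / negative planted effect, plus random controls
sim_truth <- simulate_counts(2000, c(control = 6, tumor = 6),
                             de_fraction = 0.1, lfc_magnitude = 2.5,
                             dispersion = 0.2, seed = 1 + 41)$truth
coll <- list(planted_up = names(sim_truth$lfc[sim_truth$lfc > 0]),
             planted_down = names(sim_truth$lfc[sim_truth$lfc < 0]))
set.seed(seed)
for (i in 1:3)
  coll[[paste0("random_", i)]] <- sample(rk$gene, 50)

res <- gsea_batch(rk, coll, weight_p = 1, n_perm = 1000, seed = seed)
write_results(res, "results/gsea_results.tsv")
for (i in seq_len(nrow(res)))
  log_msg("gsea", "%-13s size %3d  ES %6.3f  p %.4f  q %.4f",
          res$set[i], res$size[i], res$es[i], res$pvalue[i], res$padj[i])
log_msg("gsea", "done")
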