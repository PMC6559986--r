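#!/usr/bin/env Rscript
# Stage 2: normalization, differential expression in the two microglia
# contexts, and the fold-change rank-shift comparison between them.

suppressMessages(library(gliastate))
seed <- 1L

pos <- read_count_matrix("results/counts_microglia_pos.tsv",
                         sample_meta = data.frame(
                           condition = rep(c("control", "tumor"), each = 6)))
neg <- read_count_matrix("results/counts_microglia_neg.tsv",
                         sample_meta = data.frame(
                           condition = rep(c("control", "tumor"), each = 6)))

log_msg("de", "size factors (microglia+): %s",
        paste(round(size_factors(pos), 3), collapse = " "))

de_pos <- nb_wald_de(pos, contrast = c("tumor", "control"))
de_neg <- nb_wald_de(neg, contrast = c("tumor", "control"))
write_results(de_pos, "results/de_microglia_pos.tsv")
write_results(de_neg, "results/de_microglia_neg.tsv")
log_msg("de", "microglia+: %d genes at q < 0.05; microglia-: %d",
        sum(de_pos$padj < 0.05, na.rm = TRUE),
        sum(de_neg$padj < 0.05, na.rm = TRUE))

# rank shift of the 30 strongest tumor-induced genes between contexts
rs <- fold_change_rank_shift(de_pos, de_neg, top_n = 30)
write_results(rs, "results/rank_shift_top30.tsv")
log_msg("de", "rank shift: median |delta| = %.0f over the top 30",
        median(abs(rs$delta)))

# figure-legend style group statistics on per-sample summary measurements
expr <- normalize_log(pos)
meas <- data.frame(total_signal = colSums(expr),
                   top_gene = expr[which.max(rowMeans(expr)), ])
gc <- group_compare(meas, pos$sample_meta$condition)
write_results(gc, "results/group_compare.tsv")
log_msg("de", "done")
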