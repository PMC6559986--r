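#!/usr/bin/env Rscript
# Stage 6: FACS post-processing -- arcsinh transform, astrocyte gating
# (ZsGreen-negative / HepaCAM-positive), per-cell over-dispersion, distance
# embedding with cluster selection, and cluster x condition summaries.

suppressMessages(library(gliastate))
seed <- 902L

tab <- read_results("results/facs_intensities.tsv")
inten <- as.matrix(tab[, setdiff(names(tab), c("cell", "condition"))])
rownames(inten) <- tab$cell
f <- facs_matrix(inten, condition = tab$condition)

ft <- transform_intensities(f, cofactor = 150)
g <- apply_gates(ft, gate_spec(c("ZsGreen", "HepaCAM"),
                               c("below", "above"), c(0.5, 0.7)))
write_results(g$report, "results/facs_gating_report.tsv")
log_msg("facs", "gated %d -> %d cells", nrow(ft$intensities),
        nrow(g$gated$intensities))

od <- data.frame(cell = rownames(g$gated$intensities),
                 var_mean = cell_overdispersion(g$gated, "var_mean"),
                 cv2 = cell_overdispersion(g$gated, "cv2"),
                 fano = cell_overdispersion(g$gated, "fano"))
write_results(od, "results/facs_overdispersion.tsv")

emb <- cell_distance_embedding(g$gated, perplexity = 30, seed = seed)
log_msg("facs", "clustering channels: %s; selected k = %d",
        paste(emb$channels, collapse = ", "), emb$k)
write_results(data.frame(cell = rownames(emb$embedding$coords),
                         emb$embedding$coords,
                         cluster = unname(emb$clusters),
                         condition = unname(g$gated$condition)),
              "results/facs_embedding.tsv")

sm <- cluster_condition_summary(g$gated, emb$clusters)
write_results(sm, "results/facs_cluster_summary.tsv")
hot <- sapply(split(seq_len(nrow(sm)), sm$cluster), function(ix)
  weighted.mean(sm[["mean_STAT3-P"]][ix] + sm[["mean_KI67"]][ix],
                sm$n_cells[ix], na.rm = TRUE))
log_msg("facs", "STAT3-P/KI67-high cluster: %s (dominant condition: %s)",
        names(which.max(hot)),
        {tr <- sm[sm$cluster == names(which.max(hot)), ]
         tr$condition[which.max(tr$n_cells)]})
log_msg("facs", "done")
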