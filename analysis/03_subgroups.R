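#!/usr/bin/env Rscript
# Stage 3: unsupervised subgroup discovery on the three-group cohort --
# PAM with silhouette-selected k, core-sample filtering, NSC markers,
# consensus validation and a 2D embedding.

suppressMessages(library(gliastate))
seed <- 21L

cm <- read_count_matrix("results/counts_groups.tsv")
truth <- read_results("results/truth_groups.tsv")

pip <- subgroup_pipeline(cm, seed = seed)
log_msg("cluster", "selected k = %d; %d/%d core samples",
        pip$k, sum(pip$core), length(pip$core))

write_results(data.frame(sample = names(pip$model$assignment),
                         cluster = unname(pip$model$assignment),
                         silhouette = unname(pip$model$silhouette),
                         core = unname(pip$core)),
              "results/cluster_assignments.tsv")
write_results(pip$profile, "results/silhouette_profile.tsv")
write_results(pip$markers, "results/marker_table.tsv")
log_msg("markers", "delta = %.2f selects %d marker genes",
        pip$fit$delta, length(pip$fit$selected))

planted <- truth$gene[truth$lfc != 0]
log_msg("markers", "planted-marker recall %.2f",
        mean(planted %in% pip$fit$selected))

# consensus validation on the filtered expression
keep <- top_variable_genes(pip$expr, 200)
D <- expr_dissimilarity(pip$expr[keep, ])
cons <- consensus_cluster(D, pip$k, n_resample = 100, subsample_frac = 0.8,
                          seed = seed)
log_msg("cluster", "mean within-cluster consensus %.3f", cons$mean_within)
write_results(data.frame(sample = rownames(cons$consensus),
                         cons$consensus, check.names = FALSE),
              "results/consensus_matrix.tsv")

emb <- embed_2d(t(pip$expr[keep, ]), perplexity = 10, seed = seed)
write_results(data.frame(sample = rownames(emb$coords), emb$coords,
                         cluster = unname(pip$model$assignment)),
              "results/embedding_samples.tsv")
log_msg("cluster", "done")
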