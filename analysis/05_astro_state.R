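#!/usr/bin/env Rscript
# Stage 5: four-signature astrocyte state scoring and the 2D
# differentiation/reactivity map on the planted-state cohort.

suppressMessages(library(gliastate))

xa <- read_count_matrix("results/counts_states.tsv")
sigs <- load_signatures("results/state_signatures.gmt")
truth <- read_results("results/truth_states.tsv")

expr <- normalize_log(xa)
sc <- score_states(expr, sigs)
co <- state_coordinates(sc)
write_results(sc, "results/state_scores.tsv")
write_results(co, "results/state_coordinates.tsv")

truth_label <- c(A1 = "inflammatory", A2 = "alternative",
                 fetal = "progenitor", adult = "mature")
acc <- mean(co$state[match(truth$sample, co$sample)] ==
              truth_label[truth$planted_state])
log_msg("astro_state", "planted-state recovery %.1f%%", 100 * acc)

rep_ <- state_report(co, truth_label[truth$planted_state])
write_results(rep_, "results/state_report.tsv")
print(rep_[, c("cohort", "n", "centroid_x", "centroid_y")])
log_msg("astro_state", "done")
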