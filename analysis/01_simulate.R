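#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data used by all later stages.
#
# Three artifacts, mirroring the study design:
#   - bulk counts with three planted sample groups (subgroup discovery, DE),
#   - a two-context DE design (tumor effect with vs without microglia),
#   - a four-state astrocyte cohort with planted signatures,
#   - a FACS intensity table from the four-condition slice preset.

suppressMessages(library(gliastate))
dir.create("results", showWarnings = FALSE)
seed <- 1L

log_msg("simulate", "bulk counts: 3 groups x 20 samples, 2000 genes")
sim3 <- simulate_counts(2000, c(g1 = 20, g2 = 20, g3 = 20),
                        de_fraction = 0.1, lfc_magnitude = 2,
                        dispersion = 0.2, seed = seed + 20)
write_count_matrix(sim3$counts, "results/counts_groups.tsv")
write_results(data.frame(gene = names(sim3$truth$lfc),
                         lfc = sim3$truth$lfc,
                         target_group = sim3$truth$target_group),
              "results/truth_groups.tsv")
write_results(data.frame(sample = colnames(sim3$counts$counts),
                         condition = sim3$counts$sample_meta$condition),
              "results/samples_groups.tsv")

log_msg("simulate", "two-context DE design (microglia present / depleted)")
# tumor effect is strong with microglia present, attenuated without:
# emulated by two two-group simulations sharing a gene universe
sim_mg <- simulate_counts(2000, c(control = 6, tumor = 6), de_fraction = 0.1,
                          lfc_magnitude = 2.5, dispersion = 0.2,
                          seed = seed + 41)
sim_nomg <- simulate_counts(2000, c(control = 6, tumor = 6), de_fraction = 0.1,
                            lfc_magnitude = 1.0, dispersion = 0.2,
                            seed = seed + 41)  # same planted genes, weaker
write_count_matrix(sim_mg$counts, "results/counts_microglia_pos.tsv")
write_count_matrix(sim_nomg$counts, "results/counts_microglia_neg.tsv")

log_msg("simulate", "astro-state cohort: 4 planted states x 20 samples")
sigs <- synthetic_state_signatures(50)
write_gmt(sigs, "results/state_signatures.gmt")
sim_a <- simulate_counts(1000, c(c1 = 40, c2 = 40), de_fraction = 0,
                         dispersion = 0.2, seed = seed + 800)
counts <- sim_a$counts$counts
rownames(counts)[1:200] <- unlist(sigs, use.names = FALSE)
xa <- count_matrix(counts)
states <- c("A1", "A2", "fetal", "adult")
planted <- setNames(rep(states, each = 20), colnames(counts))
for (st in states)
  xa <- inject_state_signature(xa, sigs[[st]],
                               names(planted)[planted == st], effect_log2 = 1,
                               seed = seed + 800 + match(st, states))
write_count_matrix(xa, "results/counts_states.tsv")
write_results(data.frame(sample = names(planted), planted_state = planted),
              "results/truth_states.tsv")

log_msg("simulate", "FACS: four-condition slice preset, 100 cells/population")
f <- simulate_facs(facs_preset(100), seed = seed + 901)
write_results(data.frame(cell = rownames(f$intensities),
                         condition = unname(f$condition),
                         f$intensities, check.names = FALSE),
              "results/facs_intensities.tsv")

log_msg("simulate", "done; wrote results/*.tsv + state_signatures.gmt")
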