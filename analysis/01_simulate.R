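#!/usr/bin/env Rscript
# Stage 1: draw the synthetic serum miRNA cohort that stands in for the
# study samples (754 targets; 60 CNT vs 67 END split 40 OMA / 27 DIE;
# detection limit Cq = 40; 3 planted stable references; 20 planted group
# effects with |dCt| in [1.5, 4]) and write it as long-format TSV fixtures
# together with the planted ground truth.

suppressPackageStartupMessages(library(mircq))

seed <- 20260901L
cfg <- sim_config(seed = seed, effect_range = c(1.5, 4))
sim <- simulate_cohort(cfg)

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)
paths <- write_fixture(sim$ct, sim$samples, "results/cohort")

write.table(data.frame(target_id = sim$truth$reference_ids),
            "results/cohort/truth_references.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$de_effects, "results/cohort/truth_de_effects.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = sim$truth$hemolysed_ids),
            "results/cohort/truth_hemolysed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("cohort: %d targets x %d samples -> %s",
                nrow(sim$ct$values), ncol(sim$ct$values), paths["cq"]))
message(sprintf("planted: %d references, %d DE targets, %d hemolysed samples",
                length(sim$truth$reference_ids),
                length(unique(sim$truth$de_effects$target_id)),
                length(sim$truth$hemolysed_ids)))
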