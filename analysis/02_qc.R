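#!/usr/bin/env Rscript
# Stage 2: well-level QC (amplification score > 1, Cq confidence > 0.8,
# Cq >= 6), hemolysis screen on the miR-23a-3p / miR-451a pair (delta Cq < 8
# acceptable), and the 75% group-wise detection filter for the END/CNT pair.

suppressPackageStartupMessages(library(mircq))

rt <- read_ct_long("results/cohort/cq_long.tsv", "results/cohort/samples.tsv")
qc <- apply_well_qc(rt$ct)
samples <- hemolysis_check(qc$ct, rt$samples)
samples$analysis_set <- is.na(samples$hemolysis_pass) | samples$hemolysis_pass

ct_an <- qc$ct[, which(samples$analysis_set)]
sam_an <- samples[samples$analysis_set, ]
cand <- detection_filter(ct_an, sam_an, c("END", "CNT"), min_frac = 0.75)

dir.create("results", showWarnings = FALSE)
write.table(samples, "results/qc_samples.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(target_id = target_ids(cand),
                       detected_frac = detected_fraction(cand)),
            "results/qc_detected_targets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("wells removed by QC: %d", qc$n_removed))
message(sprintf("hemolysed samples excluded: %d (of %d)",
                sum(!samples$hemolysis_pass, na.rm = TRUE), nrow(samples)))
message(sprintf("targets detected in >= 75%% of either group: %d of %d",
                nrow(cand$values), nrow(rt$ct$values)))
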