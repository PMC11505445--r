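#!/usr/bin/env Rscript
# Stage 5: over-representation analysis of the target genes of the
# significant END/CNT miRNAs against a synthetic annotation in which one
# pathway is planted on the targets of the truly DE miRNAs. With real data
# this stage takes a validated miRNA-target TSV and GMT collections instead.

suppressPackageStartupMessages(library(mircq))

seed <- 20260901L
de <- read.delim("results/de_END_vs_CNT.tsv")
sig <- de$target_id[de$significant]
truth <- read.delim("results/cohort/truth_de_effects.tsv")
detected <- read.delim("results/qc_detected_targets.tsv")$target_id

ann <- simulate_annotation(detected,
                           planted_ids = unique(truth$target_id),
                           seed = seed)
mt <- map_targets(sig, ann$target_map)
universe <- sort(unique(unlist(ann$target_map)))
enr <- ora_test(mt$genes, ann$pathways, universe)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("query: %d genes from %d significant miRNAs (universe %d)",
                length(mt$genes), length(sig), length(universe)))
top <- enr[1, ]
message(sprintf("top pathway: %s (k=%d/K=%d, FDR=%.2g)%s", top$pathway,
                top$k, top$K, top$fdr,
                if (identical(top$pathway, ann$planted_pathway))
                  " -- the planted pathway" else ""))
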