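#!/usr/bin/env Rscript
# Stage 5: nascent-RNA differential expression between EPO+ and EPO-
# (fold >= 1.5, FDR < 0.05), replicate QC, and CAGE time-course dynamics
# (immediate <= 60 min vs delayed vs unresponsive at 2-fold response).

suppressPackageStartupMessages(library(epotargets))

ct <- read_counts("results/synthetic/counts.tsv", "results/synthetic/design.tsv")
dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)

r <- replicate_correlation(ct)
cat("Replicate Spearman correlation:",
    paste(names(r), round(r, 3), sep = " = ", collapse = ", "), "\n")

degs <- call_degs(ct)
write.table(degs, "results/expression/degs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("DEGs:", sum(degs$call == "induced"), "induced,",
    sum(degs$call == "repressed"), "repressed of", nrow(degs), "genes\n")
top <- degs[degs$call == "induced", ]
top <- top[order(-top$fold_change), ][1:5, ]
cat("Top induced fold changes:",
    paste(sprintf("%s %.1f", top$gene_id, top$fold_change), collapse = ", "),
    "\n")

cage <- read_cage_series("results/synthetic/cage.tsv")
dyn <- classify_cage_dynamics(cage)
write.table(dyn, "results/expression/cage_dynamics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CAGE dynamics:", sum(dyn$class == "immediate"), "immediate,",
    sum(dyn$class == "delayed"), "delayed,",
    sum(dyn$class == "unresponsive"), "unresponsive\n")
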