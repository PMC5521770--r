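#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study at the scale of the real one --
# 302 pSTAT5 peaks with planted feature classes and central GAS motifs,
# KLF1/GATA1 co-occupancy at 67 and 147 sites, a replicated EPO+/EPO-
# nascent-RNA count table with 63 induced and 24 repressed genes
# (fold changes 1.5-8.4), and a 0-24 h CAGE time course.
#
# Writes the raw inputs consumed by stages 02-06 under results/synthetic/.

suppressPackageStartupMessages(library(epotargets))

seed <- as.integer(Sys.getenv("EPOTARGETS_SEED", "1"))
outdir <- "results/synthetic"
cfg <- sim_config(seed = seed)
sim <- simulate_study(cfg, outdir)

cat("Synthetic study written to", outdir, "\n")
cat("  chromosomes:", cfg$n_chroms, "x", format(cfg$chrom_length, big.mark = ","), "nt\n")
cat("  genes:      ", nrow(sim$genome$genes), "\n")
cat("  peaks:      ", nrow(sim$peaks$reference), "\n")
cat("  planted DEGs:", cfg$n_induced, "induced /", cfg$n_repressed, "repressed\n")
cat("  CAGE regions:", nrow(sim$cage$counts), "\n")
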