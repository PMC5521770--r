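#!/usr/bin/env Rscript
# Stage 4: TF co-occupancy (summits within 500 bp) and the clustered signal
# heatmap: reads-per-million signal in 50 bins, clustered on the 500 bp
# around the summit with the nearest-neighbour chain algorithm, displayed
# over 10 kb.

suppressPackageStartupMessages(library(epotargets))

ref <- read_peaks("results/synthetic/pSTAT5.narrowPeak", "narrowPeak")
others <- list(KLF1 = read_peaks("results/synthetic/KLF1.narrowPeak", "narrowPeak"),
               GATA1 = read_peaks("results/synthetic/GATA1.narrowPeak", "narrowPeak"))
dir.create("results/cooccupancy", showWarnings = FALSE, recursive = TRUE)

v <- venn_counts(ref, others, max_dist = 500)
jsonlite::write_json(v, "results/cooccupancy/venn.json", auto_unbox = TRUE,
                     digits = NA)
cat("Co-occupancy of", nrow(ref), "pSTAT5 sites (summits within 500 bp):\n")
print(v$totals)
print(v$regions)

bm <- binding_matrix(ref, others)
write.table(data.frame(peak = rownames(bm), bm),
            "results/cooccupancy/binding_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tracks <- list(pSTAT5 = read_signal("results/synthetic/pSTAT5.bedGraph"),
               KLF1 = read_signal("results/synthetic/KLF1.bedGraph"),
               GATA1 = read_signal("results/synthetic/GATA1.bedGraph"))
ho <- heatmap_order(tracks, ref, cluster_half_width = 250,
                    display_half_width = 5000, n_bins = 50)
writeLines(ho$order, "results/cooccupancy/heatmap_row_order.txt")
for (nm in names(ho$display)) {
  write.table(round(ho$display[[nm]], 5),
              file.path("results/cooccupancy",
                        paste0("heatmap_", nm, ".tsv")),
              sep = "\t", quote = FALSE, col.names = FALSE)
}
cat("Heatmap rows clustered;", length(ho$tree$height), "merges, first split at height",
    round(max(ho$tree$height), 3), "\n")
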