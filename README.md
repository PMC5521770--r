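# epotargets

Identification of direct pSTAT5 target genes from ChIP-seq and nascent
transcriptomics.

EPO drives red-blood-cell production through EpoR–JAK2–STAT5: activated
(phosphorylated) STAT5 dimers bind GAS elements (consensus
`TTCYMRGAA`) in promoters and enhancers and re-program transcription in
erythroid progenitors. Deciding which EPO-responsive genes are *direct*
pSTAT5 targets requires joining two measurements that rarely agree on
their own: where pSTAT5 binds (ChIP-seq peaks with summits) and which
genes respond (4sU-labelled nascent RNA-seq shortly after stimulation,
corroborated by CAGE promoter time courses). This package implements
that integration as a reusable, tested pipeline for anyone analysing a
TF-response experiment of this shape:

* **Peak annotation** — nearest TSS, signed distance, and feature class
  (promoter = 1 kb upstream/100 nt downstream of any TSS; then
  UTR/CDS/intron inside gene bodies; distal within 50 kb of a gene
  body; else intergenic), classified at the summit.
* **Motif analysis** — IUPAC consensus and PWM scanning on both
  strands, plus a central-enrichment statistic: the best site per
  summit-centred sequence, a binomial tail over candidate central
  windows `P(X ≥ k | n, p0)`, Bonferroni-adjusted over windows.
* **Co-occupancy** — factors co-occupy a site when summits lie within
  500 bp; binding matrices and Venn counts.
* **Clustered signal heatmaps** — reads-per-million signal in 50 bins
  around summits, log-transformed, max-normalized per track, row-ordered
  by nearest-neighbour-chain hierarchical clustering (provably identical
  to naive agglomerative clustering for reducible linkages).
* **Differential expression** — median-of-ratios normalization, exact
  conditional binomial test on pooled counts, BH-FDR, and calls at
  fold ≥ 1.5 / FDR < 0.05; replicate QC by Spearman correlation of
  log FPKM.
* **CAGE dynamics** — RLE normalization and immediate (≤ 60 min peak) /
  delayed / unresponsive classification at a 2-fold response threshold.
* **Target classification** — peaks link to all TSSs within 100 kb;
  DEGs with a linked peak are *direct* (promoter- or enhancer-bound),
  DEGs without are *pSTAT5-independent*, and peaks whose linked genes
  are all unresponsive are *bound-unresponsive*.
* **Synthetic data** — a seeded generator that emulates the study's
  structure (302 peaks, 67/147 co-occupied sites, 63 induced + 24
  repressed genes with folds 1.5–8.4, a 0–24 h CAGE grid) with a
  planted-truth record, so every stage is testable by recovery.

See `vignettes/methods.Rmd` for the statistical details and design
rationale.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers
(`01_simulate.R` … `06_classify_targets.R`), which write their tables
under `results/`. Running them in order on the default configuration:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_annotate_peaks.R
Rscript analysis/05_expression.R
Rscript analysis/06_classify_targets.R
```

prints, among other things:

```
Annotated 302 peaks; feature-class fractions:
  promoter        UTR        CDS     intron     distal intergenic
     0.232      0.050      0.050      0.351      0.199      0.119
Planted-class agreement: 100 %

Replicate Spearman correlation: EPO+ = 0.99, EPO- = 0.987
DEGs: 59 induced, 29 repressed of 341 genes
Top induced fold changes: gene277 9.4, gene017 8.4, gene271 7.8, ...

Scenarios: direct = 37, independent = 51, background = 253
Bound-unresponsive peaks: 226
Planted scenario recovery: 96.2 %
```

Reading: ~23% of peaks sit in promoters and the rest in
intronic/distal/intergenic positions (enhancer-like), annotation
recovers every planted feature class; the caller finds 59/29
differentially expressed genes against 63/24 planted; integrating peaks
and DEGs classifies 37 genes as direct targets and 51 as responding
independently of binding, with 96% agreement against the planted
scenario labels. Stage 3 additionally shows the GAS element sharply
centrally enriched at summits (adjusted p ≈ 0, window 1 nt), the
specificity signature of a clean ChIP, and stage 4 recovers the planted
67 KLF1- and 147 GATA1-co-occupied sites exactly.

The same stages run on real data by pointing the readers at your own
narrowPeak/GTF/TSV files, or in one call via `run_pipeline()`:

```r
library(epotargets)
res <- run_pipeline(
  list(peaks = "pSTAT5.narrowPeak", gtf = "genes.gtf",
       counts = "counts.tsv", design = "design.tsv"),
  outdir = "out")
```

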