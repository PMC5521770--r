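# Feature annotation of peak summits against gene models.
#
# Distances are signed in gene orientation: negative = upstream of the TSS.
# A summit is "promoter" when its oriented distance to ANY TSS falls in
# [-promoter_up, +promoter_down] (inclusive); the nearest gene reported
# alongside may differ, since the promoter test is a window test, not a
# nearest-gene test.

FEATURE_CLASSES <- c("promoter", "UTR", "CDS", "intron", "distal", "intergenic")

signed_tss_distance <- function(summit, tss, strand) {
  ifelse(strand == "+", summit - tss, tss - summit)
}

#' Nearest TSS for a summit
#'
#' Finds the gene whose TSS is closest to the summit on the same chromosome.
#' The distance is signed in gene orientation (`summit - tss` on +,
#' `tss - summit` on -; negative = upstream). Ties on `|distance|` go to
#' the lexicographically smallest `gene_id` (and are messaged).
#'
#' @param chrom Chromosome of the summit.
#' @param summit Absolute 0-based summit position.
#' @param genes Gene model table from [read_gene_models()].
#' @return A list with `gene_id` and `distance`; when no gene shares the
#'   chromosome, `gene_id = NA` and `distance = NA` (with a warning).
#' @export
nearest_tss <- function(chrom, summit, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no gene on chromosome ", chrom, "; summit flagged intergenic")
    return(list(gene_id = NA_character_, distance = NA_integer_))
  }
  d <- signed_tss_distance(summit, g$tss, g$strand)
  best <- which(abs(d) == min(abs(d)))
  if (length(best) > 1L) {
    best <- best[order(g$gene_id[best])]
    message("nearest-TSS tie at ", chrom, ":", summit, " resolved to ",
            g$gene_id[best[1L]])
  }
  list(gene_id = g$gene_id[best[1L]], distance = d[best[1L]])
}

#' Classify a summit into a genomic feature class
#'
#' Precedence: (1) promoter if the oriented distance to any TSS lies in
#' `[-promoter_up, +promoter_down]` inclusive; (2) else, if the summit is
#' inside a gene body: CDS when inside an exon and inside the CDS span,
#' UTR when inside an exon but outside the CDS span (all exonic positions
#' of a gene without CDS are UTR), intron otherwise; (3) else distal when
#' within `distal_limit` of any gene-body edge; (4) else intergenic.
#'
#' @inheritParams nearest_tss
#' @param promoter_up,promoter_down Promoter window, nt upstream/downstream
#'   of a TSS (defaults 1000 and 100).
#' @param distal_limit Maximum distance (nt) from a gene-body edge for the
#'   distal class (default 50000).
#' @return One of `"promoter"`, `"UTR"`, `"CDS"`, `"intron"`, `"distal"`,
#'   `"intergenic"`.
#' @export
classify_feature <- function(chrom, summit, genes, promoter_up = 1000L,
                             promoter_down = 100L, distal_limit = 50000L) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return("intergenic")
  d <- signed_tss_distance(summit, g$tss, g$strand)
  if (any(d >= -promoter_up & d <= promoter_down)) return("promoter")
  inside <- which(summit >= g$start & summit < g$end)
  if (length(inside) > 0L) {
    # one gene decides; if several bodies contain the summit (generator
    # forbids it, but real annotations can overlap), exonic evidence wins
    cls <- vapply(inside, function(i) {
      ex <- g$exons[[i]]
      in_exon <- any(summit >= ex[, "start"] & summit < ex[, "end"])
      if (!in_exon) return("intron")
      cs <- g$cds_start[i]
      ce <- g$cds_end[i]
      if (!is.na(cs) && summit >= cs && summit < ce) "CDS" else "UTR"
    }, "")
    for (want in c("CDS", "UTR", "intron")) if (want %in% cls) return(want)
  }
  edge_dist <- pmax(g$start - summit, summit - (g$end - 1L), 0L)
  if (any(edge_dist <= distal_limit)) return("distal")
  "intergenic"
}

#' Annotate a set of peaks
#'
#' Assigns each peak its nearest TSS, signed distance, feature class and
#' (when the summit falls inside a gene body) the hosting gene.
#'
#' @param peaks Peak table from [read_peaks()].
#' @param genes Gene model table from [read_gene_models()].
#' @inheritParams classify_feature
#' @return A list with `peaks` (the input plus columns `nearest_gene`,
#'   `distance_to_tss`, `feature`, `hosting_gene`) and `fractions`
#'   (named numeric over the six classes, summing to 1).
#' @export
annotate_peaks <- function(peaks, genes, promoter_up = 1000L,
                           promoter_down = 100L, distal_limit = 50000L) {
  if (nrow(peaks) == 0L) stop("empty peak list")
  n <- nrow(peaks)
  nearest_gene <- character(n)
  distance <- rep(NA_integer_, n)
  feature <- character(n)
  hosting <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    nt <- suppressWarnings(nearest_tss(peaks$chrom[i], peaks$summit[i], genes))
    nearest_gene[i] <- nt$gene_id
    distance[i] <- nt$distance
    feature[i] <- classify_feature(peaks$chrom[i], peaks$summit[i], genes,
                                   promoter_up, promoter_down, distal_limit)
    g <- genes[genes$chrom == peaks$chrom[i] &
                 genes$start <= peaks$summit[i] &
                 genes$end > peaks$summit[i], , drop = FALSE]
    if (nrow(g) > 0L) hosting[i] <- g$gene_id[1L]
  }
  out <- peaks
  out$nearest_gene <- nearest_gene
  out$distance_to_tss <- distance
  out$feature <- feature
  out$hosting_gene <- hosting
  fr <- table(factor(feature, levels = FEATURE_CLASSES)) / n
  list(peaks = out, fractions = stats::setNames(as.numeric(fr), FEATURE_CLASSES))
}

#' Write an annotated peak table as TSV
#' @param annotated Result of [annotate_peaks()].
#' @param path Output TSV path.
#' @export
write_annotation <- function(annotated, path) {
  df <- annotated$peaks[c("name", "chrom", "summit", "nearest_gene",
                          "distance_to_tss", "feature")]
  names(df)[1L] <- "peak_name"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
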