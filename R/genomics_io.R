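# All coordinates are 0-based half-open internally; GTF (1-based inclusive)
# is converted at the reader boundary. Chromosome names are matched exactly
# (no "chr" aliasing).

#' Read ChIP-seq peak calls
#'
#' Reads ENCODE narrowPeak (10 columns) or BED6 plus a summit-offset column
#' (7 columns) into a peak table. Coordinates are kept 0-based half-open.
#' For narrowPeak, the summit is `start + peak offset` (column 10); an
#' offset of -1 (the ENCODE "no summit" convention) falls back to the
#' interval midpoint `floor((start + end)/2)`.
#'
#' @param path Path to the peak file.
#' @param format `"narrowPeak"` or `"bed6summit"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `summit` (absolute 0-based position), `fold_enrichment`, `qvalue`
#'   (linear FDR scale, in `[0, 1]`), `strand`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6summit")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty peak file: ", path)
    return(empty_peaks())
  }
  ncol_expect <- if (format == "narrowPeak") 10L else 7L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != ncol_expect)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s line %d in %s: expected %d fields, got %d",
                 format, bad[1L], path, ncol_expect, nf[bad[1L]]))
  }
  m <- do.call(rbind, fields)
  start <- as.integer(m[, 2L])
  end <- as.integer(m[, 3L])
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinates in ", path)
  }
  if (format == "narrowPeak") {
    offset <- as.integer(m[, 10L])
    summit <- ifelse(offset >= 0L, start + offset, (start + end) %/% 2L)
    fe <- as.numeric(m[, 7L])
    # narrowPeak column 9 is -log10(qvalue); -1 means unset
    qlog <- as.numeric(m[, 9L])
    qvalue <- ifelse(qlog < 0, NA_real_, 10^(-qlog))
  } else {
    offset <- as.integer(m[, 7L])
    summit <- ifelse(offset >= 0L, start + offset, (start + end) %/% 2L)
    fe <- as.numeric(m[, 5L])
    qvalue <- rep(NA_real_, nrow(m))
  }
  peaks <- data.frame(
    chrom = m[, 1L], start = start, end = end, name = m[, 4L],
    summit = as.integer(summit), fold_enrichment = fe, qvalue = qvalue,
    strand = m[, 6L], stringsAsFactors = FALSE
  )
  validate_peaks(peaks, path)
  peaks
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), summit = integer(),
             fold_enrichment = numeric(), qvalue = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

validate_peaks <- function(peaks, path = "<peaks>") {
  if (any(peaks$start < 0L)) stop("negative start coordinate in ", path)
  if (any(peaks$end <= peaks$start)) stop("empty or inverted interval in ", path)
  out <- peaks$summit < peaks$start | peaks$summit >= peaks$end
  if (any(out)) {
    stop(sprintf("summit outside interval for peak '%s' in %s",
                 peaks$name[which(out)[1L]], path))
  }
  invisible(peaks)
}

#' Write peaks in narrowPeak format
#'
#' Round-trips with [read_peaks()]: coordinates and summits are reproduced
#' exactly.
#'
#' @param peaks Peak table as returned by [read_peaks()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  qlog <- ifelse(is.na(peaks$qvalue), -1, -log10(pmax(peaks$qvalue, 1e-300)))
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   0L, peaks$strand, peaks$fold_enrichment, -1, qlog,
                   peaks$summit - peaks$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Uses `rtracklayer` for parsing, then converts to the package's 0-based
#' half-open convention. The TSS is the body start on the + strand and
#' `body end - 1` on the - strand. Exons are merged per gene; a gene with
#' no exon features gets its body as a single exon (with a warning); genes
#' with unknown strand are skipped (with a warning).
#'
#' @param path Path to a GTF2.2 file with gene/exon/CDS features.
#' @return A `data.frame` with one row per gene: `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open body), `strand`, `tss`,
#'   `cds_start`, `cds_end` (NA when the gene has no CDS), and a
#'   list-column `exons` of two-column integer matrices (`start`, `end`).
#' @export
read_gene_models <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  gid <- as.character(gr$gene_id)
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features in ", path)
  strand_chr <- as.character(GenomicRanges::strand(gr))
  keep_ids <- gid[is_gene & strand_chr %in% c("+", "-")]
  dropped <- gid[is_gene & !(strand_chr %in% c("+", "-"))]
  if (length(dropped) > 0L) {
    warning("skipping gene(s) with unknown strand: ",
            paste(dropped, collapse = ", "))
  }
  res <- lapply(keep_ids, function(g) {
    rows <- which(gid == g)
    grow <- rows[type[rows] == "gene"][1L]
    # GTF is 1-based inclusive; convert to 0-based half-open
    body_start <- GenomicRanges::start(gr)[grow] - 1L
    body_end <- GenomicRanges::end(gr)[grow]
    std <- strand_chr[grow]
    ex_rows <- rows[type[rows] == "exon"]
    if (length(ex_rows) == 0L) {
      warning("gene ", g, " has no exons; using body as a single exon")
      ex <- cbind(start = body_start, end = body_end)
    } else {
      ir <- IRanges::reduce(IRanges::IRanges(
        GenomicRanges::start(gr)[ex_rows] - 1L,
        GenomicRanges::end(gr)[ex_rows] - 1L
      ))
      ex <- cbind(start = IRanges::start(ir), end = IRanges::end(ir) + 1L)
    }
    if (any(ex[, "start"] < body_start) || any(ex[, "end"] > body_end)) {
      stop("exon outside declared gene span for gene ", g)
    }
    cds_rows <- rows[type[rows] == "CDS"]
    if (length(cds_rows) > 0L) {
      cds_start <- min(GenomicRanges::start(gr)[cds_rows]) - 1L
      cds_end <- max(GenomicRanges::end(gr)[cds_rows])
    } else {
      cds_start <- NA_integer_
      cds_end <- NA_integer_
    }
    list(gene_id = g,
         chrom = as.character(GenomicRanges::seqnames(gr))[grow],
         start = body_start, end = body_end, strand = std,
         tss = if (std == "+") body_start else body_end - 1L,
         cds_start = cds_start, cds_end = cds_end, exons = ex)
  })
  genes <- data.frame(
    gene_id = vapply(res, `[[`, "", "gene_id"),
    chrom = vapply(res, `[[`, "", "chrom"),
    start = vapply(res, `[[`, 0L, "start"),
    end = vapply(res, `[[`, 0L, "end"),
    strand = vapply(res, `[[`, "", "strand"),
    tss = vapply(res, `[[`, 0L, "tss"),
    cds_start = vapply(res, `[[`, NA_integer_, "cds_start"),
    cds_end = vapply(res, `[[`, NA_integer_, "cds_end"),
    stringsAsFactors = FALSE
  )
  genes$exons <- I(lapply(res, `[[`, "exons"))
  validate_genes(genes)
  genes
}

validate_genes <- function(genes) {
  stopifnot(all(genes$end > genes$start), all(genes$strand %in% c("+", "-")))
  plus <- genes$strand == "+"
  stopifnot(all(genes$tss[plus] == genes$start[plus]),
            all(genes$tss[!plus] == genes$end[!plus] - 1L))
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    stopifnot(all(ex[, "start"] >= genes$start[i]),
              all(ex[, "end"] <= genes$end[i]))
    if (nrow(ex) > 1L) {
      o <- order(ex[, "start"])
      stopifnot(all(ex[o[-nrow(ex)], "end"] <= ex[o[-1L], "start"]))
    }
  }
  invisible(genes)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file (0-based half-open steps).
#' @param total_reads Library size used for per-million normalization. When
#'   `NULL`, the track's summed signal (value times width) is used.
#' @return A `signal_track` object: a list with `steps` (named list, one
#'   `data.frame(start, end, value)` per chromosome, sorted) and
#'   `total_reads`.
#' @export
read_signal <- function(path, total_reads = NULL) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0) || any(!is.finite(gr$score))) {
    stop("negative or non-finite signal values in ", path)
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = gr$score, stringsAsFactors = FALSE)
  steps <- split(df[c("start", "end", "value")], df$chrom)
  steps <- lapply(steps, function(s) {
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$end[-nrow(s)] > s$start[-1L])) {
      stop("overlapping bedGraph steps in ", path)
    }
    rownames(s) <- NULL
    s
  })
  if (is.null(total_reads)) {
    total_reads <- sum(vapply(steps, function(s)
      sum(s$value * (s$end - s$start)), 0))
  }
  structure(list(steps = steps, total_reads = total_reads),
            class = "signal_track")
}

#' Write a signal track as bedGraph
#' @param track A `signal_track`.
#' @param path Output path.
#' @export
write_signal <- function(track, path) {
  rows <- lapply(names(track$steps), function(ch) {
    s <- track$steps[[ch]]
    data.frame(chrom = ch, s, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-level count table with its design
#'
#' The counts TSV has a header of sample ids and one row per gene
#' (first column = gene id, optional `length` column); the design TSV maps
#' sample id to condition (`EPO+` / `EPO-`) and replicate index.
#'
#' @param path Counts TSV.
#' @param design_path Design TSV with columns `sample`, `condition`,
#'   `replicate`.
#' @param gene_lengths Optional named vector of gene lengths (nt); required
#'   for FPKM unless the counts file carries a `length` column.
#' @return A `count_table`: list with `counts` (integer matrix genes x
#'   samples), `condition` (named character), `replicate` (named integer),
#'   `gene_lengths` (named numeric).
#' @export
read_counts <- function(path, design_path, gene_lengths = NULL) {
  stopifnot(file.exists(path), file.exists(design_path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids in ", path, ": ",
         gene_ids[duplicated(gene_ids)][1L])
  }
  tab <- tab[-1L]
  if ("length" %in% names(tab)) {
    gene_lengths <- stats::setNames(as.numeric(tab[["length"]]), gene_ids)
    tab[["length"]] <- NULL
  }
  counts <- as.matrix(tab)
  if (any(counts < 0)) stop("negative count in ", path)
  if (any(counts != round(counts))) stop("non-integer count in ", path)
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_ids
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition", "replicate") %in% names(design)))
  if (!setequal(design$sample, colnames(counts))) {
    stop("design samples do not match count columns")
  }
  design <- design[match(colnames(counts), design$sample), ]
  if (!is.null(gene_lengths)) {
    stopifnot(all(gene_lengths > 0))
    gene_lengths <- gene_lengths[gene_ids]
  }
  structure(list(counts = counts,
                 condition = stats::setNames(design$condition, design$sample),
                 replicate = stats::setNames(as.integer(design$replicate),
                                             design$sample),
                 gene_lengths = gene_lengths),
            class = "count_table")
}

#' Read FASTA sequences (uppercase-normalized)
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
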