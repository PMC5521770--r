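# Integration of DEG calls with annotated peaks into the three target
# scenarios: direct (responsive gene with a peak within the linkage window
# of its TSS), independent (responsive, no peak in window), and
# bound-unresponsive (peaks whose linked genes all show no change).

#' Link peaks to all TSSs within a window
#'
#' A peak links to every gene whose TSS lies within `window` nt of the
#' summit (inclusive); linkage is deliberately not nearest-gene-exclusive,
#' since a regulated gene need not be the closest gene to the peak.
#'
#' @param peaks Annotated peak table (`annotate_peaks()$peaks`).
#' @param genes Gene model table.
#' @param window Linkage window in nt (default 100000, i.e. 100 kb; the
#'   stricter 50 kb criterion used for pSTAT5-independent claims is
#'   available by setting `window = 50000`).
#' @return `data.frame` with `peak_name`, `gene_id`, `distance` (signed,
#'   gene orientation), `feature` (the peak's feature class).
#' @export
link_peaks_to_tss <- function(peaks, genes, window = 100000L) {
  if (window <= 0) stop("window must be positive")
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    d_abs <- abs(peaks$summit[i] - g$tss)
    keep <- which(d_abs <= window)
    if (length(keep) == 0L) return(NULL)
    data.frame(peak_name = peaks$name[i], gene_id = g$gene_id[keep],
               distance = signed_tss_distance(peaks$summit[i], g$tss[keep],
                                              g$strand[keep]),
               feature = peaks$feature[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peak_name = character(), gene_id = character(),
                      distance = integer(), feature = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Classify genes into target scenarios
#'
#' DEGs (call `induced` or `repressed`) with at least one linked peak are
#' `direct` — `promoter_bound` when some linked peak both carries the
#' promoter feature class and has its oriented TSS distance to *this* gene
#' within the promoter window, else `enhancer_bound`. DEGs with no linked
#' peak are `independent`. Non-DEGs are `background`. Separately, every
#' peak whose linked genes are all non-DEG (including peaks with no links)
#' is flagged `bound_unresponsive`.
#'
#' @param degs DEG table from [call_degs()].
#' @param links Link table from [link_peaks_to_tss()].
#' @param peaks Annotated peak table (for the per-peak flags).
#' @param promoter_up,promoter_down Promoter window used for the
#'   promoter-bound colour class (defaults 1000/100 as in annotation).
#' @return List with `genes` (`gene_id`, `scenario`, `binding_mode`,
#'   `closest_peak`, `peak_distance`) and `peaks` (`name`,
#'   `bound_unresponsive`).
#' @export
classify_target_genes <- function(degs, links, peaks, promoter_up = 1000L,
                                  promoter_down = 100L) {
  unknown <- setdiff(links$gene_id, degs$gene_id)
  if (length(unknown) > 0L) {
    stop("gene id(s) in links absent from DEG table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  is_deg <- stats::setNames(degs$call %in% c("induced", "repressed"),
                            degs$gene_id)
  n <- nrow(degs)
  scenario <- ifelse(is_deg[degs$gene_id], "independent", "background")
  binding_mode <- rep("none", n)
  closest_peak <- rep(NA_character_, n)
  peak_distance <- rep(NA_integer_, n)
  by_gene <- split(links, links$gene_id)
  for (g in names(by_gene)) {
    i <- match(g, degs$gene_id)
    lk <- by_gene[[g]]
    j <- which.min(abs(lk$distance))
    closest_peak[i] <- lk$peak_name[j]
    peak_distance[i] <- lk$distance[j]
    if (is_deg[g]) {
      prom <- lk$feature == "promoter" &
        lk$distance >= -promoter_up & lk$distance <= promoter_down
      scenario[i] <- "direct"
      binding_mode[i] <- if (any(prom)) "promoter_bound" else "enhancer_bound"
    }
  }
  deg_of_peak <- tapply(is_deg[links$gene_id], links$peak_name, any)
  bound_unresponsive <- !peaks$name %in% names(deg_of_peak)[deg_of_peak]
  list(
    genes = data.frame(gene_id = degs$gene_id, scenario = scenario,
                       binding_mode = binding_mode,
                       closest_peak = closest_peak,
                       peak_distance = peak_distance, row.names = NULL,
                       stringsAsFactors = FALSE),
    peaks = data.frame(name = peaks$name,
                       bound_unresponsive = bound_unresponsive,
                       row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Scenario and binding-mode summary
#'
#' @param calls Result of [classify_target_genes()].
#' @return List of counts: `scenario` (direct/independent/background),
#'   `binding_mode`, `bound_unresponsive_peaks`.
#' @export
summary_report <- function(calls) {
  sc <- table(factor(calls$genes$scenario,
                     levels = c("direct", "independent", "background")))
  bm <- table(factor(calls$genes$binding_mode,
                     levels = c("promoter_bound", "enhancer_bound", "none")))
  list(scenario = stats::setNames(as.integer(sc), names(sc)),
       binding_mode = stats::setNames(as.integer(bm), names(bm)),
       bound_unresponsive_peaks = sum(calls$peaks$bound_unresponsive))
}
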