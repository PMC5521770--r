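# End-to-end orchestration: annotate -> motif -> co-occupancy/heatmap ->
# DEG/CAGE -> target classification, with a provenance manifest.

#' Default pipeline configuration
#'
#' Collects every tunable with its default: the promoter window (1 kb
#' upstream / 100 nt downstream of a TSS), the 50 kb distal limit, the
#' 500 bp co-occupancy distance, the 500 bp clustering span and 10 kb
#' display span with 50 bins, the DEG thresholds (fold 1.5, FDR 0.05),
#' the 100 kb peak-gene linkage window, and the CAGE dynamics thresholds
#' (2-fold, 60 min).
#'
#' @param ... Overrides for any default.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    promoter_up = 1000L, promoter_down = 100L, distal_limit = 50000L,
    cooccupancy_max_dist = 500L,
    cluster_half_width = 250L, display_half_width = 5000L, n_bins = 50L,
    linkage = "average",
    min_fold = 1.5, fdr_threshold = 0.05, pseudocount = 1,
    min_mean_count = 10,
    link_window = 100000L,
    response_fold = 2, immediate_cutoff = 60,
    motif_flank = 500L, max_window = 101L
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Run the full target-identification pipeline
#'
#' Stages run in dependency order on file inputs; every stage writes its
#' table under `outdir`, and a manifest records the configuration, input
#' checksums and per-stage record counts. Reruns with identical inputs and
#' configuration are byte-identical except for the manifest timestamp.
#'
#' @param inputs Named list of paths: `peaks` (reference narrowPeak),
#'   `gtf`, `counts`, `design`; optional `factors` (named vector of
#'   narrowPeak paths), `flanks` (summit-centred FASTA), `tracks` (named
#'   vector of bedGraph paths), `cage` (time-series TSV).
#' @param outdir Output directory.
#' @param config From [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(inputs, outdir, config = pipeline_config()) {
  for (nm in c("peaks", "gtf", "counts", "design")) {
    if (is.null(inputs[[nm]])) stop("missing required input: ", nm)
    if (!file.exists(inputs[[nm]])) {
      stop("input file does not exist: ", inputs[[nm]])
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()
  p <- function(f) file.path(outdir, f)

  peaks <- read_peaks(inputs$peaks, "narrowPeak")
  genes <- read_gene_models(inputs$gtf)
  stage_counts$peaks_read <- nrow(peaks)
  stage_counts$genes_read <- nrow(genes)

  ann <- annotate_peaks(peaks, genes, config$promoter_up,
                        config$promoter_down, config$distal_limit)
  write_annotation(ann, p("annotated_peaks.tsv"))
  jsonlite::write_json(as.list(ann$fractions), p("feature_fractions.json"),
                       auto_unbox = TRUE, digits = NA)
  message("annotate: ", nrow(peaks), " peaks, ",
          round(100 * ann$fractions[["promoter"]]), "% promoter")

  motif_res <- NULL
  if (!is.null(inputs$flanks)) {
    flanks <- read_fasta(inputs$flanks)
    motif_res <- lapply(motif_presets()[c("GAS", "GATA", "KLF")],
                        central_enrichment_test, sequences = flanks,
                        max_window = config$max_window)
    jsonlite::write_json(motif_res, p("central_enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    message("motif: GAS adjusted p = ",
            signif(motif_res$GAS$adjusted_p, 3))
  }

  venn <- NULL
  if (!is.null(inputs$factors)) {
    others <- lapply(inputs$factors, read_peaks, format = "narrowPeak")
    venn <- venn_counts(peaks, others, config$cooccupancy_max_dist)
    jsonlite::write_json(venn, p("venn_counts.json"), auto_unbox = TRUE,
                         digits = NA)
    bm <- binding_matrix(peaks, others, config$cooccupancy_max_dist)
    utils::write.table(data.frame(peak = rownames(bm), bm),
                       p("binding_matrix.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage_counts$cooccupied <- as.list(venn$totals)
    message("cooccupy: ", paste(names(venn$totals), venn$totals,
                                sep = "=", collapse = ", "))
  }

  heat <- NULL
  if (!is.null(inputs$tracks)) {
    tracks <- lapply(inputs$tracks, read_signal)
    heat <- heatmap_order(tracks, peaks, config$cluster_half_width,
                          config$display_half_width, config$n_bins,
                          config$linkage)
    writeLines(heat$order, p("heatmap_row_order.txt"))
  }

  ct <- read_counts(inputs$counts, inputs$design)
  degs <- call_degs(ct, config$min_fold, config$fdr_threshold,
                    config$pseudocount, config$min_mean_count)
  utils::write.table(degs, p("degs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stage_counts$degs_called <- sum(degs$call != "unchanged")
  message("deg: ", sum(degs$call == "induced"), " induced, ",
          sum(degs$call == "repressed"), " repressed")

  cage_dyn <- NULL
  if (!is.null(inputs$cage)) {
    cage_dyn <- classify_cage_dynamics(read_cage_series(inputs$cage),
                                       config$response_fold,
                                       config$immediate_cutoff)
    utils::write.table(cage_dyn, p("cage_dynamics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  links <- link_peaks_to_tss(ann$peaks, genes, config$link_window)
  calls <- classify_target_genes(degs, links, ann$peaks,
                                 config$promoter_up, config$promoter_down)
  utils::write.table(calls$genes, p("target_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(calls$peaks, p("peak_flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- summary_report(calls)
  jsonlite::write_json(summ, p("scenario_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  stage_counts$links_made <- nrow(links)
  stage_counts$scenario <- as.list(summ$scenario)
  message("classify: ", paste(names(summ$scenario), summ$scenario,
                              sep = "=", collapse = ", "))

  input_paths <- unlist(inputs, use.names = FALSE)
  manifest <- list(
    config = config,
    inputs = as.list(stats::setNames(unname(tools::md5sum(input_paths)),
                                     input_paths)),
    stage_counts = stage_counts,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(annotation = ann, motifs = motif_res, venn = venn,
                 heatmap = heat, degs = degs, cage = cage_dyn,
                 links = links, calls = calls, summary = summ,
                 manifest = manifest))
}
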