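mk_ann_peaks <- function(summits, features, chrom = "chr1") {
  data.frame(chrom = chrom, start = summits - 100, end = summits + 100,
             name = paste0("p", seq_along(summits)), summit = summits,
             fold_enrichment = 10, qvalue = 1e-4, strand = ".",
             nearest_gene = NA, distance_to_tss = NA, feature = features,
             stringsAsFactors = FALSE)
}

mk_deg_table <- function(ids, calls) {
  data.frame(gene_id = ids, fold_change = ifelse(calls == "induced", 4, 1),
             mean_fpkm = 10, p_value = 0.01, fdr = 0.01, call = calls,
             stringsAsFactors = FALSE)
}

two_gene_models <- function() {
  g <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                  start = c(500000L, 900000L), end = c(510000L, 910000L),
                  strand = "+", tss = c(500000L, 900000L),
                  cds_start = NA_integer_, cds_end = NA_integer_,
                  stringsAsFactors = FALSE)
  g$exons <- I(list(cbind(start = 500000L, end = 510000L),
                    cbind(start = 900000L, end = 910000L)))
  g
}

test_that("peak-TSS linkage has an inclusive 100 kb boundary", {
  g <- two_gene_models()
  pk <- mk_ann_peaks(c(500000 + 99999, 900000 + 100001), c("distal", "distal"))
  links <- link_peaks_to_tss(pk, g, window = 100000)
  expect_equal(links$peak_name, "p1")
  expect_equal(links$gene_id, "gA")
  expect_equal(links$distance, 99999)
  expect_error(link_peaks_to_tss(pk, g, window = 0), "positive")
})

test_that("a peak between two TSSs links to both genes", {
  g <- two_gene_models()
  g$tss[2] <- 600000L
  g$start[2] <- 600000L
  g$end[2] <- 610000L
  g$exons[[2]] <- cbind(start = 600000L, end = 610000L)
  pk <- mk_ann_peaks(550000, "intergenic")
  links <- link_peaks_to_tss(pk, g, window = 100000)
  expect_setequal(links$gene_id, c("gA", "gB"))
})

test_that("the three scenarios are assigned per the DEG/link geometry", {
  g <- two_gene_models()
  # p1 at gA promoter (+31), p2 far from everything but within 100 kb of gB
  pk <- mk_ann_peaks(c(500031, 950000), c("promoter", "distal"))
  links <- link_peaks_to_tss(pk, g, window = 100000)
  degs <- mk_deg_table(c("gA", "gB", "gC"),
                       c("induced", "unchanged", "induced"))
  calls <- classify_target_genes(degs, links, pk)
  gcall <- calls$genes
  expect_equal(gcall$scenario[gcall$gene_id == "gA"], "direct")
  expect_equal(gcall$binding_mode[gcall$gene_id == "gA"], "promoter_bound")
  # induced gene with no linked peak: independent
  expect_equal(gcall$scenario[gcall$gene_id == "gC"], "independent")
  expect_equal(gcall$scenario[gcall$gene_id == "gB"], "background")
  # p2 links only the unresponsive gB: bound_unresponsive
  expect_true(calls$peaks$bound_unresponsive[calls$peaks$name == "p2"])
  expect_false(calls$peaks$bound_unresponsive[calls$peaks$name == "p1"])
})

test_that("an enhancer-linked DEG is enhancer_bound, not promoter_bound", {
  g <- two_gene_models()
  pk <- mk_ann_peaks(530000, "distal")
  links <- link_peaks_to_tss(pk, g, window = 100000)
  degs <- mk_deg_table("gA", "induced")
  calls <- classify_target_genes(degs, links, pk[, ])
  expect_equal(calls$genes$binding_mode, "enhancer_bound")
})

test_that("unknown gene ids in the link table are reported", {
  g <- two_gene_models()
  pk <- mk_ann_peaks(500031, "promoter")
  links <- link_peaks_to_tss(pk, g, window = 100000)
  degs <- mk_deg_table("gZ", "induced")
  expect_error(classify_target_genes(degs, links, pk), "gA")
})

test_that("scenario labels partition the DEG set", {
  cfg <- small_sim_config(seed = 16)
  sim <- simulate_study(cfg, withr::local_tempdir())
  genes <- sim$genome$genes
  ann <- annotate_peaks(sim$peaks$reference, genes)
  links <- link_peaks_to_tss(ann$peaks, genes)
  degs <- call_degs(sim$expr$counts)
  calls <- classify_target_genes(degs, links, ann$peaks)
  n_deg <- sum(degs$call != "unchanged")
  sc <- summary_report(calls)$scenario
  expect_equal(unname(sc["direct"] + sc["independent"]), n_deg)
  expect_equal(sum(sc), nrow(degs))
})

test_that("enlarging the window never moves a gene from direct to independent", {
  cfg <- small_sim_config(seed = 17)
  sim <- simulate_study(cfg, withr::local_tempdir())
  genes <- sim$genome$genes
  ann <- annotate_peaks(sim$peaks$reference, genes)
  degs <- call_degs(sim$expr$counts)
  prev_direct <- character(0)
  for (w in c(2e4, 5e4, 1e5, 2e5)) {
    links <- link_peaks_to_tss(ann$peaks, genes, window = w)
    calls <- classify_target_genes(degs, links, ann$peaks)
    direct <- calls$genes$gene_id[calls$genes$scenario == "direct"]
    expect_true(all(prev_direct %in% direct))
    prev_direct <- direct
  }
})

test_that("classification agrees with a brute-force all-pairs distance check", {
  cfg <- small_sim_config(seed = 18)
  sim <- simulate_study(cfg, withr::local_tempdir())
  genes <- sim$genome$genes
  ann <- annotate_peaks(sim$peaks$reference, genes)
  links <- link_peaks_to_tss(ann$peaks, genes, window = 1e5)
  degs <- call_degs(sim$expr$counts)
  calls <- classify_target_genes(degs, links, ann$peaks)
  is_deg <- stats::setNames(degs$call != "unchanged", degs$gene_id)
  for (i in seq_len(nrow(degs))) {
    gid <- degs$gene_id[i]
    gi <- genes[genes$gene_id == gid, ]
    near <- any(ann$peaks$chrom == gi$chrom &
                  abs(ann$peaks$summit - gi$tss) <= 1e5)
    want <- if (!is_deg[gid]) "background"
            else if (near) "direct" else "independent"
    expect_equal(calls$genes$scenario[calls$genes$gene_id == gid], want)
  }
})
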