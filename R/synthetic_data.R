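# Seeded synthetic-data generator. Emits a toy genome, pSTAT5/KLF1/GATA1
# peak sets, signal tracks, a replicated nascent-RNA count table and a CAGE
# time course, all with a planted-truth record, so that every stage of the
# pipeline can be tested by recovery.
#
# The default configuration mirrors the study's scale: 302 reference peaks
# (23% at promoters), 67 KLF1- and 147 GATA1-co-occupied sites, 63 induced
# and 24 repressed genes with fold changes in the printed 1.5-8.4 range,
# and a 0-24 h CAGE grid. Geometry is laid out in isolated blocks so that
# planted feature classes, co-occupancy counts and target scenarios are
# unambiguous by construction.

#' Simulation configuration
#'
#' @param seed Base RNG seed; every generator is a pure function of the
#'   configuration including this seed.
#' @param n_chroms,chrom_length Number and length (nt) of chromosomes.
#' @param n_peaks Number of reference (pSTAT5) peaks.
#' @param feature_fractions Planted feature-class mix over the six classes.
#' @param cooccupancy_counts Named integer: co-occupied reference peaks per
#'   partner factor.
#' @param central_motif_rate Fraction of reference peaks with a GAS 9-mer
#'   planted at the summit.
#' @param n_induced,n_repressed Planted DEG counts.
#' @param direct_induced,direct_repressed How many planted DEGs get a peak
#'   within the linkage window (scenario "direct"); the rest are
#'   "independent".
#' @param n_null_extra Additional unbound, unresponsive genes.
#' @param fold_range Range of planted fold changes (log-uniform draw).
#' @param dispersion Negative-binomial dispersion of the count noise.
#' @param n_reps Replicates per condition.
#' @param baseline_range,deg_baseline_range Baseline mean-count ranges
#'   (log-uniform) for null and planted-DEG genes.
#' @param cage_n_per_class Named integer vector of CAGE regions per
#'   dynamics class (immediate/delayed/unresponsive). The default keeps
#'   responders a minority, as in a genome-wide promoter panel, which the
#'   RLE median-of-ratios reference relies on.
#' @param cage_times Time grid in minutes.
#' @param cage_noise_sd Lognormal noise sigma on CAGE counts.
#' @param cage_amplitude_range Planted peak fold range for responsive
#'   regions.
#' @param signal_heights Per-base peak heights for the two planted signal
#'   row-clusters (tall, short).
#' @param flank Summit flank (nt) for motif sequences (sequences have
#'   length `2 * flank + 1`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L, chrom_length = 3.5e6,
                       n_peaks = 302L,
                       feature_fractions = c(promoter = 0.23, intron = 0.35,
                                             distal = 0.20, intergenic = 0.12,
                                             CDS = 0.05, UTR = 0.05),
                       cooccupancy_counts = c(KLF1 = 67L, GATA1 = 147L),
                       central_motif_rate = 0.9,
                       n_induced = 63L, n_repressed = 24L,
                       direct_induced = 25L, direct_repressed = 8L,
                       n_null_extra = 21L,
                       fold_range = c(1.5, 8.4),
                       dispersion = 0.02, n_reps = 2L,
                       baseline_range = c(20, 2000),
                       deg_baseline_range = c(500, 5000),
                       cage_n_per_class = c(immediate = 40L, delayed = 40L,
                                            unresponsive = 160L),
                       cage_times = c(0, 30, 60, 120, 240, 480, 1440),
                       cage_noise_sd = 0.1,
                       cage_amplitude_range = c(3, 8),
                       signal_heights = c(40, 8),
                       flank = 500L) {
  stopifnot(abs(sum(feature_fractions) - 1) < 1e-9,
            all(feature_fractions >= 0),
            all(cooccupancy_counts <= n_peaks),
            central_motif_rate >= 0, central_motif_rate <= 1,
            direct_induced <= n_induced, direct_repressed <= n_repressed,
            all(fold_range > 0), dispersion >= 0, n_reps >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

# largest-remainder apportionment of n into named fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

UNIT_MARGIN <- 3000L
UNIT_W <- 22000L
UNIT_W_DISTAL <- 70000L
BLOCK_BUFFER <- 110000L
INTERGENIC_MARGIN <- 55000L
INTERGENIC_SPACING <- 5000L

# Lays out gene/peak "units" in scenario blocks separated by buffers wider
# than the 100 kb linkage window. Returns the per-gene and per-peak plan.
plan_layout <- function(config) {
  cc <- apportion(config$n_peaks, config$feature_fractions)
  n_direct <- config$direct_induced + config$direct_repressed
  n_dp <- if (n_direct == 0L) 0L
          else min(cc[["promoter"]], max(1L, round(0.35 * n_direct)))
  n_di <- n_direct - n_dp
  if (cc[["intron"]] < n_di) stop("demanded feature-class counts infeasible")
  hosted <- c(promoter = cc[["promoter"]] - n_dp,
              intron = cc[["intron"]] - n_di,
              distal = cc[["distal"]], CDS = cc[["CDS"]], UTR = cc[["UTR"]])
  direct_classes <- c(rep("promoter", n_dp), rep("intron", n_di))
  bound_classes <- rep(names(hosted), hosted)
  n_indep <- (config$n_induced - config$direct_induced) +
    (config$n_repressed - config$direct_repressed)

  units <- list()
  add_unit <- function(block, width, gene_role = NA, peak_class = NA) {
    units[[length(units) + 1L]] <<- list(block = block, width = width,
                                         gene_role = gene_role,
                                         peak_class = peak_class)
  }
  deg_dirs <- c(rep("induced", config$direct_induced),
                rep("repressed", config$direct_repressed))
  for (k in seq_len(n_direct)) {
    add_unit("direct", UNIT_W, deg_dirs[k], direct_classes[k])
  }
  for (cl in bound_classes) {
    add_unit("bound", if (cl == "distal") UNIT_W_DISTAL else UNIT_W,
             "null", cl)
  }
  indep_dirs <- c(rep("induced", config$n_induced - config$direct_induced),
                  rep("repressed", config$n_repressed - config$direct_repressed),
                  rep("null", config$n_null_extra))
  for (r in indep_dirs) add_unit("independent", UNIT_W, r, NA)

  n_intergenic <- cc[["intergenic"]]
  intergenic_width <- 2L * INTERGENIC_MARGIN +
    max(0L, n_intergenic - 1L) * INTERGENIC_SPACING

  # greedy packing into chromosomes; buffer between blocks on a chromosome
  chroms <- paste0("chr", seq_len(config$n_chroms))
  cur_chrom <- 1L
  cursor <- 0
  prev_block <- NA
  place <- function(width, block) {
    if (!is.na(prev_block) && block != prev_block) cursor <<- cursor + BLOCK_BUFFER
    if (cursor + width > config$chrom_length) {
      cur_chrom <<- cur_chrom + 1L
      cursor <<- 0
      if (cur_chrom > config$n_chroms) {
        stop("infeasible packing: increase n_chroms or chrom_length")
      }
    }
    u0 <- cursor
    cursor <<- cursor + width
    prev_block <<- block
    list(chrom = chroms[cur_chrom], start = u0)
  }
  for (k in seq_along(units)) {
    pos <- place(units[[k]]$width, units[[k]]$block)
    units[[k]]$chrom <- pos$chrom
    units[[k]]$start <- pos$start
  }
  ig <- if (n_intergenic > 0L) place(intergenic_width, "intergenic") else NULL
  list(units = units, class_counts = cc, n_intergenic = n_intergenic,
       intergenic = ig, n_indep = n_indep)
}

random_dna <- function(n) {
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)],
        collapse = "")
}

#' Generate the synthetic genome (gene models + sequence)
#'
#' Genes are placed in scenario blocks (see the package vignette); bodies
#' are pairwise disjoint, strands alternate, each gene has 4 exons and a
#' CDS span leaving UTR room in the terminal exons. The sequence is
#' i.i.d. uniform A/C/G/T.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (gene-model table as from
#'   [read_gene_models()]), `seqs` (named chromosome sequences), and
#'   `layout` (internal placement plan consumed by the other generators).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed + 1L)
  layout <- plan_layout(config)
  units <- layout$units
  gene_units <- which(!vapply(units, function(u) is.na(u$gene_role), TRUE))
  res <- vector("list", length(gene_units))
  for (k in seq_along(gene_units)) {
    u <- units[[gene_units[k]]]
    L <- sample(8000:16000, 1L)
    b0 <- as.integer(u$start + UNIT_MARGIN)
    b1 <- b0 + L
    strand <- if (k %% 2L == 0L) "+" else "-"
    e <- rbind(c(b0, b0 + 400L),
               c(b0 + round(0.4 * L), b0 + round(0.4 * L) + 400L),
               c(b0 + round(0.7 * L), b0 + round(0.7 * L) + 400L),
               c(b1 - 400L, b1))
    colnames(e) <- c("start", "end")
    res[[k]] <- list(chrom = u$chrom, start = b0, end = b1, strand = strand,
                     tss = if (strand == "+") b0 else b1 - 1L,
                     cds_start = b0 + 200L, cds_end = b1 - 200L, exons = e,
                     block = u$block, role = u$gene_role,
                     unit = gene_units[k])
  }
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_along(res)),
    chrom = vapply(res, `[[`, "", "chrom"),
    start = vapply(res, `[[`, 0L, "start"),
    end = vapply(res, `[[`, 0L, "end"),
    strand = vapply(res, `[[`, "", "strand"),
    tss = vapply(res, `[[`, 0L, "tss"),
    cds_start = vapply(res, `[[`, 0L, "cds_start"),
    cds_end = vapply(res, `[[`, 0L, "cds_end"),
    stringsAsFactors = FALSE
  )
  genes$exons <- I(lapply(res, `[[`, "exons"))
  genes$block <- vapply(res, `[[`, "", "block")
  genes$role <- vapply(res, `[[`, "", "role")
  for (k in seq_along(res)) units[[res[[k]]$unit]]$gene_id <- genes$gene_id[k]
  layout$units <- units
  if (nrow(genes) > 0L) validate_genes(genes)
  seqs <- stats::setNames(
    vapply(seq_len(config$n_chroms), function(i)
      random_dna(config$chrom_length), ""),
    paste0("chr", seq_len(config$n_chroms)))
  list(genes = genes, seqs = seqs, layout = layout)
}

# one realization of the GAS consensus TTCYMRGAA
sample_gas_site <- function() {
  paste0("TTC", sample(c("C", "T"), 1L), sample(c("A", "C"), 1L),
         sample(c("A", "G"), 1L), "GAA")
}

place_summit <- function(u, gene) {
  L <- gene$end - gene$start
  switch(u$peak_class,
    promoter = {
      d <- sample(-900:0, 1L)  # oriented distance in the promoter window
      if (gene$strand == "+") gene$tss + d else gene$tss - d
    },
    intron = gene$start + round(0.4 * L) + 400L + sample(200:800, 1L),
    CDS = gene$start + round(0.4 * L) + sample(50:350, 1L),
    UTR = if (gene$strand == "+") gene$end - sample(50:150, 1L)
          else gene$start + sample(50:150, 1L),
    distal = gene$end + sample(10000:40000, 1L)
  )
}

#' Generate peak sets with planted classes, co-occupancy and motifs
#'
#' Reference (pSTAT5) peaks are placed to hit the planted feature classes;
#' KLF1/GATA1 partner summits sit at uniform offsets within 500 nt of a
#' sampled subset of reference summits while decoys sit 2000-2500 nt away;
#' a GAS 9-mer is written into the genome sequence at `central_motif_rate`
#' of the summits.
#'
#' @param config A [sim_config()].
#' @param genome Result of [generate_genome()].
#' @return List with `reference` and `factors` (peak tables), `flanks`
#'   (summit-centred sequences, length `2 * flank + 1`), `seqs` (genome
#'   sequences after motif planting), and `truth` (per-peak planted class,
#'   partner flags, motif flag, scenario role).
#' @export
generate_peak_sets <- function(config, genome) {
  set.seed(config$seed + 2L)
  layout <- genome$layout
  units <- layout$units
  genes <- genome$genes
  specs <- list()
  for (u in units) {
    if (is.na(u$peak_class)) next
    gene <- genes[genes$gene_id == u$gene_id, ]
    summit <- as.integer(place_summit(u, gene))
    specs[[length(specs) + 1L]] <- list(chrom = u$chrom, summit = summit,
                                        class = u$peak_class,
                                        block = u$block,
                                        host_gene = u$gene_id)
  }
  if (layout$n_intergenic > 0L) {
    for (k in seq_len(layout$n_intergenic)) {
      specs[[length(specs) + 1L]] <- list(
        chrom = layout$intergenic$chrom,
        summit = as.integer(layout$intergenic$start + INTERGENIC_MARGIN +
                              (k - 1L) * INTERGENIC_SPACING),
        class = "intergenic", block = "intergenic", host_gene = NA_character_)
    }
  }
  o <- order(vapply(specs, `[[`, "", "chrom"),
             vapply(specs, `[[`, 0L, "summit"))
  specs <- specs[o]
  n <- length(specs)
  stopifnot(n == config$n_peaks)
  reference <- data.frame(
    chrom = vapply(specs, `[[`, "", "chrom"),
    start = vapply(specs, `[[`, 0L, "summit") - 250L,
    end = vapply(specs, `[[`, 0L, "summit") + 250L,
    name = sprintf("pSTAT5_%03d", seq_len(n)),
    summit = vapply(specs, `[[`, 0L, "summit"),
    fold_enrichment = round(exp(stats::runif(n, log(5), log(40))), 1),
    qvalue = 10^-stats::runif(n, 2, 10),
    strand = ".", stringsAsFactors = FALSE
  )
  truth <- data.frame(
    name = reference$name,
    class = vapply(specs, `[[`, "", "class"),
    block = vapply(specs, `[[`, "", "block"),
    host_gene = vapply(specs, `[[`, NA_character_, "host_gene"),
    stringsAsFactors = FALSE
  )
  # plant GAS sites at summits
  with_motif <- sort(sample.int(n, round(config$central_motif_rate * n)))
  seqs <- genome$seqs
  for (i in with_motif) {
    s <- reference$summit[i]
    substr(seqs[[reference$chrom[i]]], s - 3L, s + 5L) <- sample_gas_site()
  }
  truth$motif_planted <- seq_len(n) %in% with_motif
  # partner factors
  factors <- list()
  for (f in names(config$cooccupancy_counts)) {
    partners <- sort(sample.int(n, config$cooccupancy_counts[[f]]))
    truth[[paste0("partner_", f)]] <- seq_len(n) %in% partners
    offs <- integer(n)
    offs[partners] <- sample(0:500, length(partners), replace = TRUE)
    decoys <- setdiff(seq_len(n), partners)
    offs[decoys] <- sample(2000:2500, length(decoys), replace = TRUE)
    fs <- reference$summit + offs
    factors[[f]] <- data.frame(
      chrom = reference$chrom, start = fs - 250L, end = fs + 250L,
      name = sprintf("%s_%03d", f, seq_len(n)), summit = fs,
      fold_enrichment = round(exp(stats::runif(n, log(5), log(30))), 1),
      qvalue = 10^-stats::runif(n, 2, 10), strand = ".",
      stringsAsFactors = FALSE
    )
  }
  flank <- config$flank
  flanks <- vapply(seq_len(n), function(i) {
    substr(seqs[[reference$chrom[i]]],
           reference$summit[i] - flank + 1L, reference$summit[i] + flank + 1L)
  }, "")
  names(flanks) <- reference$name
  list(reference = reference, factors = factors, flanks = flanks,
       seqs = seqs, truth = truth)
}

#' Generate triangular signal tracks over peak summits
#'
#' Each factor gets a bedGraph-style step track with a triangular peak of
#' half-width 200 nt at every summit of its peak set, approximated in
#' 20 nt steps, on a flat (default zero) noise floor. Reference peaks in
#' the first planted row-cluster are tall, the rest short, so heatmap
#' clustering has recoverable structure.
#'
#' @param config A [sim_config()].
#' @param peak_sets Result of [generate_peak_sets()].
#' @return Named list of `signal_track` objects (reference factor first);
#'   the reference track carries the planted cluster labels as attribute
#'   `"cluster"`.
#' @export
generate_signal_tracks <- function(config, peak_sets) {
  set.seed(config$seed + 3L)
  half <- 200L
  step <- 20L
  tri_steps <- function(summit, height) {
    starts <- seq(summit - half, summit + half - step, by = step)
    mids <- starts + step / 2
    data.frame(start = starts, end = starts + step,
               value = height * pmax(0, 1 - abs(mids - summit) / half))
  }
  n <- nrow(peak_sets$reference)
  cluster <- rep(c(1L, 2L), c(ceiling(n / 2), floor(n / 2)))
  heights <- config$signal_heights[cluster]
  build_track <- function(peaks, hts) {
    df <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
      cbind(chrom = peaks$chrom[i], tri_steps(peaks$summit[i], hts[i]))
    }))
    steps <- split(df[c("start", "end", "value")], df$chrom)
    steps <- lapply(steps, function(s) {
      s <- s[order(s$start), , drop = FALSE]
      rownames(s) <- NULL
      s
    })
    structure(list(steps = steps, total_reads = 1e6), class = "signal_track")
  }
  tracks <- c(
    list(pSTAT5 = build_track(peak_sets$reference, heights)),
    lapply(peak_sets$factors, function(p)
      build_track(p, rep(20, nrow(p))))
  )
  attr(tracks$pSTAT5, "cluster") <- cluster
  tracks
}

#' Generate the replicated EPO+/EPO- count table
#'
#' Baseline means are log-uniform; planted DEGs multiply (induced) or
#' divide (repressed) the EPO+ mean by a fold change drawn log-uniformly
#' from `fold_range`; counts are negative-binomial with the configured
#' dispersion (Poisson at dispersion 0).
#'
#' @param config A [sim_config()].
#' @param genes Gene table from [generate_genome()] (needs `gene_id`,
#'   `role`, `exons`).
#' @return List with `counts` (a `count_table`) and `truth` (per gene:
#'   `true_fold` as the planted EPO+/EPO- ratio, `direction`, `scenario`).
#' @export
generate_count_table <- function(config, genes) {
  set.seed(config$seed + 4L)
  n <- nrow(genes)
  role <- genes$role
  is_deg <- role %in% c("induced", "repressed")
  base <- exp(stats::runif(n, log(config$baseline_range[1]),
                           log(config$baseline_range[2])))
  base[is_deg] <- exp(stats::runif(sum(is_deg),
                                   log(config$deg_baseline_range[1]),
                                   log(config$deg_baseline_range[2])))
  fold <- rep(1, n)
  draw <- exp(stats::runif(sum(is_deg), log(config$fold_range[1]),
                           log(config$fold_range[2])))
  fold[is_deg] <- ifelse(role[is_deg] == "induced", draw, 1 / draw)
  mu_minus <- base
  mu_plus <- base * fold
  samples <- c(paste0("EPOplus_rep", seq_len(config$n_reps)),
               paste0("EPOminus_rep", seq_len(config$n_reps)))
  cond <- rep(c("EPO+", "EPO-"), each = config$n_reps)
  draw_counts <- function(mu) {
    if (config$dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  counts <- vapply(seq_along(samples), function(j) {
    mu <- if (cond[j] == "EPO+") mu_plus else mu_minus
    draw_counts(mu)
  }, numeric(n))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes$gene_id, samples)
  lengths <- vapply(genes$exons, function(e)
    sum(e[, "end"] - e[, "start"]), 0)
  ct <- structure(list(
    counts = counts,
    condition = stats::setNames(cond, samples),
    replicate = stats::setNames(rep(seq_len(config$n_reps), 2L), samples),
    gene_lengths = stats::setNames(lengths, genes$gene_id)
  ), class = "count_table")
  scenario <- ifelse(!is_deg, "background",
                     ifelse(genes$block == "direct", "direct", "independent"))
  truth <- data.frame(gene_id = genes$gene_id, true_fold = fold,
                      direction = role, scenario = scenario,
                      stringsAsFactors = FALSE)
  list(counts = ct, truth = truth)
}

#' Generate the CAGE time-course matrix
#'
#' Immediate regions peak at 30-60 min, delayed regions at 2-4 h,
#' unresponsive regions stay flat; counts get multiplicative lognormal
#' noise.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (regions x time matrix, column names =
#'   minutes) and `truth` (`region_id`, `class`).
#' @export
generate_cage_series <- function(config) {
  set.seed(config$seed + 5L)
  times <- config$cage_times
  npc <- config$cage_n_per_class
  if (is.null(names(npc))) {
    npc <- stats::setNames(rep_len(npc, 3L),
                           c("immediate", "delayed", "unresponsive"))
  }
  classes <- rep(c("immediate", "delayed", "unresponsive"),
                 npc[c("immediate", "delayed", "unresponsive")])
  profile <- function(cls, A) {
    peak_at <- function(tp) {
      prof <- 1 + (A - 1) * pmax(0, 1 - abs(log2(pmax(times, 15) / tp)) / 1.5)
      prof[1L] <- 1
      prof
    }
    switch(cls,
      immediate = peak_at(sample(c(30, 60), 1L)),
      delayed = peak_at(sample(c(120, 240), 1L)),
      unresponsive = rep(1, length(times)))
  }
  n <- length(classes)
  base <- exp(stats::runif(n, log(50), log(500)))
  counts <- t(vapply(seq_len(n), function(i) {
    A <- exp(stats::runif(1, log(config$cage_amplitude_range[1]),
                          log(config$cage_amplitude_range[2])))
    mu <- base[i] * profile(classes[i], A)
    pmax(0, round(mu * exp(stats::rnorm(length(times), 0,
                                        config$cage_noise_sd))))
  }, numeric(length(times))))
  dimnames(counts) <- list(sprintf("region%03d", seq_len(n)), times)
  list(counts = counts,
       truth = data.frame(region_id = rownames(counts), class = classes,
                          stringsAsFactors = FALSE))
}

#' Write a gene-model table as GTF
#' @param genes Gene table (`gene_id`, coordinates, `exons`, `cds_*`).
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    attr_s <- sprintf('gene_id "%s";', genes$gene_id[i])
    add <- function(type, s0, s1) {
      sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
              genes$chrom[i], type, s0 + 1L, s1, genes$strand[i], attr_s)
    }
    lines <- c(lines, add("gene", genes$start[i], genes$end[i]))
    ex <- genes$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, add("exon", ex[j, "start"], ex[j, "end"]))
    }
    if (!is.na(genes$cds_start[i])) {
      lines <- c(lines, add("CDS", genes$cds_start[i], genes$cds_end[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the whole generator and write every artifact
#'
#' Emits `genome.fa`, `genes.gtf`, `<factor>.narrowPeak`, `<factor>.bedGraph`,
#' `peaks_flank.fa`, `counts.tsv`, `design.tsv`, `cage.tsv` and
#' `truth.json` under `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory objects and `paths`.
#' @export
simulate_study <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  peaks <- generate_peak_sets(config, genome)
  tracks <- generate_signal_tracks(config, peaks)
  expr <- generate_count_table(config, genome$genes)
  cage <- generate_cage_series(config)
  p <- function(f) file.path(outdir, f)
  write_fasta(peaks$seqs, p("genome.fa"))
  write_gtf(genome$genes, p("genes.gtf"))
  write_peaks(peaks$reference, p("pSTAT5.narrowPeak"))
  for (f in names(peaks$factors)) {
    write_peaks(peaks$factors[[f]], p(paste0(f, ".narrowPeak")))
  }
  for (f in names(tracks)) write_signal(tracks[[f]], p(paste0(f, ".bedGraph")))
  write_fasta(peaks$flanks, p("peaks_flank.fa"))
  cnt <- data.frame(gene_id = rownames(expr$counts$counts),
                    expr$counts$counts,
                    length = expr$counts$gene_lengths, check.names = FALSE)
  utils::write.table(cnt, p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  des <- data.frame(sample = names(expr$counts$condition),
                    condition = unname(expr$counts$condition),
                    replicate = unname(expr$counts$replicate))
  utils::write.table(des, p("design.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cg <- data.frame(region_id = rownames(cage$counts), cage$counts,
                   check.names = FALSE)
  utils::write.table(cg, p("cage.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(peaks = peaks$truth, genes = expr$truth, cage = cage$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns")
  invisible(list(config = config, genome = genome, peaks = peaks,
                 tracks = tracks, expr = expr, cage = cage, truth = truth,
                 paths = stats::setNames(
                   file.path(outdir, c("genome.fa", "genes.gtf",
                                       "pSTAT5.narrowPeak", "counts.tsv",
                                       "design.tsv", "cage.tsv",
                                       "peaks_flank.fa", "truth.json")),
                   c("genome", "gtf", "peaks", "counts", "design", "cage",
                     "flanks", "truth"))))
}
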