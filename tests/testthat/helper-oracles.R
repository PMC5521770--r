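# Brute-force reference implementations, kept deliberately independent of
# the package internals: plain loops and closed forms only.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 M = "K", K = "M", S = "S", W = "W", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

oracle_revcomp <- function(pattern) {
  paste(rev(unname(ORACLE_COMP[strsplit(pattern, "")[[1]]])), collapse = "")
}

oracle_symbol_matches <- function(psym, base) {
  if (base == "N") return(psym == "N")
  base %in% ORACLE_IUPAC[[psym]]
}

# all (start, strand) pairs where the pattern matches, 0-based
oracle_iupac_match <- function(pattern, seq) {
  bases <- strsplit(seq, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else oracle_revcomp(pattern)
    psym <- strsplit(pat, "")[[1]]
    w <- length(psym)
    if (length(bases) < w) next
    for (s in 0:(length(bases) - w)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!oracle_symbol_matches(psym[j], bases[s + j])) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1]] <- c(start = s, strand = strand)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), strand = character()))
  }
  df <- data.frame(start = as.integer(vapply(out, `[[`, "", "start")),
                   strand = vapply(out, `[[`, "", "strand"))
  df[order(df$start, df$strand), ]
}

oracle_pwm_score <- function(pwm, window) {
  total <- 0
  for (j in seq_along(window)) {
    if (!window[j] %in% c("A", "C", "G", "T")) return(-Inf)
    total <- total + log2(pwm$probs[window[j], j] / pwm$background[[window[j]]])
  }
  total
}

oracle_scan_pwm <- function(pwm, seq, threshold) {
  bases <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  w <- pwm$width
  out <- list()
  for (s in 0:(length(bases) - w)) {
    win <- bases[(s + 1):(s + w)]
    fs <- oracle_pwm_score(pwm, win)
    if (fs >= threshold) out[[length(out) + 1]] <- list(s, "+", fs)
    rs <- oracle_pwm_score(pwm, rev(unname(comp[win])))
    if (rs >= threshold) out[[length(out) + 1]] <- list(s, "-", rs)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  }
  df <- data.frame(start = as.integer(sapply(out, `[[`, 1)),
                   strand = sapply(out, `[[`, 2),
                   score = sapply(out, `[[`, 3))
  df[order(df$start, df$strand), ]
}

# position-by-position feature classifier following the stated rules
oracle_classify <- function(chrom, summit, genes, promoter_up = 1000,
                            promoter_down = 100, distal_limit = 50000) {
  on_chr <- which(genes$chrom == chrom)
  if (length(on_chr) == 0) return("intergenic")
  for (i in on_chr) {
    d <- if (genes$strand[i] == "+") summit - genes$tss[i]
         else genes$tss[i] - summit
    if (d >= -promoter_up && d <= promoter_down) return("promoter")
  }
  hits <- character(0)
  for (i in on_chr) {
    if (summit >= genes$start[i] && summit < genes$end[i]) {
      ex <- genes$exons[[i]]
      in_exon <- FALSE
      for (j in seq_len(nrow(ex))) {
        if (summit >= ex[j, "start"] && summit < ex[j, "end"]) in_exon <- TRUE
      }
      if (!in_exon) hits <- c(hits, "intron")
      else if (!is.na(genes$cds_start[i]) && summit >= genes$cds_start[i] &&
               summit < genes$cds_end[i]) hits <- c(hits, "CDS")
      else hits <- c(hits, "UTR")
    }
  }
  for (want in c("CDS", "UTR", "intron")) if (want %in% hits) return(want)
  for (i in on_chr) {
    gap <- max(genes$start[i] - summit, summit - (genes$end[i] - 1), 0)
    if (gap <= distal_limit) return("distal")
  }
  "intergenic"
}

# naive O(n^3) agglomerative clustering recomputing inter-cluster
# distances from scratch each step; ward uses the centroid closed form
oracle_agglomerative <- function(x, linkage) {
  n <- nrow(x)
  d0 <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  cdist <- function(a, b) {
    if (linkage == "ward") {
      ca <- colMeans(x[a, , drop = FALSE])
      cb <- colMeans(x[b, , drop = FALSE])
      2 * length(a) * length(b) / (length(a) + length(b)) *
        sum((ca - cb)^2)
    } else {
      vals <- d0[a, b, drop = FALSE]
      switch(linkage, single = min(vals), complete = max(vals),
             average = mean(vals))
    }
  }
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- cdist(clusters[[i]], clusters[[j]])
        if (dd < bd) { bd <- dd; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merges[step, ] <- sort(c(ids[i], ids[j]))
    heights[step] <- if (linkage == "ward") sqrt(bd) else bd
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merges, height = heights)
}

# canonical dendrogram representation: sorted leaf sets with heights
tree_clusters <- function(merge, height) {
  members <- list()
  out <- list()
  for (k in seq_len(nrow(merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- sort(c(get(merge[k, 1]), get(merge[k, 2])))
    out[[k]] <- list(members = members[[k]], height = height[k])
  }
  out[order(vapply(out, `[[`, 0, "height"),
            vapply(out, function(o) paste(o$members, collapse = ","), ""))]
}

expect_same_tree <- function(a, b, tol = 1e-8) {
  ca <- tree_clusters(a$merge, a$height)
  cb <- tree_clusters(b$merge, b$height)
  expect_equal(length(ca), length(cb))
  for (k in seq_along(ca)) {
    expect_identical(ca[[k]]$members, cb[[k]]$members)
    expect_equal(ca[[k]]$height, cb[[k]]$height, tolerance = tol)
  }
}

# small random gene-model table with disjoint bodies on one chromosome
random_genes <- function(n, chrom = "chr1", chrom_length = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slot <- floor(chrom_length / n)
  rows <- lapply(seq_len(n), function(i) {
    b0 <- (i - 1) * slot + sample(500:2000, 1)
    L <- sample(2000:(slot - 3000), 1)
    b1 <- b0 + L
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(2:4, 1)
    cuts <- sort(sample(seq(b0 + 200, b1 - 200, by = 50), 2 * (n_ex - 1)))
    starts <- c(b0, cuts[seq(2, length(cuts), by = 2)])
    ends <- c(cuts[seq(1, length(cuts), by = 2)], b1)
    has_cds <- stats::runif(1) < 0.8
    list(gene_id = sprintf("g%02d", i), chrom = chrom, start = b0, end = b1,
         strand = strand, tss = if (strand == "+") b0 else b1 - 1,
         cds_start = if (has_cds) b0 + 150 else NA_integer_,
         cds_end = if (has_cds) b1 - 150 else NA_integer_,
         exons = cbind(start = starts, end = ends))
  })
  genes <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), 0L),
    end = vapply(rows, function(r) as.integer(r$end), 0L),
    strand = vapply(rows, `[[`, "", "strand"),
    tss = vapply(rows, function(r) as.integer(r$tss), 0L),
    cds_start = vapply(rows, function(r) as.integer(r$cds_start), 0L),
    cds_end = vapply(rows, function(r) as.integer(r$cds_end), 0L),
    stringsAsFactors = FALSE
  )
  genes$exons <- I(lapply(rows, `[[`, "exons"))
  genes
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_pwm <- function(width) {
  probs <- vapply(seq_len(width), function(j) {
    p <- stats::rgamma(4, 1) + 0.05
    p / sum(p)
  }, numeric(4))
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(probs = probs,
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 width = width), class = "pwm")
}

small_sim_config <- function(seed = 5, ...) {
  args <- list(seed = seed, n_chroms = 2, chrom_length = 1.5e6, n_peaks = 24,
               cooccupancy_counts = c(KLF1 = 6, GATA1 = 12),
               n_induced = 8, n_repressed = 3, direct_induced = 4,
               direct_repressed = 1, n_null_extra = 4,
               cage_n_per_class = c(immediate = 8, delayed = 8,
                                    unresponsive = 34))
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}
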