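# Nascent-RNA (4sU) differential expression between EPO-stimulated and
# unstimulated conditions, replicate QC, and CAGE time-course dynamics.

#' FPKM from a count table
#'
#' `FPKM = count * 1e9 / (gene_length * library_size)` with library size =
#' column sum.
#'
#' @param ct A `count_table` ([read_counts()]) with gene lengths.
#' @return Numeric matrix of FPKM, genes x samples.
#' @export
fpkm <- function(ct) {
  stopifnot(inherits(ct, "count_table"), !is.null(ct$gene_lengths))
  lib <- colSums(ct$counts)
  if (any(lib == 0)) stop("zero library size")
  sweep(ct$counts * 1e9 / ct$gene_lengths, 2L, lib, "/")
}

# two-sided exact binomial p-values, minimum-likelihood definition
# (identical to stats::binom.test), vectorized over observations
binom_p2 <- function(x, n, p0) {
  out <- numeric(length(x))
  dx <- stats::dbinom(x, n, p0) * (1 + 1e-7)
  mode <- floor((n + 1) * p0)
  lower_side <- x < mode
  # x below the mode: p = P(X <= x) plus the upper tail of outcomes no more
  # likely than x; dbinom is unimodal, so the flank boundary is found by
  # bisection. Mirrored for x at or above the mode.
  if (any(lower_side)) {
    i <- which(lower_side)
    ni <- n[i]; pi0 <- p0[i]; di <- dx[i]
    lo <- mode[i]; hi <- ni
    while (any(lo < hi)) {  # smallest k on [mode, n] with dbinom(k) <= dx
      mid <- (lo + hi) %/% 2
      ok <- stats::dbinom(mid, ni, pi0) <= di
      hi <- ifelse(ok, mid, hi)
      lo <- ifelse(ok, lo, mid + 1)
    }
    add <- ifelse(stats::dbinom(lo, ni, pi0) <= di,
                  stats::pbinom(lo - 1, ni, pi0, lower.tail = FALSE), 0)
    out[i] <- pmin(1, stats::pbinom(x[i], ni, pi0) + add)
  }
  if (any(!lower_side)) {
    i <- which(!lower_side)
    ni <- n[i]; pi0 <- p0[i]; di <- dx[i]
    lo <- rep(0, length(i)); hi <- mode[i]
    while (any(lo < hi)) {  # largest k on [0, mode] with dbinom(k) <= dx
      mid <- (lo + hi + 1) %/% 2
      ok <- stats::dbinom(mid, ni, pi0) <= di
      lo <- ifelse(ok, mid, lo)
      hi <- ifelse(ok, hi, mid - 1)
    }
    add <- ifelse(stats::dbinom(lo, ni, pi0) <= di,
                  stats::pbinom(lo, ni, pi0), 0)
    out[i] <- pmin(1, stats::pbinom(x[i] - 1, ni, pi0, lower.tail = FALSE) + add)
  }
  out
}

#' Call differentially expressed genes between EPO+ and EPO- conditions
#'
#' Library scale factors are median-of-ratios against the per-gene
#' geometric-mean reference (robust to composition bias from strongly
#' induced genes), normalized to geometric mean 1; the fold change is the
#' ratio of pseudocounted normalized condition means. The p-value is a
#' two-sided exact conditional binomial test of the pooled raw EPO+ count
#' against the pooled total, with null proportion equal to the EPO+ share
#' of effective depth; Benjamini-Hochberg FDR follows. A gene is
#' `induced` when `fdr < fdr_threshold` and `fold_change >= min_fold`,
#' `repressed` when `fold_change <= 1/min_fold`, else `unchanged`. Genes
#' below `min_mean_count` (mean raw count across samples) are not tested.
#'
#' @param ct A `count_table` with conditions `EPO+` and `EPO-`.
#' @param min_fold Fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param pseudocount Added to normalized condition means (default 1).
#' @param min_mean_count Expression filter (default 10).
#' @return `data.frame` with `gene_id`, `fold_change`, `mean_fpkm` (NA
#'   without gene lengths), `p_value`, `fdr`, `call`.
#' @export
call_degs <- function(ct, min_fold = 1.5, fdr_threshold = 0.05,
                      pseudocount = 1, min_mean_count = 10) {
  stopifnot(inherits(ct, "count_table"))
  cond <- ct$condition
  plus <- names(cond)[cond == "EPO+"]
  minus <- names(cond)[cond == "EPO-"]
  stopifnot(length(plus) >= 1L, length(minus) >= 1L)
  lib <- colSums(ct$counts)
  if (any(lib == 0)) stop("zero library size")
  # median-of-ratios to the per-gene geometric-mean reference; robust to
  # composition bias from strongly induced genes. Falls back to
  # total-count scaling when no gene is positive everywhere.
  pos <- rowSums(ct$counts == 0) == 0L
  if (any(pos)) {
    geo <- exp(rowMeans(log(ct$counts[pos, , drop = FALSE])))
    sf <- apply(ct$counts[pos, , drop = FALSE] / geo, 2L, stats::median)
  } else {
    sf <- lib
  }
  sf <- sf / exp(mean(log(sf)))
  norm <- sweep(ct$counts, 2L, sf, "/")
  mean_plus <- rowMeans(norm[, plus, drop = FALSE])
  mean_minus <- rowMeans(norm[, minus, drop = FALSE])
  fc <- (mean_plus + pseudocount) / (mean_minus + pseudocount)
  x <- as.numeric(rowSums(ct$counts[, plus, drop = FALSE]))
  tot <- x + as.numeric(rowSums(ct$counts[, minus, drop = FALSE]))
  p0 <- sum(sf[plus]) / sum(sf)  # effective depth share under the null
  tested <- rowMeans(ct$counts) >= min_mean_count & tot > 0
  p <- rep(1, nrow(ct$counts))
  if (any(tested)) {
    p[tested] <- binom_p2(x[tested], tot[tested], rep(p0, sum(tested)))
  }
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  call <- rep("unchanged", length(p))
  sig <- tested & !is.na(fdr) & fdr < fdr_threshold
  call[sig & fc >= min_fold] <- "induced"
  call[sig & fc <= 1 / min_fold] <- "repressed"
  mean_fpkm <- if (is.null(ct$gene_lengths)) NA_real_ else {
    fp <- fpkm(ct)
    (rowMeans(fp[, plus, drop = FALSE]) + rowMeans(fp[, minus, drop = FALSE])) / 2
  }
  data.frame(gene_id = rownames(ct$counts), fold_change = fc,
             mean_fpkm = mean_fpkm, p_value = p, fdr = fdr, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Between-replicate rank correlation per condition
#'
#' Spearman correlation of log-scale FPKM over genes expressed (FPKM > 0)
#' in at least one replicate of the pair; with more than two replicates,
#' all pairwise correlations are averaged.
#'
#' @param ct A `count_table` with gene lengths.
#' @return Named numeric, one correlation per condition.
#' @export
replicate_correlation <- function(ct) {
  fp <- fpkm(ct)
  cond <- ct$condition
  vapply(unique(cond), function(cc) {
    cols <- names(cond)[cond == cc]
    if (length(cols) < 2L) stop("need >= 2 replicates for condition ", cc)
    prs <- utils::combn(cols, 2L)
    mean(apply(prs, 2L, function(pr) {
      a <- fp[, pr[1L]]
      b <- fp[, pr[2L]]
      keep <- a > 0 | b > 0
      stats::cor(log2(a[keep] + 1), log2(b[keep] + 1), method = "spearman")
    }))
  }, 0)
}

#' Relative-log-expression normalization of a CAGE tag matrix
#'
#' Median-of-ratios scaling: each library's scale factor is the median,
#' over regions with no zero count in any library, of the ratio of its
#' count to the per-region geometric mean across libraries. When every
#' region contains a zero, upper-quartile scaling is used instead (with a
#' warning). The RLE value is `log2(count / scale + 1)`.
#'
#' @param counts Numeric matrix, regions x libraries (e.g. time points).
#' @return List with `scale_factors`, `normalized` (linear scale), `rle`
#'   (log2 scale).
#' @export
rle_normalize <- function(counts) {
  stopifnot(ncol(counts) >= 2L)
  nz <- rowSums(counts == 0) == 0L
  if (any(nz)) {
    geo <- exp(rowMeans(log(counts[nz, , drop = FALSE])))
    sf <- apply(counts[nz, , drop = FALSE] / geo, 2L, stats::median)
  } else {
    warning("all regions contain a zero; falling back to upper-quartile scaling")
    uq <- apply(counts, 2L, stats::quantile, probs = 0.75)
    sf <- uq / exp(mean(log(uq)))
  }
  normalized <- sweep(counts, 2L, sf, "/")
  list(scale_factors = sf, normalized = normalized,
       rle = log2(normalized + 1))
}

#' Classify the temporal dynamics of one CAGE region
#'
#' On the normalized linear scale, the fold over t = 0 is
#' `(x_t + 1)/(x_0 + 1)`. Regions whose maximum fold stays below
#' `response_fold` are `unresponsive`; responsive regions are `immediate`
#' when the argmax time is `<= immediate_cutoff` minutes, else `delayed`.
#'
#' @param values Normalized counts over time for one region.
#' @param times Time points in minutes, strictly increasing, first = 0.
#' @param response_fold Response threshold (default 2).
#' @param immediate_cutoff Minutes separating immediate from delayed
#'   induction (default 60).
#' @return List with `class`, `peak_time`, `max_fold_over_t0`.
#' @export
classify_dynamics <- function(values, times, response_fold = 2,
                              immediate_cutoff = 60) {
  if (length(values) < 2L) stop("single time point")
  stopifnot(length(values) == length(times), times[1L] == 0,
            all(diff(times) > 0))
  fold <- (values + 1) / (values[1L] + 1)
  k <- which.max(fold)
  mx <- fold[k]
  cls <- if (mx < response_fold) "unresponsive"
         else if (times[k] <= immediate_cutoff) "immediate" else "delayed"
  list(class = cls, peak_time = times[k], max_fold_over_t0 = unname(mx))
}

#' Read a CAGE tag-count time series
#'
#' TSV with a `region_id` column and one column per time point (minutes).
#'
#' @param path Input TSV.
#' @return Numeric matrix, regions x time points; column names are the
#'   time points in minutes.
#' @export
read_cage_series <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[-1L])
  rownames(m) <- tab[[1L]]
  times <- suppressWarnings(as.numeric(colnames(m)))
  if (anyNA(times) || is.unsorted(times, strictly = TRUE)) {
    stop("CAGE columns must be strictly increasing time points in minutes")
  }
  m
}

#' Classify dynamics for every region of a CAGE matrix
#'
#' Runs [rle_normalize()] then [classify_dynamics()] per region.
#'
#' @param counts Regions x time-point count matrix; column names are the
#'   time points in minutes.
#' @inheritParams classify_dynamics
#' @return `data.frame` with `region_id`, `class`, `peak_time`,
#'   `max_fold_over_t0`.
#' @export
classify_cage_dynamics <- function(counts, response_fold = 2,
                                   immediate_cutoff = 60) {
  times <- as.numeric(colnames(counts))
  stopifnot(!anyNA(times))
  norm <- rle_normalize(counts)$normalized
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- classify_dynamics(norm[i, ], times, response_fold, immediate_cutoff)
    data.frame(region_id = rownames(counts)[i], class = r$class,
               peak_time = r$peak_time, max_fold_over_t0 = r$max_fold_over_t0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
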