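# Summit-distance co-occupancy, binned signal matrices, and the
# nearest-neighbour-chain hierarchical clustering behind the signal heatmap.

#' Match peak summits between two factors
#'
#' A reference peak is co-occupied when some peak of the other set on the
#' same chromosome has its summit within `max_dist` nt (inclusive). Each
#' reference peak pairs with its nearest qualifying partner summit.
#'
#' @param set_a,set_b Peak tables ([read_peaks()]).
#' @param max_dist Maximum summit distance in nt (default 500, inclusive).
#' @return `data.frame` with `peak_a`, `peak_b`, `summit_distance`.
#' @export
match_summits <- function(set_a, set_b, max_dist = 500L) {
  if (max_dist < 0) stop("negative max_dist")
  stopifnot(nrow(set_a) > 0L, nrow(set_b) > 0L)
  rows <- lapply(seq_len(nrow(set_a)), function(i) {
    b <- set_b[set_b$chrom == set_a$chrom[i], , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    d <- abs(b$summit - set_a$summit[i])
    j <- which.min(d)
    if (d[j] > max_dist) return(NULL)
    data.frame(peak_a = set_a$name[i], peak_b = b$name[j],
               summit_distance = d[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peak_a = character(), peak_b = character(),
                      summit_distance = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Binding matrix of reference peaks against factor sets
#'
#' @param reference Reference peak table.
#' @param others Named list of peak tables.
#' @inheritParams match_summits
#' @return Logical matrix, rows = reference peak names, columns = factors.
#' @export
binding_matrix <- function(reference, others, max_dist = 500L) {
  stopifnot(nrow(reference) > 0L)
  if (anyDuplicated(names(others))) stop("duplicate dataset names")
  m <- vapply(others, function(b) {
    pairs <- match_summits(reference, b, max_dist)
    reference$name %in% pairs$peak_a
  }, logical(nrow(reference)))
  m <- matrix(m, nrow = nrow(reference),
              dimnames = list(reference$name, names(others)))
  m
}

#' Venn-region counts of co-occupancy over the reference set
#'
#' Partitions the reference peaks by their combination of co-occupying
#' factors (e.g. `KLF1`, `GATA1`, `KLF1+GATA1`, `none`), plus marginal
#' per-factor totals.
#'
#' @inheritParams binding_matrix
#' @return List with `regions` (named counts partitioning the reference
#'   set) and `totals` (per-factor co-occupied counts).
#' @export
venn_counts <- function(reference, others, max_dist = 500L) {
  bm <- binding_matrix(reference, others, max_dist)
  combo <- apply(bm, 1L, function(r) {
    on <- colnames(bm)[r]
    if (length(on) == 0L) "none" else paste(on, collapse = "+")
  })
  lv <- c(unlist(lapply(seq_along(others), function(k) {
    apply(utils::combn(names(others), k), 2L, paste, collapse = "+")
  })), "none")
  regions <- table(factor(combo, levels = unique(lv)))
  list(regions = stats::setNames(as.integer(regions), names(regions)),
       totals = colSums(bm))
}

track_value_steps <- function(track, chrom) {
  s <- track$steps[[chrom]]
  if (is.null(s)) data.frame(start = integer(), end = integer(),
                             value = numeric()) else s
}

# mean per-base value of a step track over [from, to)
mean_step_value <- function(steps, from, to) {
  if (to <= from) return(0)
  keep <- steps$end > from & steps$start < to
  if (!any(keep)) return(0)
  s <- steps[keep, , drop = FALSE]
  cov <- pmin(s$end, to) - pmax(s$start, from)
  sum(cov * s$value) / (to - from)
}

#' Binned, normalized signal matrix around peak summits
#'
#' For each reference summit, the window `summit +/- half_width` is split
#' into `n_bins` equal bins; each bin gets the mean per-base signal scaled
#' to reads-per-million (`1e6 / total_reads`). Optionally values are
#' `log2(x + 1)`-transformed and divided by the track's maximum over the
#' matrix ("max signal in the clustered area").
#'
#' @param track A `signal_track`.
#' @param summits Reference peak table.
#' @param half_width Half window width, nt; `2 * half_width` must be
#'   divisible by `n_bins`.
#' @param n_bins Number of bins (default 50).
#' @param log_transform,max_normalize Post-processing switches.
#' @return Numeric matrix, rows = peak names, columns = bins. Windows
#'   truncated at a chromosome start are flagged via the
#'   `"truncated"` attribute.
#' @export
quantify_signal_matrix <- function(track, summits, half_width, n_bins = 50L,
                                   log_transform = TRUE, max_normalize = TRUE) {
  stopifnot((2L * half_width) %% n_bins == 0L)
  scale <- 1e6 / track$total_reads
  edges <- seq(-half_width, half_width, length.out = n_bins + 1L)
  truncated <- character(0)
  m <- t(vapply(seq_len(nrow(summits)), function(i) {
    steps <- track_value_steps(track, summits$chrom[i])
    from <- summits$summit[i] + edges[-length(edges)]
    to <- summits$summit[i] + edges[-1L]
    if (from[1L] < 0) truncated <<- c(truncated, summits$name[i])
    vapply(seq_len(n_bins), function(b)
      mean_step_value(steps, max(0, from[b]), max(0, to[b])), 0) * scale
  }, numeric(n_bins)))
  rownames(m) <- summits$name
  if (log_transform) m <- log2(m + 1)
  if (max_normalize && max(m) > 0) m <- m / max(m)
  attr(m, "truncated") <- truncated
  m
}

# Lance-Williams coefficients; ward operates on squared Euclidean
# distances with heights reported on the original (ward.D2) scale.
lw_update <- function(linkage, d_ik, d_jk, d_ij, ni, nj, nk) {
  switch(linkage,
    single = pmin(d_ik, d_jk),
    complete = pmax(d_ik, d_jk),
    average = (ni * d_ik + nj * d_jk) / (ni + nj),
    ward = ((ni + nk) * d_ik + (nj + nk) * d_jk - nk * d_ij) / (ni + nj + nk)
  )
}

prepare_dist <- function(x, linkage) {
  d <- as.matrix(stats::dist(x))
  if (linkage == "ward") d <- d^2
  d
}

report_height <- function(h, linkage) {
  if (linkage == "ward") sqrt(h) else h
}

#' Nearest-neighbour-chain agglomerative clustering
#'
#' Hierarchical clustering of matrix rows (Euclidean distance) by the
#' nearest-neighbour chain algorithm, which finds mutually nearest pairs
#' by following chains of nearest neighbours and merges them. For the
#' reducible linkages supported here the resulting merge tree (merges and
#' heights) is identical to naive agglomerative clustering; Ward heights
#' follow the `ward.D2` convention. Centroid/median linkage is refused:
#' it is not reducible, so chain merges would not reproduce the
#' agglomerative dendrogram.
#'
#' @param x Numeric matrix (rows = observations).
#' @param linkage One of `"average"`, `"complete"`, `"single"`, `"ward"`.
#' @return List with `merge` (two-column matrix in `stats::hclust`
#'   convention: negatives index leaves), `height`, `order` (leaf order by
#'   recursive traversal, tighter cluster first), `labels`.
#' @export
nn_chain_cluster <- function(x, linkage = c("average", "complete", "single",
                                            "ward")) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  linkage <- match.arg(linkage, several.ok = FALSE)
  if (linkage %in% c("centroid", "median")) {
    stop("centroid/median linkage is not reducible; the NN-chain ",
         "algorithm does not reproduce its dendrogram")
  }
  n <- nrow(x)
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1L) {
    return(list(merge = matrix(integer(), 0L, 2L), height = numeric(0),
                order = 1L, labels = labels))
  }
  d <- prepare_dist(x, linkage)
  diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)          # hclust convention: leaves negative
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  chain <- integer(0)
  for (step in seq_len(n - 1L)) {
    if (length(chain) == 0L) chain <- which(active)[1L]
    repeat {
      i <- chain[length(chain)]
      cand <- which(active)
      cand <- cand[cand != i]
      nn <- cand[which.min(d[i, cand])]
      # prefer the chain predecessor on ties so mutual pairs terminate
      if (length(chain) > 1L) {
        prev <- chain[length(chain) - 1L]
        if (d[i, nn] == d[i, prev]) nn <- prev
      }
      if (length(chain) > 1L && nn == chain[length(chain) - 1L]) break
      chain <- c(chain, nn)
    }
    j <- chain[length(chain)]
    i <- chain[length(chain) - 1L]
    chain <- chain[seq_len(length(chain) - 2L)]
    a <- min(i, j); b <- max(i, j)
    h <- d[a, b]
    merge[step, ] <- sort_merge_pair(node[a], node[b])
    height[step] <- report_height(h, linkage)
    others <- which(active)
    others <- others[!(others %in% c(a, b))]
    if (length(others) > 0L) {
      newd <- lw_update(linkage, d[a, others], d[b, others], h,
                        size[a], size[b], size[others])
      d[a, others] <- newd
      d[others, a] <- newd
    }
    size[a] <- size[a] + size[b]
    node[a] <- step
    active[b] <- FALSE
    d[b, ] <- Inf
    d[, b] <- Inf
  }
  # NN-chain emits merges in chain order; re-sort by height for the
  # canonical dendrogram (stable on ties)
  res <- canonicalize_tree(merge, height)
  res$order <- tree_leaf_order(res$merge, res$height)
  res$labels <- labels
  res
}

sort_merge_pair <- function(u, v) {
  # negatives (leaves) first, then by value — matches hclust's convention
  if (u < 0 && v < 0) c(min(u, v), max(u, v))
  else if (u < 0) c(u, v)
  else if (v < 0) c(v, u)
  else c(min(u, v), max(u, v))
}

canonicalize_tree <- function(merge, height) {
  o <- order(height)
  remap <- integer(length(height))
  remap[o] <- seq_along(o)
  new_merge <- merge[o, , drop = FALSE]
  pos <- new_merge > 0
  new_merge[pos] <- remap[new_merge[pos]]
  for (r in seq_len(nrow(new_merge))) {
    new_merge[r, ] <- sort_merge_pair(new_merge[r, 1L], new_merge[r, 2L])
  }
  list(merge = new_merge, height = height[o])
}

# leaf order by recursive traversal, tighter (lower) cluster first
tree_leaf_order <- function(merge, height) {
  n <- nrow(merge) + 1L
  if (n == 1L) return(1L)
  node_height <- function(k) if (k < 0) -1 else height[k]
  leaves <- function(k) {
    if (k < 0) return(-k)
    a <- merge[k, 1L]; b <- merge[k, 2L]
    ha <- node_height(a); hb <- node_height(b)
    if (hb < ha || (hb == ha && first_leaf(b) < first_leaf(a))) {
      tmp <- a; a <- b; b <- tmp
    }
    c(leaves(a), leaves(b))
  }
  first_leaf <- function(k) if (k < 0) -k else first_leaf(merge[k, 1L])
  leaves(nrow(merge))
}

#' Cluster peaks on a narrow window, order matrices for display
#'
#' Clustering is computed on the concatenation of all tracks' bins within
#' `cluster_half_width` of the summit; display matrices are re-quantified
#' at `display_half_width` and returned in the clustered row order.
#'
#' @param tracks Named list of `signal_track`s (non-empty).
#' @param summits Reference peak table.
#' @param cluster_half_width Half-width (nt) of the clustering window
#'   (default 250, i.e. a 500 bp span).
#' @param display_half_width Half-width of the display window (default
#'   5000, i.e. 10 kb).
#' @param n_bins Bins per window (default 50).
#' @param linkage Linkage for [nn_chain_cluster()].
#' @return List with `order` (peak names, display order), `tree`, and
#'   `display` (named list of matrices in display order).
#' @export
heatmap_order <- function(tracks, summits, cluster_half_width = 250L,
                          display_half_width = 5000L, n_bins = 50L,
                          linkage = "average") {
  if (length(tracks) == 0L || is.null(names(tracks))) {
    stop("tracks must be a non-empty named list")
  }
  cl_mats <- lapply(tracks, quantify_signal_matrix, summits = summits,
                    half_width = cluster_half_width, n_bins = n_bins)
  rows <- lapply(cl_mats, rownames)
  if (length(unique(rows)) != 1L) stop("mismatched row sets across tracks")
  cl <- do.call(cbind, cl_mats)
  tree <- nn_chain_cluster(cl, linkage = linkage)
  ord <- tree$order
  display <- lapply(tracks, function(tr) {
    m <- quantify_signal_matrix(tr, summits, half_width = display_half_width,
                                n_bins = n_bins)
    m[ord, , drop = FALSE]
  })
  list(order = summits$name[ord], tree = tree, display = display)
}
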