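mk_peaks <- function(summits, chrom = "chr1", prefix = "p") {
  data.frame(chrom = chrom, start = summits - 100, end = summits + 100,
             name = paste0(prefix, seq_along(summits)), summit = summits,
             fold_enrichment = 10, qvalue = 1e-4, strand = ".",
             stringsAsFactors = FALSE)
}

test_that("summit matching uses an inclusive distance boundary", {
  a <- mk_peaks(10000)
  expect_equal(nrow(match_summits(a, mk_peaks(10000, prefix = "b"))), 1L)
  expect_equal(nrow(match_summits(a, mk_peaks(10500, prefix = "b"))), 1L)
  expect_equal(nrow(match_summits(a, mk_peaks(10501, prefix = "b"))), 0L)
  expect_error(match_summits(a, a, max_dist = -1), "negative")
})

test_that("each reference peak pairs with its nearest qualifying summit", {
  a <- mk_peaks(10000)
  b <- mk_peaks(c(10400, 10100), prefix = "b")
  pr <- match_summits(a, b)
  expect_equal(pr$peak_b, "b2")
  expect_equal(pr$summit_distance, 100)
})

test_that("co-occupied counts are symmetric for unique non-degenerate pairings", {
  set.seed(21)
  a <- mk_peaks(sort(sample(seq(1e4, 1e6, by = 5000), 40)))
  b <- mk_peaks(a$summit[1:25] + sample(-400:400, 25, replace = TRUE),
                prefix = "b")
  expect_equal(nrow(match_summits(a, b)), nrow(match_summits(b, a)))
})

test_that("co-occupancy counts are monotone in max_dist", {
  set.seed(22)
  a <- mk_peaks(sort(sample(seq(1e4, 1e6, by = 2000), 50)))
  b <- mk_peaks(a$summit + sample(0:1500, 50, replace = TRUE), prefix = "b")
  prev <- -1
  for (d in c(0, 100, 300, 500, 1000, 2000)) {
    n <- nrow(match_summits(a, b, max_dist = d))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("venn counts partition the reference set", {
  a <- mk_peaks(seq(1e4, 5e4, by = 1e4))
  v <- venn_counts(a, list(self = a))
  expect_equal(unname(v$totals["self"]), nrow(a))
  v2 <- venn_counts(a, list(other = mk_peaks(seq(1e4, 5e4, by = 1e4),
                                             chrom = "chr9", prefix = "o")))
  expect_equal(unname(v2$totals["other"]), 0L)
  expect_equal(sum(v2$regions), nrow(a))
  expect_error(venn_counts(a, list(x = a, x = a)), "duplicate")
})

test_that("binned quantification reproduces constant and zero tracks", {
  tr <- structure(list(
    steps = list(chr1 = data.frame(start = 0L, end = 100000L, value = 3)),
    total_reads = 1e6), class = "signal_track")
  pk <- mk_peaks(50000)
  m <- quantify_signal_matrix(tr, pk, half_width = 500, n_bins = 50,
                              log_transform = FALSE, max_normalize = FALSE)
  expect_equal(unname(m[1, ]), rep(3, 50))
  m2 <- quantify_signal_matrix(tr, pk, half_width = 500, n_bins = 50,
                               log_transform = FALSE, max_normalize = TRUE)
  expect_equal(unname(m2[1, ]), rep(1, 50))
  tr0 <- structure(list(steps = list(), total_reads = 1e6),
                   class = "signal_track")
  expect_equal(unname(quantify_signal_matrix(tr0, pk, 500)[1, ]), rep(0, 50))
})

test_that("bin means of a triangular peak equal the analytic trapezoid average", {
  # per-base triangle of height 10 and half-width 100 centred at the summit
  h <- 10; hw <- 100; summit <- 5000
  pos <- (summit - hw):(summit + hw - 1)
  val <- h * pmax(0, 1 - abs(pos + 0.5 - summit) / hw)
  tr <- structure(list(
    steps = list(chr1 = data.frame(start = pos, end = pos + 1L, value = val)),
    total_reads = 1e6), class = "signal_track")
  pk <- mk_peaks(summit)
  m <- quantify_signal_matrix(tr, pk, half_width = 100, n_bins = 20,
                              log_transform = FALSE, max_normalize = FALSE)
  bins <- seq(-hw, hw, length.out = 21)
  analytic <- vapply(1:20, function(b) {
    xs <- seq(bins[b], bins[b + 1] - 1)
    mean(h * pmax(0, 1 - abs(xs + 0.5) / hw))
  }, 0)
  expect_equal(unname(m[1, ]), analytic, tolerance = 1e-10)
})

test_that("reads-per-million scaling is invariant to joint track scaling", {
  tr <- structure(list(
    steps = list(chr1 = data.frame(start = 0L, end = 10000L, value = 2)),
    total_reads = 5e5), class = "signal_track")
  tr2 <- tr
  tr2$steps$chr1$value <- tr$steps$chr1$value * 7
  tr2$total_reads <- tr$total_reads * 7
  pk <- mk_peaks(5000)
  expect_equal(quantify_signal_matrix(tr, pk, 500),
               quantify_signal_matrix(tr2, pk, 500))
})

test_that("degenerate clustering inputs behave: single row, duplicate rows", {
  one <- nn_chain_cluster(matrix(1:5, nrow = 1))
  expect_equal(one$order, 1L)
  expect_equal(nrow(one$merge), 0L)

  set.seed(23)
  x <- matrix(rnorm(50), nrow = 5)
  x[4, ] <- x[2, ]
  res <- nn_chain_cluster(x, "average")
  expect_equal(res$height[1], 0)
  expect_identical(sort(res$merge[1, ]), c(-4L, -2L))
})

test_that("non-reducible linkages are refused", {
  expect_error(nn_chain_cluster(matrix(rnorm(20), 4), "centroid"))
})

test_that("NN-chain equals the naive agglomerative oracle on random matrices", {
  set.seed(24)
  for (i in 1:6) {
    x <- matrix(rnorm(10 * 6), nrow = 10)
    for (lk in c("average", "complete", "single", "ward")) {
      expect_same_tree(nn_chain_cluster(x, lk), oracle_agglomerative(x, lk))
    }
  }
})

test_that("NN-chain heights match stats::hclust for all four linkages", {
  set.seed(25)
  x <- matrix(rnorm(12 * 8), nrow = 12)
  for (lk in c("average", "complete", "single", "ward")) {
    hc <- stats::hclust(stats::dist(x),
                        method = if (lk == "ward") "ward.D2" else lk)
    res <- nn_chain_cluster(x, lk)
    expect_equal(sort(res$height), sort(hc$height), tolerance = 1e-9)
  }
})

test_that("heatmap ordering groups planted tall and short row blocks", {
  cfg <- small_sim_config()
  sim <- generate_peak_sets(cfg, generate_genome(cfg))
  tracks <- generate_signal_tracks(cfg, sim)
  ho <- heatmap_order(tracks["pSTAT5"], sim$reference,
                      cluster_half_width = 250, display_half_width = 1000)
  cl <- attr(tracks$pSTAT5, "cluster")[match(ho$order, sim$reference$name)]
  expect_equal(length(rle(cl)$lengths), 2L)  # contiguous blocks
  expect_error(heatmap_order(list(), sim$reference), "non-empty")
})

test_that("display at the clustering span reproduces the clustering matrix", {
  cfg <- small_sim_config()
  sim <- generate_peak_sets(cfg, generate_genome(cfg))
  tracks <- generate_signal_tracks(cfg, sim)
  ho <- heatmap_order(tracks["pSTAT5"], sim$reference,
                      cluster_half_width = 250, display_half_width = 250)
  m <- quantify_signal_matrix(tracks$pSTAT5, sim$reference, 250)
  expect_equal(ho$display$pSTAT5, m[match(ho$order, rownames(m)), ])
})
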