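mk_ct <- function(counts, cond = c("EPO+", "EPO+", "EPO-", "EPO-"),
                  lengths = NULL) {
  samples <- paste0("s", seq_len(ncol(counts)))
  dimnames(counts) <- list(rownames(counts) %||%
                             sprintf("g%03d", seq_len(nrow(counts))), samples)
  storage.mode(counts) <- "integer"
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  structure(list(counts = counts, condition = stats::setNames(cond, samples),
                 replicate = stats::setNames(rep(1:2, 2), samples),
                 gene_lengths = stats::setNames(lengths, rownames(counts))),
            class = "count_table")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("FPKM follows the count/length/depth formula and is scale invariant", {
  ct <- mk_ct(matrix(c(10, rep(0, 3), rep(999990, 4)), nrow = 2,
                     byrow = TRUE))
  f <- fpkm(ct)
  expect_equal(f["g001", "s1"], 10 * 1e9 / (1000 * 1e6))
  expect_equal(f["g001", "s2"], 0)
  ct2 <- ct
  ct2$counts <- ct$counts * 2L
  expect_equal(fpkm(ct2), fpkm(ct))
})

test_that("the vectorized exact binomial matches stats::binom.test", {
  set.seed(41)
  n <- sample(5:4000, 200, replace = TRUE)
  x <- vapply(n, function(k) sample(0:k, 1), 0L)
  p0 <- stats::runif(200, 0.2, 0.8)
  got <- epotargets:::binom_p2(x, n, p0)
  want <- vapply(seq_along(n), function(i)
    stats::binom.test(x[i], n[i], p0[i])$p.value, 0)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("identical conditions give fold change 1 and no calls", {
  m <- matrix(rep(c(100L, 500L, 50L), each = 4), nrow = 3, byrow = TRUE)
  degs <- call_degs(mk_ct(m))
  expect_equal(degs$fold_change, rep(1, 3))
  expect_equal(degs$call, rep("unchanged", 3))
})

test_that("an all-zero gene is unchanged with p = 1", {
  m <- rbind(rep(0L, 4), rep(1000L, 4))
  degs <- call_degs(mk_ct(m), min_mean_count = 0)
  expect_equal(degs$p_value[1], 1)
  expect_equal(degs$call[1], "unchanged")
})

test_that("a planted 8-fold induced gene is recovered with fold in [6, 10]", {
  set.seed(42)
  n_genes <- 200
  mu <- exp(stats::runif(n_genes, log(200), log(2000)))
  mu[1] <- 1000
  m <- cbind(stats::rnbinom(n_genes, mu = mu * c(8, rep(1, n_genes - 1)),
                            size = 50),
             stats::rnbinom(n_genes, mu = mu * c(8, rep(1, n_genes - 1)),
                            size = 50),
             stats::rnbinom(n_genes, mu = mu, size = 50),
             stats::rnbinom(n_genes, mu = mu, size = 50))
  degs <- call_degs(mk_ct(m))
  expect_equal(degs$call[1], "induced")
  expect_gt(degs$fold_change[1], 6)
  expect_lt(degs$fold_change[1], 10)
})

test_that("BH-adjusted values are monotone in p-value rank", {
  set.seed(43)
  m <- matrix(stats::rnbinom(400 * 4, mu = 300, size = 50), ncol = 4)
  degs <- call_degs(mk_ct(m))
  o <- order(degs$p_value)
  expect_true(all(diff(degs$fdr[o]) >= -1e-12))
})

test_that("replicate correlation is 1 for duplicated replicates and ~0 for noise", {
  set.seed(44)
  base <- stats::rnbinom(1000, mu = 400, size = 10)
  m <- cbind(base, base, base, base)
  expect_equal(unname(replicate_correlation(mk_ct(m))), c(1, 1))
  m2 <- matrix(stats::rnbinom(4000, mu = 400, size = 10), ncol = 4)
  r <- replicate_correlation(mk_ct(m2))
  expect_true(all(abs(r) < 0.1))
  expect_error(replicate_correlation(mk_ct(m2, cond = c("EPO+", "EPO-",
                                                        "EPO-", "EPO-"))),
               "replicates")
})

test_that("synthetic replicates at default noise correlate above 0.9", {
  cfg <- small_sim_config(seed = 6)
  genome <- generate_genome(cfg)
  expr <- generate_count_table(cfg, genome$genes)
  r <- replicate_correlation(expr$counts)
  expect_true(all(r >= 0.9))
})

test_that("RLE scaling absorbs a planted library scale factor", {
  set.seed(45)
  base <- matrix(stats::rnbinom(300 * 3, mu = 200, size = 20) + 1, ncol = 3)
  scaled <- base
  scaled[, 2] <- base[, 2] * 4L
  r0 <- rle_normalize(base)
  r1 <- rle_normalize(scaled)
  # scale factors are defined up to the geometric-mean anchor, so the
  # relative factor of the scaled library rises by exactly 4
  expect_equal(unname((r1$scale_factors[2] / r1$scale_factors[1]) /
                        (r0$scale_factors[2] / r0$scale_factors[1])), 4,
               tolerance = 1e-9)
  # normalized values are unchanged up to one global constant
  ratio <- r1$normalized / r0$normalized
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("identical libraries get identical scale factors", {
  base <- matrix(rep(c(5, 80, 300, 17), 3), ncol = 3)
  expect_equal(unname(rle_normalize(base)$scale_factors), rep(1, 3))
})

test_that("RLE factors match a hand-computed median-of-ratios fixture", {
  counts <- rbind(c(10, 20), c(100, 200), c(4, 8), c(0, 5))
  # rows without zeros: geometric means sqrt(200), sqrt(20000), sqrt(32);
  # ratios col1: 10/14.142..., 100/141.42..., 4/5.656... all = 0.7071
  res <- suppressWarnings(rle_normalize(counts))
  expect_equal(unname(res$scale_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)
})

test_that("all-zero-containing regions trigger the upper-quartile fallback", {
  counts <- cbind(c(0, 5, 0), c(3, 0, 9))
  expect_warning(res <- rle_normalize(counts), "upper-quartile")
  expect_equal(length(res$scale_factors), 2L)
})

test_that("dynamics classification separates immediate, delayed and flat series", {
  times <- c(0, 30, 120, 240, 1440)
  expect_equal(classify_dynamics(c(1, 4, 3, 2, 1) * 100, times)$class,
               "immediate")
  expect_equal(classify_dynamics(c(1, 1.2, 3, 4, 2) * 100, times)$class,
               "delayed")
  expect_equal(classify_dynamics(rep(100, 5), times)$class, "unresponsive")
  expect_error(classify_dynamics(100, 0), "single")
})

test_that("CAGE matrix classification recovers planted dynamics", {
  cfg <- small_sim_config(seed = 8)
  cage <- generate_cage_series(cfg)
  dyn <- classify_cage_dynamics(cage$counts)
  expect_gte(mean(dyn$class == cage$truth$class), 0.95)
})
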