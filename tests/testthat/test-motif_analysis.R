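test_that("degenerate consensus matching follows IUPAC sets on both strands", {
  hits <- iupac_match("TTCYMRGAA", "TTCCAGGAA")
  # forward match at 0; the GAS layout also matches on the reverse strand
  expect_true(any(hits$start == 0 & hits$strand == "+"))
  expect_equal(nrow(iupac_match("TTCYMRGAA", "TTCGAGGAA")), 0L)
  expect_error(iupac_match("TTCXAGGAA", "TTCCAGGAA"), "IUPAC")
})

test_that("exactly eight distinct 9-mers match the GAS consensus", {
  sets <- list(T = "T", T2 = "T", C = "C", Y = c("C", "T"), M = c("A", "C"),
               R = c("A", "G"), G = "G", A = "A", A2 = "A")
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  kmers <- apply(combos, 1, paste, collapse = "")
  expect_equal(length(unique(kmers)), 8L)
  for (k in kmers) {
    expect_true(any(iupac_match("TTCYMRGAA", k)$start == 0))
  }
})

test_that("N in the sequence matches only an N in the pattern", {
  expect_equal(nrow(iupac_match("TTCYMRGAA", "TTCNAGGAA")), 0L)
  expect_true(nrow(iupac_match("TTN", "TTN")) > 0)
})

test_that("palindromy is exact reverse-complement identity", {
  expect_true(is_palindromic("TTCCNGGAA"))
  # the printed GAS consensus is close to, but not exactly, palindromic
  expect_false(is_palindromic("TTCYMRGAA"))
  expect_equal(revcomp_pattern("TTCYMRGAA"), "TTCYKRGAA")
  expect_false(is_palindromic("A"))
})

test_that("reverse complement is an involution on random patterns", {
  set.seed(9)
  syms <- c("A", "C", "G", "T", "R", "Y", "M", "K", "S", "W", "N")
  for (i in 1:20) {
    p <- paste(sample(syms, sample(4:12, 1), replace = TRUE), collapse = "")
    expect_equal(revcomp_pattern(revcomp_pattern(p)), p)
  }
})

test_that("strand symmetry: pattern on seq equals revcomp pattern on revcomp seq", {
  set.seed(10)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:10) {
    s <- random_dna_str(80)
    rc <- paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
    n1 <- nrow(iupac_match("TTCYMRGAA", s))
    n2 <- nrow(iupac_match(revcomp_pattern("TTCYMRGAA"), rc))
    expect_equal(n1, n2)
  }
})

test_that("PWM construction applies the pseudocount formula", {
  p <- build_pwm(c("AC", "AC"), pseudocount = 0)
  expect_equal(unname(p$probs["A", 1]), 1)
  expect_equal(unname(p$probs["C", 2]), 1)
  p2 <- build_pwm(c("A", "A"), pseudocount = 1)
  expect_equal(unname(p2$probs["A", 1]), 3 / 6)
  expect_error(build_pwm(c("AC", "ACG")), "ragged")
})

test_that("PWM probabilities converge to the generating distribution", {
  set.seed(12)
  truth <- c(A = 0.5, C = 0.3, G = 0.15, T = 0.05)
  sites <- replicate(400, paste(
    sample(names(truth), 6, replace = TRUE, prob = truth), collapse = ""))
  p <- build_pwm(sites, pseudocount = 0.5)
  expect_true(all(abs(p$probs - truth[rownames(p$probs)]) < 0.1))
})

test_that("PWM scanning scores log-odds in bits and honours thresholds", {
  p <- build_pwm(c("AAAA", "AAAA"), pseudocount = 0)
  hits <- scan_pwm(p, "AAAAAA", threshold = 7.9)
  expect_equal(hits$score[hits$strand == "+"], rep(8, 3))  # 4 * log2(1/0.25)
  expect_equal(nrow(scan_pwm(p, "AAAAAA", threshold = Inf)), 0L)
})

test_that("PWM scanning equals the exhaustive oracle", {
  set.seed(13)
  for (i in 1:10) {
    pwm <- random_pwm(sample(4:8, 1))
    s <- random_dna_str(sample(30:200, 1))
    got <- scan_pwm(pwm, s, threshold = -2)
    want <- oracle_scan_pwm(pwm, s, threshold = -2)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("all-central best sites give the closed-form binomial p-value", {
  set.seed(14)
  seqs <- vapply(1:10, function(i) {
    s <- random_dna_str(101)
    paste0(substr(s, 1, 46), "TTCCAGGAA", substr(s, 56, 101))
  }, "")
  res <- central_enrichment_test(consensus_pwm("TTCYMRGAA"), seqs)
  expect_equal(res$best_window_width, 1L)
  expect_equal(res$central_count, 10L)
  expect_equal(res$p_value, (1 / 93)^10, tolerance = 1e-9)
})

test_that("a single sequence yields the n = 1 binomial tail", {
  res <- central_enrichment_stat(centres = 50, L = 101, w = 9)
  expect_equal(res$p_value, 1 / 93, tolerance = 1e-12)
  off <- central_enrichment_stat(centres = 10, L = 101, w = 9)
  expect_gt(off$p_value, 1 / 93)
})

test_that("uniform best-site positions are not called centrally enriched", {
  set.seed(15)
  centres <- sample(0:92, 200, replace = TRUE) + 4
  res <- central_enrichment_stat(centres, L = 101, w = 9)
  expect_gt(res$adjusted_p, 0.01)
})

test_that("degenerate inputs to the enrichment test are rejected", {
  expect_error(central_enrichment_test("TTCYMRGAA", character(0)), "zero")
  expect_error(central_enrichment_test("TTCYMRGAA", c("ACGT", "ACG")), "equal")
  expect_error(central_enrichment_test("TTCYMRGAA", "ACGT"), "wider")
})
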