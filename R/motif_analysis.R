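# Degenerate-consensus and PWM motif detection, plus the central-enrichment
# statistic used to confirm that binding sites concentrate at peak summits.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", M = "K", K = "M", S = "S", W = "W",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

#' Motif presets used throughout the pipeline
#'
#' Degenerate consensus strings for the three motif families enriched at
#' pSTAT5-occupied sites: the palindrome-like GAS element bound by STAT
#' dimers, the GATA-factor site (in its two printed variants), and the
#' KLF/CACCC-box site.
#'
#' @return Named character vector of IUPAC consensus strings.
#' @export
motif_presets <- function() {
  c(GAS = "TTCYMRGAA",
    GATA = "WGATAR",
    GATA_alt = "WGATAA",
    KLF = "CCMCRCCCN")
}

check_iupac <- function(pattern) {
  sym <- strsplit(pattern, "")[[1L]]
  if (length(sym) == 0L) stop("empty motif pattern")
  bad <- setdiff(sym, names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC symbol(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "))
  }
  sym
}

#' Reverse complement of a degenerate IUPAC pattern
#' @param pattern IUPAC consensus string.
#' @return The reverse-complemented pattern.
#' @export
revcomp_pattern <- function(pattern) {
  sym <- check_iupac(pattern)
  paste(rev(unname(IUPAC_COMPLEMENT[sym])), collapse = "")
}

#' Is a degenerate pattern palindromic?
#'
#' TRUE iff the pattern equals its own reverse complement symbol-for-symbol.
#' Note the GAS consensus TTCYMRGAA is *not* exactly palindromic by this
#' test (its reverse complement is TTCYKRGAA); the fully degenerate form
#' TTCNNNGAA is.
#'
#' @param pattern IUPAC consensus string.
#' @export
is_palindromic <- function(pattern) {
  identical(pattern, revcomp_pattern(pattern))
}

#' Match a degenerate consensus on both strands
#'
#' A hit is reported at every offset where each pattern symbol's IUPAC set
#' contains the sequence base. An `N` in the *sequence* matches only an `N`
#' in the pattern. The reverse strand is scanned by matching the
#' reverse-complemented pattern on the forward sequence; reverse-strand hit
#' positions refer to the forward coordinate of the matched window.
#'
#' @param pattern IUPAC consensus string.
#' @param seq DNA string over A/C/G/T/N.
#' @param sequence_id Identifier recorded in the hit table.
#' @return `data.frame` with columns `sequence_id`, `start` (0-based),
#'   `strand`, `score` (1 for an exact consensus match).
#' @export
iupac_match <- function(pattern, seq, sequence_id = "seq") {
  sym <- check_iupac(pattern)
  w <- length(sym)
  bases <- strsplit(toupper(seq), "")[[1L]]
  L <- length(bases)
  hits <- list()
  for (strand in c("+", "-")) {
    psym <- if (strand == "+") sym else strsplit(revcomp_pattern(pattern), "")[[1L]]
    if (L < w) break
    ok <- rep(TRUE, L - w + 1L)
    for (j in seq_len(w)) {
      sets <- IUPAC_SETS[psym[j]][[1L]]
      b <- bases[j:(L - w + j)]
      # sequence N only matches a pattern N
      ok <- ok & ((b %in% sets) | (b == "N" & psym[j] == "N"))
    }
    if (any(ok)) {
      hits[[strand]] <- data.frame(sequence_id = sequence_id,
                                   start = which(ok) - 1L, strand = strand,
                                   score = 1, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(sequence_id = character(), start = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param sites Character vector of equal-length aligned DNA sites (>= 2).
#' @param pseudocount Per-base pseudocount (default 0.5).
#' @param background Base composition, length-4 named numeric summing to 1
#'   (default uniform).
#' @return A `pwm` object: list with `probs` (4 x width matrix, rows
#'   A/C/G/T), `background`, `width`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(length(sites) >= 2L)
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) stop("ragged site lengths")
  w <- lens[1L]
  stopifnot(abs(sum(background) - 1) < 1e-9)
  mat <- do.call(rbind, strsplit(toupper(sites), ""))
  probs <- vapply(seq_len(w), function(j) {
    cnt <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    (as.numeric(cnt) + pseudocount) / (length(sites) + 4 * pseudocount)
  }, numeric(4))
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(probs = probs, background = background[c("A", "C", "G", "T")],
                 width = w), class = "pwm")
}

#' Build a PWM directly from a degenerate consensus
#'
#' Allowed bases of each symbol share the column probability equally
#' (softened by the pseudocount), giving a scoring model for consensus
#' motifs that central-enrichment analysis can rank.
#'
#' @inheritParams build_pwm
#' @param pattern IUPAC consensus string.
#' @export
consensus_pwm <- function(pattern, pseudocount = 0.01,
                          background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sym <- check_iupac(pattern)
  probs <- vapply(sym, function(s) {
    p <- stats::setNames(rep(pseudocount / 4, 4), c("A", "C", "G", "T"))
    allowed <- IUPAC_SETS[[s]]
    p[allowed] <- p[allowed] + (1 - pseudocount) / length(allowed)
    p
  }, numeric(4))
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(probs = probs, background = background[c("A", "C", "G", "T")],
                 width = length(sym)), class = "pwm")
}

pwm_score_matrix <- function(pwm) {
  log2(pwm$probs / pwm$background)
}

score_offsets <- function(scores, bases, w) {
  L <- length(bases)
  n_off <- L - w + 1L
  if (n_off < 1L) return(numeric(0))
  idx <- match(bases, c("A", "C", "G", "T"))  # N -> NA -> -Inf
  total <- rep(0, n_off)
  for (j in seq_len(w)) {
    col <- scores[, j][idx[j:(L - w + j)]]
    col[is.na(col)] <- -Inf
    total <- total + col
  }
  total
}

#' Scan a PWM over a sequence on both strands
#'
#' Log-odds scores in bits (`log2(prob/background)` summed over positions);
#' windows containing `N` score `-Inf`. Reverse-strand hits are scored on
#' the reverse complement and reported at the forward-strand offset of the
#' window.
#'
#' @param pwm A `pwm` from [build_pwm()] or [consensus_pwm()].
#' @param seq DNA string.
#' @param threshold Minimum score (bits) for a hit.
#' @param sequence_id Identifier recorded in the hit table.
#' @return `data.frame` with `sequence_id`, `start` (0-based), `strand`,
#'   `score`.
#' @export
scan_pwm <- function(pwm, seq, threshold = 0, sequence_id = "seq") {
  bases <- strsplit(toupper(seq), "")[[1L]]
  stopifnot(length(bases) >= pwm$width)
  sc <- pwm_score_matrix(pwm)
  fwd <- score_offsets(sc, bases, pwm$width)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
  rc <- rev(unname(comp))
  rev_scores <- rev(score_offsets(sc, rc, pwm$width))
  keep_f <- which(fwd >= threshold)
  keep_r <- which(rev_scores >= threshold)
  out <- data.frame(
    sequence_id = rep(sequence_id, length(keep_f) + length(keep_r)),
    start = c(keep_f, keep_r) - 1L,
    strand = c(rep("+", length(keep_f)), rep("-", length(keep_r))),
    score = c(fwd[keep_f], rev_scores[keep_r]),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

best_site_centre <- function(pwm, seq) {
  bases <- strsplit(toupper(seq), "")[[1L]]
  L <- length(bases)
  w <- pwm$width
  sc <- pwm_score_matrix(pwm)
  fwd <- score_offsets(sc, bases, w)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
  rev_scores <- rev(score_offsets(sc, rev(unname(comp)), w))
  score <- pmax(fwd, rev_scores)
  best <- max(score)
  if (!is.finite(best)) return(NA_real_)
  cand <- which(score == best) - 1L          # 0-based offsets
  centre_seq <- (L - 1) / 2
  centres <- cand + (w - 1) / 2
  # ties: closest to centre, then lowest offset
  cand <- cand[order(abs(centres - centre_seq), cand)]
  cand[1L] + (w - 1) / 2
}

#' Central-enrichment statistic from best-site centre positions
#'
#' For odd window widths `W = 1, 3, ...` up to `max_window`, counts the
#' best sites whose centre lies within `(W - 1)/2` of the sequence centre
#' and computes the binomial tail `P(X >= k | n, p0)` with `p0` the
#' fraction of possible site-centre positions inside the window. The
#' reported window minimizes the p-value; `adjusted_p` is a Bonferroni
#' correction over the number of windows tested.
#'
#' @param centres Numeric vector of best-site centre positions (one per
#'   sequence; `NA` = no scoreable site, dropped).
#' @param L Common sequence length.
#' @param w Motif width.
#' @param max_window Largest window width tested (default `L/2`).
#' @return List with `best_window_width`, `central_count`, `total_count`,
#'   `p_value`, `adjusted_p`, `n_windows`.
#' @export
central_enrichment_stat <- function(centres, L, w, max_window = floor(L / 2)) {
  centres <- centres[!is.na(centres)]
  n <- length(centres)
  if (n == 0L) stop("no scoreable sequences")
  stopifnot(w <= L)
  centre_seq <- (L - 1) / 2
  n_pos <- L - w + 1L
  widths <- seq(1L, max(1L, max_window), by = 2L)
  all_centres <- (0:(n_pos - 1L)) + (w - 1) / 2
  best <- NULL
  for (W in widths) {
    half <- (W - 1) / 2
    inside <- sum(abs(all_centres - centre_seq) <= half)
    if (inside == 0L) next
    p0 <- inside / n_pos
    k <- sum(abs(centres - centre_seq) <= half)
    p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    if (is.null(best) || p < best$p_value) {
      best <- list(best_window_width = W, central_count = k,
                   total_count = n, p_value = p)
    }
  }
  best$adjusted_p <- min(1, best$p_value * length(widths))
  best$n_windows <- length(widths)
  best
}

#' Central-enrichment test for a motif over summit-centred sequences
#'
#' Takes the single best-scoring site per sequence (ties resolved towards
#' the sequence centre, then the lowest offset) and tests whether the best
#' sites concentrate near the centre; see [central_enrichment_stat()] for
#' the statistic. Consensus motifs are scored through [consensus_pwm()].
#'
#' @param motif A `pwm` or an IUPAC consensus string.
#' @param sequences Character vector of equal-length, summit-centred
#'   sequences.
#' @param max_window Largest (odd) central window width tested.
#' @return As [central_enrichment_stat()].
#' @export
central_enrichment_test <- function(motif, sequences,
                                    max_window = floor(nchar(sequences[1L]) / 2)) {
  if (length(sequences) == 0L) stop("zero sequences")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length")
  pwm <- if (inherits(motif, "pwm")) motif else consensus_pwm(motif)
  if (pwm$width > L) stop("motif wider than sequences")
  centres <- vapply(sequences, function(s) best_site_centre(pwm, s), 0,
                    USE.NAMES = FALSE)
  central_enrichment_stat(centres, L, pwm$width, max_window)
}
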