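# In-house PWM scanner: log-odds scoring on both strands with exact
# per-position p-values from a dynamic-programming convolution over an
# integerized score grid. Replaces an external FIMO-style stage.

BASES <- c("A", "C", "G", "T")

# complement index: A<->T, C<->G on the 1..4 coding
COMP <- c(4L, 3L, 2L, 1L)

seq_to_codes <- function(sequence) {
  x <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], BASES)
  x # N and anything else -> NA
}

#' Build a position weight matrix from a PFM
#'
#' Standard log-odds construction: per column,
#' `prob[b] = (count[b] + pseudocount * background[b]) / (total + pseudocount)`
#' and `logodds = log2(prob / background)` (bits). The pseudocount is
#' distributed by background so zero counts stay finite.
#'
#' Scores are also integerized on a grid of `granularity` bins per bit
#' (`round(logodds * granularity)`), the grid on which the exact p-value
#' distribution is computed; the grid is the only source of p-value
#' discretization error.
#'
#' @param pfm A PFM record from [read_jaspar_pfm()] (list with `motif_id`,
#'   `motif_name`, `counts`), or a bare 4 x w count matrix.
#' @param pseudocount Positive pseudocount mass.
#' @param background Base frequencies (A, C, G, T), strictly positive,
#'   summing to 1.
#' @param granularity Integer score bins per bit.
#' @return Object of class `pwm`: list with `motif_id`, `motif_name`,
#'   `probs`, `background`, `logodds`, `int_scores`, `granularity`,
#'   `consensus`, `width`, `min_score`, `max_score`, `ic_bits` (total
#'   information content).
#' @examples
#' pwm <- pfm_to_pwm(matrix(c(4, 0, 0, 0, 0, 4, 0, 0), nrow = 4))
#' pwm$consensus
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.1,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       granularity = 1000) {
  if (is.matrix(pfm)) {
    pfm <- list(motif_id = "motif", motif_name = "motif", counts = pfm)
  }
  counts <- pfm$counts
  stopifnot(nrow(counts) == 4, all(counts >= 0))
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  background <- as.numeric(background)
  if (length(background) != 4 || any(background <= 0)) {
    stop("background must be 4 strictly positive frequencies", call. = FALSE)
  }
  background <- background / sum(background)
  totals <- colSums(counts)
  probs <- sweep(counts + pseudocount * background, 2, totals + pseudocount, "/")
  logodds <- log2(probs / background)
  rownames(probs) <- rownames(logodds) <- BASES
  int_scores <- round(logodds * granularity)
  structure(
    list(
      motif_id = pfm$motif_id,
      motif_name = pfm$motif_name,
      probs = probs,
      background = stats::setNames(background, BASES),
      logodds = logodds,
      int_scores = int_scores,
      granularity = granularity,
      consensus = paste(BASES[apply(probs, 2, which.max)], collapse = ""),
      width = ncol(counts),
      min_score = sum(apply(logodds, 2, min)),
      max_score = sum(apply(logodds, 2, max)),
      ic_bits = sum(2 + colSums(probs * log2(probs)))
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, " (", x$motif_name, "): width ", x$width,
      ", consensus ", x$consensus, ", ",
      formatC(x$ic_bits, digits = 2, format = "f"), " bits\n", sep = "")
  invisible(x)
}

# Exact distribution of the integer score of a random background word:
# convolve the 4-point column distributions. Returns list(offset, surv) where
# surv[k] = Pr(int score >= offset + k - 1).
score_distribution <- function(int_scores, background) {
  w <- ncol(int_scores)
  mins <- apply(int_scores, 2, min)
  maxs <- apply(int_scores, 2, max)
  lo <- sum(mins); hi <- sum(maxs)
  d <- numeric(hi - lo + 1L)
  d[1L] <- 1 # start at offset lo with the degenerate distribution
  cur_lo <- 0L
  cur_len <- 1L
  for (j in seq_len(w)) {
    nd <- numeric(length(d))
    s <- int_scores[, j] - mins[j]
    for (b in 1:4) {
      if (background[b] == 0) next
      idx <- seq_len(cur_len) + s[b]
      nd[idx] <- nd[idx] + d[seq_len(cur_len)] * background[b]
    }
    cur_len <- cur_len + (maxs[j] - mins[j])
    d <- nd
  }
  surv <- rev(cumsum(rev(d)))
  list(offset = lo, surv = surv, max = hi)
}

# p-value lookup for an integer score under a precomputed distribution
surv_lookup <- function(dist, int_score) {
  k <- int_score - dist$offset + 1L
  ifelse(k <= 0L, 1, ifelse(k > length(dist$surv), 0, dist$surv[pmax(k, 1L)]))
}

#' Exact PWM score p-value
#'
#' `Pr(score >= threshold)` for a random word drawn i.i.d. from the
#' background, computed by dynamic programming over the integerized score
#' grid (exact on the grid). Thresholds at or below the minimum score give
#' p = 1; p is non-increasing in the threshold.
#'
#' @param pwm A [pfm_to_pwm()] object.
#' @param threshold Score threshold in bits.
#' @return The p-value.
#' @export
score_pvalue <- function(pwm, threshold) {
  stopifnot(inherits(pwm, "pwm"), is.finite(threshold))
  if (threshold <= pwm$min_score) return(1)
  dist <- score_distribution(pwm$int_scores, pwm$background)
  t_int <- as.integer(round(threshold * pwm$granularity))
  surv_lookup(dist, t_int)
}

# CpG sites (0-based C positions) associated with a hit interval
# [start, end): "contain" needs both bases inside, "any" needs >= 1 base.
contained_cpg_indices <- function(start, end, cpg_positions,
                                  overlap = c("contain", "any")) {
  overlap <- match.arg(overlap)
  if (overlap == "contain") {
    which(cpg_positions >= start & cpg_positions + 2 <= end)
  } else {
    which(cpg_positions + 1 >= start & cpg_positions < end)
  }
}

#' Scan a promoter sequence with a PWM
#'
#' Scores every offset on both strands (the minus strand is scored with the
#' reverse-complemented matrix and reported in plus-strand coordinates),
#' assigns each position its exact background p-value, and returns hits with
#' `p <= p_threshold`, sorted by start then strand. Each hit carries the
#' indices (1-based, into the region's CpG list) of CpG dinucleotides it
#' covers under the chosen overlap rule. Overlapping hits of the same motif
#' are all reported. Positions covering an `N` are skipped. Benjamini-
#' Hochberg q-values are computed across every scored (motif, position,
#' strand) test in the call.
#'
#' @param pwms A `pwm`, or list of them (scan all).
#' @param region A [promoter_region()].
#' @param p_threshold Per-position p-value cutoff (default 1e-4).
#' @param overlap CpG association rule: `"contain"` (both bases of the
#'   dinucleotide inside the hit) or `"any"` (at least one base).
#' @return Tibble with columns `motif_id`, `motif_name`, `region`, `start`,
#'   `end` (0-based half-open), `strand`, `score` (bits), `p`, `q`,
#'   `contained_cpgs` (list column of CpG indices), `cpg_labels`
#'   (comma-separated 1-based labels).
#' @export
scan_sequence <- function(pwms, region, p_threshold = 1e-4,
                          overlap = c("contain", "any")) {
  overlap <- match.arg(overlap)
  stopifnot(inherits(region, "promoter_region"))
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  codes <- seq_to_codes(region$sequence)
  L <- length(codes)

  per_motif <- purrr::map(pwms, function(pwm) {
    w <- pwm$width
    if (L < w) return(NULL)
    n_pos <- L - w + 1L
    rc_int <- pwm$int_scores[COMP, rev(seq_len(w)), drop = FALSE]
    score_strand <- function(m) {
      s <- numeric(n_pos)
      ok <- rep(TRUE, n_pos)
      for (j in seq_len(w)) {
        cj <- codes[seq_len(n_pos) + j - 1L]
        bad <- is.na(cj)
        ok <- ok & !bad
        cj[bad] <- 1L
        s <- s + m[cbind(cj, j)]
      }
      s[!ok] <- NA_real_
      s
    }
    fwd <- score_strand(pwm$int_scores)
    rev_ <- score_strand(rc_int)
    dist_f <- score_distribution(pwm$int_scores, pwm$background)
    dist_r <- score_distribution(rc_int, pwm$background)
    tibble::tibble(
      motif_id = pwm$motif_id,
      motif_name = pwm$motif_name,
      start = rep(0:(n_pos - 1L), 2L),
      end = rep(0:(n_pos - 1L) + w, 2L),
      strand = rep(c("+", "-"), each = n_pos),
      int_score = c(fwd, rev_),
      score = c(fwd, rev_) / pwm$granularity,
      p = c(surv_lookup(dist_f, fwd), surv_lookup(dist_r, rev_))
    )
  })
  all_tests <- dplyr::bind_rows(per_motif)
  if (nrow(all_tests) == 0) return(empty_hits())
  all_tests <- all_tests[!is.na(all_tests$int_score), ]
  all_tests$q <- stats::p.adjust(all_tests$p, method = "BH")
  hits <- all_tests[all_tests$p <= p_threshold, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  hits$region <- region$name
  hits$contained_cpgs <- purrr::map2(
    hits$start, hits$end,
    ~ contained_cpg_indices(.x, .y, region$cpg_positions, overlap)
  )
  hits$cpg_labels <- vapply(
    hits$contained_cpgs, function(v) paste(v, collapse = ","), character(1)
  )
  hits <- hits[order(hits$start, hits$strand, hits$motif_id), ]
  tibble::as_tibble(hits[c(
    "motif_id", "motif_name", "region", "start", "end", "strand",
    "score", "p", "q", "contained_cpgs", "cpg_labels"
  )])
}

empty_hits <- function() {
  tibble::tibble(
    motif_id = character(0), motif_name = character(0), region = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    score = numeric(0), p = numeric(0), q = numeric(0),
    contained_cpgs = list(), cpg_labels = character(0)
  )
}

#' Retain motif hits overlapping CpG dinucleotides
#'
#' Keeps statistically significant hits whose `contained_cpgs` is non-empty
#' (the CpG association rule was fixed at scan time), preserving order —
#' the retention step applied before CpG-frequency integration.
#'
#' @param hits Hit tibble from [scan_sequence()].
#' @return The filtered tibble.
#' @export
retain_cpg_overlapping <- function(hits) {
  hits[lengths(hits$contained_cpgs) > 0, , drop = FALSE]
}

#' Reverse complement of a DNA string
#'
#' @param sequence DNA string over `A,C,G,T,N`.
#' @return The reverse complement.
#' @export
reverse_complement <- function(sequence) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(sequence), "",
                                              fixed = TRUE)[[1]]), collapse = ""))
}
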