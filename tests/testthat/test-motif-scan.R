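test_that("PFM to PWM conversion matches closed forms", {
  # uniform column: log-odds 0 everywhere
  uni <- pfm_to_pwm(matrix(1, 4, 3))
  expect_true(all(abs(uni$logodds) < 1e-12))

  # counts [3,1,1,1] with a vanishing pseudocount: A log-odds -> 1 bit
  sk <- pfm_to_pwm(matrix(c(3, 1, 1, 1), 4, 1), pseudocount = 1e-9)
  expect_equal(unname(sk$logodds["A", 1]), 1, tolerance = 1e-6)

  # probability columns always sum to 1
  set.seed(5)
  for (i in 1:10) {
    counts <- matrix(rpois(4 * 6, 5), 4, 6)
    counts[counts == 0 & row(counts) == 1] <- 1 # keep columns non-degenerate
    p <- pfm_to_pwm(counts, pseudocount = runif(1, 0.01, 2))
    expect_equal(unname(colSums(p$probs)), rep(1, 6), tolerance = 1e-9)
    expect_lte(p$min_score, p$max_score)
  }

  expect_error(pfm_to_pwm(matrix(1, 4, 2), pseudocount = 0), "pseudocount")
  expect_error(pfm_to_pwm(matrix(1, 4, 2), background = c(0.5, 0.5, 0, 0)),
               "strictly positive")
})

test_that("score p-values match closed forms and are monotone", {
  w1 <- pfm_to_pwm(matrix(c(100, 1, 1, 1), 4, 1))
  # unique best base at a width-1 motif: p at the max score is 1/4
  expect_equal(score_pvalue(w1, w1$max_score), 0.25)
  expect_equal(score_pvalue(w1, w1$min_score - 1), 1)
  expect_equal(score_pvalue(w1, w1$min_score), 1)

  set.seed(8)
  counts <- matrix(rpois(4 * 4, 4) + 1, 4, 4)
  pwm <- pfm_to_pwm(counts)
  ts <- seq(pwm$min_score - 0.5, pwm$max_score + 0.5, length.out = 40)
  ps <- vapply(ts, function(t) score_pvalue(pwm, t), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_equal(ps[1], 1)
})

test_that("DP p-values equal exhaustive word enumeration", {
  set.seed(10)
  for (i in 1:20) {
    w <- sample(2:4, 1)
    counts <- matrix(rpois(4 * w, 3) + 1, 4, w)
    bg <- if (i %% 2 == 0) rep(0.25, 4) else c(0.3, 0.2, 0.2, 0.3)
    pwm <- pfm_to_pwm(counts, background = bg)
    enum <- oracle_pwm_enumeration(pwm$logodds, pwm$background, pwm$granularity)
    candidates <- enum$real[enum$real > pwm$min_score + 1e-9]
    for (thr in sample(candidates, 4)) {
      p_dp <- score_pvalue(pwm, thr)
      # same integer grid, independent enumeration path: exact agreement
      t_int <- round(thr * pwm$granularity)
      expect_equal(p_dp, sum(enum$prob[enum$grid >= t_int]), tolerance = 1e-12)
      # real-score enumeration within the integerization tolerance
      tol <- (0.5 * ncol(counts) + 1) / pwm$granularity
      expect_lte(p_dp, sum(enum$prob[enum$real >= thr - tol]) + 1e-12)
      expect_gte(p_dp, sum(enum$prob[enum$real >= thr + tol]) - 1e-12)
    }
  }
})

test_that("scanning recovers a planted consensus and respects thresholds", {
  pwm <- pfm_to_pwm(consensus_pfm("TTGACGTCAA"))
  set.seed(12)
  bg <- random_seq(200)
  seqc <- paste0(substr(bg, 1, 50), pwm$consensus, substr(bg, 61, 200))
  region <- promoter_region("r", seqc)
  hits <- scan_sequence(pwm, region, p_threshold = 1e-4)
  expect_true(any(hits$start == 50 & hits$strand == "+"))
  expect_true(all(hits$p <= 1e-4))
  expect_true(all(hits$end - hits$start == pwm$width))

  none <- scan_sequence(pwm, region, p_threshold = 0)
  expect_equal(nrow(none), 0)

  short <- promoter_region("s", "ACGT")
  expect_equal(nrow(scan_sequence(pwm, short)), 0)
})

test_that("hit sets mirror between a sequence and its reverse complement", {
  pwm <- pfm_to_pwm(consensus_pfm("TTGACGTC"))
  set.seed(14)
  seqc <- paste0(random_seq(40), pwm$consensus, random_seq(40))
  fwd <- scan_sequence(pwm, promoter_region("f", seqc), p_threshold = 1e-3)
  rev_ <- scan_sequence(pwm, promoter_region("r", reverse_complement(seqc)),
                        p_threshold = 1e-3)
  L <- nchar(seqc)
  mirrored <- tibble::tibble(
    start = L - rev_$end, end = L - rev_$start,
    strand = ifelse(rev_$strand == "+", "-", "+"),
    score = rev_$score
  )
  ord <- function(d) d[order(d$start, d$strand), ]
  expect_equal(ord(mirrored)$start, ord(fwd[c("start", "end", "strand", "score")])$start)
  expect_equal(ord(mirrored)$strand, ord(fwd[c("start", "end", "strand", "score")])$strand)
  expect_equal(ord(mirrored)$score, ord(fwd[c("start", "end", "strand", "score")])$score)
})

test_that("CpG containment distinguishes full containment from any overlap", {
  # motif ends on the C of a CpG: C inside the hit, G just outside
  pwm <- pfm_to_pwm(consensus_pfm("AATTAATC"))
  seqc <- paste0(strrep("A", 10), "AATTAATC", "G", strrep("T", 20))
  region <- promoter_region("r", seqc)
  expect_equal(region$cpg_positions, 17L) # the C at the hit's last base

  contain <- scan_sequence(pwm, region, p_threshold = 1e-3, overlap = "contain")
  hit <- contain[contain$start == 10 & contain$strand == "+", ]
  expect_equal(lengths(hit$contained_cpgs), 0)
  expect_equal(nrow(retain_cpg_overlapping(hit)), 0)

  any_ov <- scan_sequence(pwm, region, p_threshold = 1e-3, overlap = "any")
  hit2 <- any_ov[any_ov$start == 10 & any_ov$strand == "+", ]
  expect_equal(hit2$contained_cpgs[[1]], 1)
  expect_equal(nrow(retain_cpg_overlapping(hit2)), 1)

  # fully contained CpG is kept under the default rule
  pwm2 <- pfm_to_pwm(consensus_pfm("AATCGAAT"))
  seq2 <- paste0(strrep("A", 10), "AATCGAAT", strrep("T", 20))
  region2 <- promoter_region("r2", seq2)
  got <- scan_sequence(pwm2, region2, p_threshold = 1e-3)
  expect_equal(got$contained_cpgs[[which(got$start == 10 & got$strand == "+")]], 1)

  # region without CpGs: retention empties everything
  no_cpg <- promoter_region("r3", paste0(strrep("A", 12), "AATTAATC", strrep("T", 12)))
  expect_equal(nrow(retain_cpg_overlapping(
    scan_sequence(pwm, no_cpg, p_threshold = 1e-3)
  )), 0)
})

test_that("q-values are BH-adjusted over all scored tests", {
  pwm <- pfm_to_pwm(consensus_pfm("TTGACGTC"))
  set.seed(20)
  region <- promoter_region("r", paste0(random_seq(60), pwm$consensus, random_seq(60)))
  hits <- scan_sequence(pwm, region, p_threshold = 1)
  expect_true(all(hits$q >= hits$p - 1e-15))
  expect_true(all(hits$q <= 1))
})
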