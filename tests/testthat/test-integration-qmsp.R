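fake_hits <- function(contained, region_name = "r") {
  tibble::tibble(
    motif_id = sprintf("M%d", seq_along(contained)),
    motif_name = "m", region = region_name,
    start = 0L, end = 8L, strand = "+",
    score = 1, p = 1e-5, q = 1e-4,
    contained_cpgs = contained,
    cpg_labels = vapply(contained, paste, character(1), collapse = ",")
  )
}

test_that("TFBS frequencies count per-CpG hit containment", {
  region <- promoter_region("r", strrep("ACGT", 10)) # 10 CpGs
  hits <- fake_hits(list(5L, 5L, 7L))
  fr <- tfbs_frequency_per_cpg(hits, region)
  expect_equal(fr$tfbs_frequency[fr$cpg == 5], 2)
  expect_equal(fr$tfbs_frequency[fr$cpg == 7], 1)
  expect_true(all(fr$tfbs_frequency[!fr$cpg %in% c(5, 7)] == 0))

  none <- tfbs_frequency_per_cpg(fake_hits(list())[0, ], region)
  expect_true(all(none$tfbs_frequency == 0))

  # a hit spanning two CpGs increments both; counting is conserved
  span <- fake_hits(list(c(3L, 4L), 4L))
  fr2 <- tfbs_frequency_per_cpg(span, region)
  expect_equal(fr2$tfbs_frequency[fr2$cpg %in% 3:4], c(1, 2))
  expect_equal(sum(fr2$tfbs_frequency), sum(lengths(span$contained_cpgs)))

  expect_error(
    tfbs_frequency_per_cpg(fake_hits(list(1L), region_name = "other"), region),
    "other"
  )
})

test_that("the CpG report applies the candidate rule and validates labels", {
  vals <- rbind(c(20, 60, 60), c(30, 90, 90), c(25, 75, 80), c(15, 55, 65))
  idx <- relative_methylation_index(make_meth(vals))
  flags <- flag_critical_cpgs(idx)
  region <- promoter_region("r", "ACGTACGTACGT") # 3 CpGs
  fr <- tfbs_frequency_per_cpg(fake_hits(list(1L, 1L, 1L, 1L, 1L, 1L)), region)

  rep1 <- build_cpg_report(idx, flags, fr) # defaults: index < 1, freq >= 1
  expect_true(rep1$candidate[rep1$cpg == 1]) # low methylation + 6 hits
  expect_false(any(rep1$candidate[rep1$cpg != 1]))

  # a high-index CpG is never a candidate regardless of frequency
  fr_high <- fr; fr_high$tfbs_frequency <- c(0L, 9L, 9L)
  rep2 <- build_cpg_report(idx, flags, fr_high)
  expect_false(any(rep2$candidate[rep2$cpg %in% c(2, 3) &
                                    rep2$median_index >= 1]))

  # stricter frequency floor
  rep3 <- build_cpg_report(idx, flags, fr, candidate_freq_min = 7)
  expect_false(any(rep3$candidate))

  bad <- fr[fr$cpg != 2, ]
  expect_error(build_cpg_report(idx, flags, bad), "labels")
})

test_that("qMSP calling follows the strict background rule", {
  qm <- tibble::tibble(
    sample = c("C-", "s1", "s2", "s3", "s4"),
    group = c("C_minus", rep("case_tissue", 4)),
    ct_target = c(37, 37, 32, NA, 33),
    ct_reference = c(25, 25, 25, 25, NA),
    dct = compute_dct(ct_target, ct_reference)
  )
  calls <- call_qmsp(qm)
  got <- calls$calls$call
  expect_equal(got[calls$calls$sample == "s1"], "negative") # equals background
  expect_equal(got[calls$calls$sample == "s2"], "positive") # 5 below background
  expect_equal(got[calls$calls$sample == "s3"], "undetected")
  expect_equal(got[calls$calls$sample == "s4"], "invalid")

  # margin widens the background band
  expect_equal(
    call_qmsp(qm, margin = 6)$calls$call[calls$calls$sample == "s2"], "negative"
  )
  # inverted reading flips the rule
  inv <- call_qmsp(
    dplyr::mutate(qm, ct_target = c(30, 30, 36, NA, 33),
                  dct = compute_dct(ct_target, ct_reference)),
    invert_background_rule = TRUE
  )
  expect_equal(inv$calls$call[inv$calls$sample == "s2"], "positive")

  expect_error(call_qmsp(qm[-1, ]), "C_minus")
})

test_that("decreasing a sample's delta-Ct never flips positive to negative", {
  set.seed(6)
  base <- generate_qmsp_cohort(n_cases = 8, frac_methylated_cases = 0.5,
                               noise_sd = 1, seed = 6)$qmsp
  calls0 <- call_qmsp(base)$calls
  shifted <- dplyr::mutate(
    base, dct = ifelse(group == "case_tissue", dct - 2, dct)
  )
  calls1 <- call_qmsp(shifted)$calls
  was_pos <- calls0$sample[calls0$call == "positive"]
  expect_true(all(calls1$call[calls1$sample %in% was_pos] == "positive"))
})

test_that("cohort rates report fractions with Clopper-Pearson intervals", {
  qm <- generate_qmsp_cohort(
    n_cases = 12, frac_methylated_cases = 5 / 12, noise_sd = 0,
    case_group = "case_plasma", seed = 30
  )
  rates <- cohort_rates(call_qmsp(qm$qmsp))
  expect_equal(rates$rate, 5 / 12, tolerance = 1e-12)
  ci <- binom.test(5, 12)$conf.int
  expect_equal(rates$ci_low, ci[1])
  expect_equal(rates$ci_high, ci[2])

  zero <- generate_qmsp_cohort(n_cases = 6, frac_methylated_cases = 0,
                               noise_sd = 0, seed = 31)
  r0 <- cohort_rates(call_qmsp(zero$qmsp))
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)

  all_pos <- generate_qmsp_cohort(n_cases = 6, frac_methylated_cases = 1,
                                  noise_sd = 0, seed = 32)
  expect_equal(cohort_rates(call_qmsp(all_pos$qmsp))$rate, 1)

  expect_warning(cohort_rates(call_qmsp(qm$qmsp), groups = c("case_plasma", "ghost")),
                 "ghost")
})

test_that("qMSP tidiers and plots expose calls", {
  qm <- generate_qmsp_cohort(n_cases = 5, frac_methylated_cases = 0.6,
                             noise_sd = 0.2, seed = 33)
  calls <- call_qmsp(qm$qmsp)
  td <- tidy(calls)
  expect_equal(nrow(td), 5)
  expect_true(all(td$background_dct == calls$background_dct))
  gl <- glance(calls)
  expect_equal(gl$n_positive, sum(td$call == "positive"))
  expect_s3_class(plot_qmsp_calls(calls), "ggplot")
})

test_that("a single simulated study yields exactly the planted candidates", {
  st <- simulate_study(seed = 101)
  idx <- relative_methylation_index(st$panel$methylation)
  flags <- flag_critical_cpgs(idx)
  hits <- retain_cpg_overlapping(scan_sequence(st$pwms, st$region))
  fr <- tfbs_frequency_per_cpg(hits, st$region)
  report <- build_cpg_report(idx, flags, fr)
  expect_equal(report$cpg[report$candidate], st$truth$candidate_cpgs)
  # every planted candidate is covered by at least two motif occurrences
  expect_true(all(report$tfbs_frequency[report$candidate] >= 2))
  expect_s3_class(autoplot(report), "ggplot")
  expect_s3_class(plot_relative_index(idx), "ggplot")
})
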