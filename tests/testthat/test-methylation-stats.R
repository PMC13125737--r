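test_that("promoter means aggregate replicates and exclude missing pairwise", {
  m <- make_meth(matrix(c(80, 100, 120), 1))
  expect_equal(promoter_mean_methylation(m)$promoter_mean, 100)

  m_na <- make_meth(matrix(c(80, NA, 120), 1))
  expect_equal(promoter_mean_methylation(m_na)$promoter_mean, 100)

  m_all_na <- make_meth(matrix(c(NA_real_, NA_real_), 1))
  expect_error(promoter_mean_methylation(m_all_na), "all CpG values missing")
})

test_that("replicate aggregation uses the median and a dropout rule", {
  m <- tibble::tibble(
    sample = "s1", replicate = 1:3, cpg = 1L, percent = c(10, 20, 90)
  )
  expect_equal(aggregate_replicates(m)$percent, 20)
  expect_equal(aggregate_replicates(m, aggregate = "mean")$percent, 40)

  # 2 of 3 replicates missing -> cell reported missing
  m$percent <- c(10, NA, NA)
  expect_true(is.na(aggregate_replicates(m)$percent))
  m$percent <- c(10, 20, NA) # 1 of 3 missing -> median of the rest
  expect_equal(aggregate_replicates(m)$percent, 15)
})

test_that("relative index follows the ratio definition", {
  m <- make_meth(matrix(c(80, 100, 120), 1))
  idx <- relative_methylation_index(m)
  expect_equal(idx$index, c(0.8, 1.0, 1.2))

  flat <- make_meth(matrix(rep(37, 4), 1))
  expect_true(all(relative_methylation_index(flat)$index == 1))
})

test_that("per-sample mean of indices is 1 and indices are scale-invariant", {
  set.seed(42)
  for (i in 1:20) {
    vals <- matrix(runif(5 * 8, 1, 99), 5, 8)
    idx <- relative_methylation_index(make_meth(vals))
    per_sample <- tapply(idx$index, idx$sample, mean)
    expect_true(all(abs(per_sample - 1) < 1e-12))

    # multiplying one sample's values by c > 0 leaves its indices unchanged
    scaled <- vals
    scaled[2, ] <- scaled[2, ] * 0.37
    idx2 <- relative_methylation_index(make_meth(scaled))
    expect_equal(idx2$index[idx2$sample == "s02"],
                 idx$index[idx$sample == "s02"])
  }
})

test_that("planted multiplicative effects are recovered analytically", {
  effects <- rep(1, 10); effects[3] <- 1.5
  p <- generate_panel(
    n_samples = 8, n_cpgs = 10, cpg_effects = effects,
    line_means = seq(20, 55, length.out = 8), # stay clear of the 100% clip
    read_depth = 1e6, precision = Inf, seed = 8
  )
  idx <- relative_methylation_index(p$methylation)
  med3 <- median(idx$index[idx$cpg == 3])
  expect_equal(med3, 1.5 / mean(effects), tolerance = 0.05 / 1.4)
})

test_that("zero-denominator samples yield missing indices with a warning", {
  vals <- rbind(c(0, 0, 0), c(10, 20, 30))
  expect_warning(idx <- relative_methylation_index(make_meth(vals)), "mean is 0")
  expect_true(all(is.na(idx$index[idx$sample == "s01"])))
  expect_false(anyNA(idx$index[idx$sample == "s02"]))
})

test_that("critical-CpG flags: direction, exact p, and untestable CpGs", {
  # indices exactly 1 -> neutral
  flat <- relative_methylation_index(make_meth(matrix(50, 5, 4)))
  fl <- flag_critical_cpgs(flat)
  expect_true(all(fl$direction == "neutral"))

  # 12 samples, one CpG consistently at 1.5x: exact signed-rank p = 2/2^12
  vals <- matrix(50, 12, 5)
  vals[, 3] <- 90 # index at CpG 3 = 90/58 > 1 for every sample
  idx <- relative_methylation_index(make_meth(vals))
  fl2 <- flag_critical_cpgs(idx)
  expect_equal(fl2$direction[fl2$cpg == 3], "high")
  expect_equal(fl2$p[fl2$cpg == 3], 2 / 4096)
  # the other CpGs share index 50/58 < 1 in all 12 samples -> flagged low
  expect_true(all(fl2$direction[fl2$cpg != 3] == "low"))

  # fewer than 3 usable samples -> untestable (neutral, missing p)
  two <- relative_methylation_index(make_meth(matrix(c(10, 30, 20, 60), 2)))
  fl3 <- flag_critical_cpgs(two)
  expect_true(all(fl3$direction == "neutral"))
  expect_true(all(is.na(fl3$p)))
})

test_that("Mann-Whitney exact branch matches hand-derived cases", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1) # 2 of the 20 assignments are as extreme

  same <- mann_whitney(c(5, 9, 2), c(2, 9, 5))
  expect_equal(same$p, 1)
})

test_that("Mann-Whitney exact p equals enumeration for small groups", {
  set.seed(7)
  for (i in 1:120) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    a <- sample(0:5, na, replace = TRUE) # small support forces ties
    b <- sample(0:5, nb, replace = TRUE)
    expect_equal(mann_whitney(a, b)$p, oracle_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("group_compare dispatches and guards group counts", {
  v <- c(1, 2, 3, 4, 5, 6)
  g2 <- rep(c("x", "y"), each = 3)
  expect_equal(group_compare(v, g2)$p, 0.1)
  expect_error(group_compare(v, g2, test = "kruskal_wallis"), "mann_whitney")
  g3 <- rep(c("x", "y", "z"), each = 2)
  expect_error(group_compare(v, g3, test = "mann_whitney"), "kruskal_wallis")

  # identical constant groups: all ties, H = 0
  const <- group_compare(rep(7, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(const$statistic, 0)

  # wrapper agrees with stats::kruskal.test on untied data
  set.seed(1)
  vv <- rnorm(15); gg <- rep(letters[1:3], each = 5)
  kt <- kruskal.test(vv, factor(gg))
  res <- group_compare(vv, gg)
  expect_equal(res$statistic, unname(kt$statistic))
  expect_equal(res$p, kt$p.value)
})

test_that("demethylation contrast computes deltas and exact p-values", {
  veh <- make_meth(matrix(90, 1, 4))
  same <- demethylation_contrast(veh, veh)
  expect_true(all(same$methylation$delta == 0))

  # 3 treated vs 3 vehicle replicates, complete separation at every CpG
  treated <- tibble::tibble(
    sample = "A549", replicate = rep(1:3, each = 4),
    cpg = rep(1:4, 3), percent = 40
  )
  vehicle <- dplyr::mutate(treated, percent = 90)
  res <- demethylation_contrast(treated, vehicle)
  expect_true(all(res$methylation$delta == -50))
  expect_true(all(res$methylation$p == 0.1)) # 2/20 assignments for 3 vs 3

  t_expr <- tibble::tibble(sample = "A549", replicate = 1:3,
                           transcript = "t", dct = 10)
  v_expr <- dplyr::mutate(t_expr, dct = 15)
  res2 <- demethylation_contrast(treated, vehicle, t_expr, v_expr)
  expect_equal(res2$expression$ddct, -5) # re-expression

  mismatched <- dplyr::mutate(vehicle, cpg = cpg + 10)
  expect_error(demethylation_contrast(treated, mismatched), "mismatched CpG")
})
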