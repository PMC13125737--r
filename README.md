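# cpgsight

CpG-resolution analysis of promoter DNA methylation for multi-transcript
loci, in R. The package is written for labs that assay small promoter
regions by bisulfite pyrosequencing (percent methylation per CpG, in
replicates), measure transcript abundance by qPCR (delta-Ct), test clinical
material by quantitative methylation-specific PCR (qMSP), and want to ask:
*which individual CpG sites are locally hyper- or hypo-methylated, do they
sit inside predicted transcription-factor binding sites, and does promoter
methylation track expression?* The motivating system is the *RASSF1* locus,
whose promoters drive a tumor suppressor (*RASSF1A*), an oncogenic isoform
(*RASSF1C*) and an antisense lncRNA (*RASSF1-AS1*).

## What it computes

- **Relative methylation index** per CpG and sample:
  `I(s,c) = m(s,c) / mean_c m(s,c)` on replicate-aggregated (median)
  percent methylation — >1 is locally hyper-methylated, <1 locally
  hypo-methylated; the per-sample mean of indices is exactly 1.
- **Critical-CpG flags**: exact one-sample Wilcoxon signed-rank test of the
  index against 1 across the panel (ties handled exactly), direction from
  the median, BH q-values across CpGs.
- **Expression analysis**: delta-Ct tertile classification
  (`high: dCt <= q33`, `low: dCt >= q66`, type-7 quantiles; the published
  preset pair 9.083 / 15.308 ships as `rassf1_tertile_cutoffs`), Spearman
  correlation of promoter methylation vs delta-Ct (exact permutation p for
  n <= 9) with both orientations reported, and Euclidean / complete-linkage
  hierarchical clustering of raw delta-Ct profiles with Newick export.
- **PWM scanning** of promoter sequences against JASPAR-format count
  matrices: log-odds scores in bits (pseudocount 0.1), both strands, exact
  per-position p-values by dynamic programming on a 1000-bins-per-bit
  grid, retention of significant hits containing CpG dinucleotides, and a
  per-CpG TFBS frequency; candidate regulatory CpGs are low-index,
  high-frequency sites.
- **qMSP calling**: positive iff a sample's delta-Ct is strictly below the
  unmethylated-control (C−) background minus a configurable margin; rates
  per cohort with Clopper–Pearson intervals.
- **Synthetic data** for all of the above with known ground truth
  (beta-binomial pyrosequencing, methylation-coupled delta-Ct, promoters
  with planted CpG islands and motif consensi, qMSP cohorts with planted
  positives).

Everything takes and returns tibbles, pipes cleanly, and fitted objects
have `tidy()` / `glance()` / `autoplot()` methods.

## Worked example

A fully synthetic study with three planted candidate CpGs (low methylation,
inside motif cassettes) among 20 panel CpGs:

```r
library(cpgsight)
library(dplyr)

st    <- simulate_study(seed = 42)
idx   <- relative_methylation_index(st$panel$methylation)
flags <- flag_critical_cpgs(idx)
hits  <- retain_cpg_overlapping(scan_sequence(st$pwms, st$region))
report <- build_cpg_report(idx, flags, tfbs_frequency_per_cpg(hits, st$region))
filter(report, candidate)
#> # A tibble: 3 × 9
#>     cpg position mean_methylation_panel median_index direction        p       q
#>   <int>    <int>                  <dbl>        <dbl> <chr>        <dbl>   <dbl>
#> 1     3       55                   25.2        0.512 low       0.000488 0.00140
#> 2     9      151                   26.4        0.551 low       0.000488 0.00140
#> 3    15      247                   26.7        0.536 low       0.000488 0.00140
```

The three recovered sites are exactly the planted ones: their median index
sits near the planted 0.5 effect divided by the panel's mean effect, and
p = 2/4096 is the exact signed-rank p-value when all 12 samples deviate in
the same direction. The qMSP arm of the same study plants 7 methylated
cases among 13:

```r
calls <- call_qmsp(st$qmsp)
cohort_rates(calls)
#> # A tibble: 1 × 7
#>   group       n_valid n_positive  rate ci_low ci_high n_invalid
#>   <chr>         <int>      <int> <dbl>  <dbl>   <dbl>     <int>
#> 1 case_tissue      13          7 0.538  0.251   0.808         0
```

and methylation–expression coupling is summarized with both orientations
explicit (delta-Ct is inversely related to expression):

```r
m <- promoter_mean_methylation(st$panel$methylation)
j <- inner_join(m, st$panel$expression, by = "sample")
spearman_methylation_expression(j$promoter_mean, j$dct)
#> Spearman correlation (n = 12, t approximation)
#>   rho vs delta-Ct:    0.5455
#>   rho vs expression:  -0.5455
#>   two-sided p:        0.06661
```

`plot_relative_index(idx)`, `autoplot(report)` and
`plot_qmsp_calls(calls)` draw the standard views of these results.

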