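---
title: "CpG-resolution promoter methylation analysis with cpgsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CpG-resolution promoter methylation analysis with cpgsight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgsight)
```

## The problem

Promoters of multi-transcript loci — the motivating case is the *RASSF1*
locus, where the tumor suppressor *RASSF1A*, the oncogenic isoform
*RASSF1C*, and the antisense lncRNA *RASSF1-AS1* are driven by promoters
sharing two CpG islands — can be regulated CpG by CpG rather than by bulk
promoter methylation. Bisulfite pyrosequencing measures percent methylation
at each CpG of a small assayed region across a panel of cell lines or
samples; qPCR gives transcript abundance as delta-Ct (lower delta-Ct =
higher expression); qMSP detects promoter methylation in clinical material
against fully methylated (C+) and unmethylated (C−) DNA controls. cpgsight
implements the analysis that connects these assays:

1. a **relative methylation index** per CpG: its percent methylation divided
   by the mean promoter methylation of the same sample, so >1 means locally
   hyper-methylated and <1 locally hypo-methylated regardless of the
   sample's overall methylation level;
2. **critical-CpG flagging**: a per-CpG test of whether the index deviates
   from 1 across the panel;
3. **expression analysis**: delta-Ct tertile classification, Spearman
   correlation of promoter methylation with delta-Ct, and unsupervised
   hierarchical clustering of transcript profiles;
4. a **PWM scanner** over the assayed promoter sequences with exact
   p-values, retaining transcription-factor binding sites (TFBS) that
   contain CpG dinucleotides, and a per-CpG TFBS frequency;
5. **qMSP calling** against the unmethylated-control background, with
   per-cohort detection rates;
6. a **synthetic-data generator** that emulates all three assays with known
   ground truth, so every stage is testable without access to the original
   measurements (which are not published as data).

## The relative index and its arithmetic identity

For sample $s$ with replicate-aggregated methylation $m_{s,c}$ at CpG $c$,

$$ I_{s,c} = \frac{m_{s,c}}{\bar m_s}, \qquad
   \bar m_s = \frac{1}{|C|}\sum_{c \in C} m_{s,c}. $$

Replicates are collapsed by the **median** before anything else (the mean is
available via `aggregate = "mean"`); the denominator uses the same
aggregated values over the same CpG set as the numerator. That choice makes
the identity $\frac{1}{|C|}\sum_c I_{s,c} = 1$ exact (to floating point) on
complete data, which the tests assert at $10^{-12}$, and it makes indices
invariant to rescaling a sample's values — the property that lets indices
be compared across samples with very different absolute methylation.
Missing values (pyrosequencing dropouts) are excluded pairwise; a cell
missing in more than half of its replicates is reported missing; a sample
with promoter mean 0 gets missing indices rather than infinities.

```{r index}
panel <- generate_panel(n_samples = 6, n_cpgs = 9, seed = 1)
idx <- relative_methylation_index(panel$methylation)
head(idx, 3)
```

## Critical-CpG flagging

The reference analysis marks per-CpG significance without naming the test
at that level, so the package's choice is documented as an interpretation:
for each CpG, a **two-sided one-sample Wilcoxon signed-rank test** of the
index against 1 across samples, with direction from the median index and
`neutral` whenever the raw p-value is at or above `alpha` (default 0.05).
Benjamini–Hochberg q-values across the CpGs of a region are reported
alongside. This is consistent with the locus analysis' otherwise strictly
non-parametric toolkit (Mann–Whitney for two groups, Kruskal–Wallis for
three or more, Spearman for correlation).

Two numerical points matter. First, replicated percent data tie constantly,
and the standard implementation abandons exactness under ties; the package
therefore computes the exact null distribution by convolution over signed
midranks (and, for the two-sample test, by full enumeration of group
assignments up to group size 8), falling back to tie-corrected normal
approximations only beyond those sizes. Second, because the indices of a
sample average to 1 by construction, planting *high* CpGs necessarily
pushes every other CpG's expected index *below* 1: any calibration of
flagging performance must therefore be direction-aware. The recovery
properties in the test suite count a planted ×1.5 CpG as found only when it
is flagged `high`, and a false flag as a non-planted CpG flagged `high`.

## Expression: tertiles, correlation, clustering

Tertile cutoffs are the 33rd and 66th percentiles of the pooled delta-Ct
distribution, computed with linear interpolation between order statistics
($h = (n-1)p + 1$, R's default type-7 quantile). The cell-line panel the
package accompanies used the constants 9.083 and 15.308; their generating
delta-Ct distribution is unpublished, so the pair ships as the opaque
preset `rassf1_tertile_cutoffs`, with the quoted inclusive boundary
semantics: high iff $\Delta Ct \le 9.083$, low iff $\Delta Ct \ge 15.308$.

Correlation is Spearman with midranks, exact permutation p-values up to
$n = 9$ and the t-approximation beyond. Every result carries both
`rho_vs_dct` and `rho_vs_expression = -rho_vs_dct`: delta-Ct is inversely
related to abundance, and reporting both signs avoids the recurring
ambiguity of "positive r, negative correlation with expression".

Clustering is agglomerative with **Euclidean distance and complete
linkage** on raw delta-Ct values (no per-gene transformation), cut at a
requested `k`; complete linkage is monotone, so merge heights never
decrease (asserted in the tests). The tree serializes to Newick via `ape`
rather than to a heatmap, which is out of scope.

## The PWM scanner

The scanner replaces an external FIMO stage with an in-package
implementation so that the pipeline is self-contained and its significance
criterion explicit:

* `probs[b,j] = (counts[b,j] + 0.1 * background[b]) / (total_j + 0.1)` —
  pseudocount 0.1 distributed by background, uniform background by default;
* scores are log-odds in bits, summed over motif columns; both strands are
  scored, the minus strand against the reverse-complemented matrix, and
  reported in plus-strand coordinates;
* the per-position p-value is $\Pr(\text{score} \ge t)$ for a random
  background word, computed **exactly by dynamic programming** on an
  integer grid of 1000 bins per bit. The grid is the only source of
  discretization error, and the tests verify the DP against exhaustive
  $4^w$ word enumeration;
* hits with $p \le 10^{-4}$ (configurable, recorded in outputs) are kept,
  and the retention rule keeps only hits overlapping CpG dinucleotides.
  The default requires the **full dinucleotide inside the hit interval**
  ("directly containing"); `overlap = "any"` relaxes to one base. The
  per-CpG **TFBS frequency** counts retained hits containing each CpG,
  with overlapping and duplicate occurrences all counted.

The integrated per-CpG report joins indices, flags and frequencies, and
marks **candidate regulatory CpGs**: median index below
`candidate_index_max` (default 1.0) and TFBS frequency at least
`candidate_freq_min` (default 1) — the "low methylation, high TFBS
frequency" pattern. Both thresholds are explicit configuration because the
reference description of the pattern is qualitative.

## qMSP calling

qMSP delta-Ct is oriented so that lower values mean a stronger methylation
signal. The calling rule is anchored to the unmethylated control: a sample
is **positive iff its delta-Ct is strictly below the C− control's delta-Ct
minus a guard margin** (default 0; the margin exists because baseline
technical variation around the background is documented but not
quantified). Values at or weaker than background are negative; a sample
whose methylation-specific amplicon does not amplify but whose input-DNA
control is valid is `undetected` (counted negative); samples without a
valid input control are excluded from rates. The published figure caption
for this assay states the opposite inequality while simultaneously stating
the delta-Ct orientation that contradicts it; the package follows the
orientation-consistent body-text reading and exposes
`invert_background_rule` for the literal caption reading rather than
deciding silently. Detection rates come with Clopper–Pearson 95% intervals.

## What the generator emulates — and what it does not

`generate_panel()` draws, per (sample, replicate, CpG), a true proportion
`clip(line_mean * cpg_effect, 0, 100)/100`, overdisperses it with a Beta
distribution of precision 100 (replicate-to-replicate spread of a few
percentage points at intermediate methylation, typical of pyrosequencing;
`Inf` disables it), and observes `100 * Binomial(depth, q) / depth` at
depth 500 by default. Expression is coupled linearly:
`dct = 4 + 0.12 * true_promoter_mean + N(0, 2.9)`. With promoter means
spread uniformly over 10–90%, these defaults imply a population Spearman of
≈ 0.70 against delta-Ct (`coupling_rho()` evaluates it by Monte Carlo) —
the magnitude of the correlations the pipeline is expected to recover.
A positive slope means methylation correlates *positively* with delta-Ct,
i.e. *negatively* with expression; this sign convention is deliberate and
matches how such panels report "negative correlation" with positive r
values on the delta-Ct scale. The default panel shape is 13 samples × 3
replicates, matching the assayed panel, with CpG counts 9/20/22 as the
assayed regions' presets.

`generate_promoter()` writes islands as CpG-rich fills that satisfy the
island criterion and plants motif consensi (reverse-complemented on the
minus strand); `generate_qmsp_cohort()` plants exactly
`round(frac * n)` methylated samples at `background - effect_dct`, with
unmethylated samples never below background, so a noise-free cohort of 13
with 7 planted signals yields a detection rate of 7/13 by construction —
mirroring, not reproducing, the published 54% (7/13) tissue and 42% (5/12)
plasma rates.

`simulate_study()` builds the fully controlled end-to-end fixture: a
CpG-free background sequence with bare CpG insertions at neutral panel
sites and motif cassettes at candidate sites, so the panel's CpG list is
exactly known. Because planted motif occurrences may not overlap one
another, "at least two occurrences per candidate CpG" is realized by
scanning two distinct PWMs that share the cassette consensus — one
physical insertion, two retained hits.

What passing these synthetic checks does **not** show: the generator's
binomial/Beta model has no bisulfite conversion failure, no PCR bias, no
spatially correlated methylation along the region, and its expression noise
is Gaussian on the delta-Ct scale; real panels may violate any of these.
The published headline numbers (Spearman 0.643/0.678, the five cluster
memberships, TFBS counts 5/39/28) depend on unpublished panel data, exact
promoter sequences and a versioned motif database, and are therefore not
desk-reproducible; the pipeline's validation is property-based recovery of
planted truth instead.

## CpG islands

The conventional verbal definition (≥200 nt, elevated GC, elevated CpG
observed/expected) is not operational as stated; `find_cpg_islands()`
implements the standard sliding-window rule — every 200-nt window with GC
fraction ≥ 0.5 and observed/expected CpG ratio ≥ 0.6 marks its positions,
marked positions merge, and merged runs of at least 200 nt are reported.
All four thresholds are arguments; a stricter GC ≥ 0.6 reading is one
argument away. Observed/expected uses the Gardiner-Garden form
`n_CpG / (n_C * n_G / window)`. The implementation is verified against a
brute-force all-windows oracle.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; 1-based CpG labels appear
  only in reports.
* Quantile type 7 for tertiles; median for replicate aggregation.
* Two-sided p-values for the exact tests are deviation-based
  ($\Pr(|T - E T| \ge |t - E T|)$ under the permutation null), which is the
  definition that returns 1 for identical groups and matches enumeration
  under ties; the large-sample Mann–Whitney branch uses the tie-corrected
  normal approximation without continuity correction.
* PWM score grid: 1000 bins per bit; thresholds map to the grid by
  rounding, with $p = 1$ guaranteed at or below the minimum score.
* Fewer than 3 usable samples makes a CpG untestable (neutral, missing p);
  fewer than 3 complete pairs is an error for correlation; missing
  delta-Ct cells are an error for clustering (no silent imputation).
* Problem sizes in the validation suite (100 panels of 12 × 20 × 3 for flag
  recovery, 200 panels for correlation recovery, 100 seeds for clustering
  and end-to-end recovery, enumeration up to width 6 / group size 4) were
  chosen to make the Monte-Carlo acceptance bands tight while keeping the
  whole suite around a minute of compute.

## Known limitations

* The scanner's background model is 0-order i.i.d.; no Markov background,
  no q-value $\pi_0$ estimation (plain Benjamini–Hochberg only).
* No DMR calling, array (450K) parsing, raw-trace alignment, or motif
  discovery; motif files and promoter sequences are user- or
  simulator-supplied.
* `demethylation_contrast()` treats replicates as exchangeable units within
  condition; with 3 vs 3 replicates the smallest attainable two-sided exact
  p is 0.1, so "significance" at conventional levels needs more replicates
  — a property of the design, not the implementation.
* The qMSP margin default of 0 is deliberately conservative; cohorts with
  appreciable baseline drift should set a positive margin or calibrate one
  from repeated C− measurements.
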