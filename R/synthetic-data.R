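# Synthetic pyrosequencing / qPCR / qMSP data with known ground truth.
# The generator defines the study conditions every downstream stage is
# validated against: a cell-line panel with line-specific promoter
# methylation, planted over/under-methylated CpGs, delta-Ct expression
# monotonically coupled to promoter methylation, promoter sequences with
# planted CpG islands and motif occurrences, and qMSP cohorts with an
# unmethylated background control.

#' Monte-Carlo implied Spearman of the methylation--delta-Ct coupling
#'
#' The population rank correlation implied by the linear coupling
#' `dct = intercept + slope * methylation + N(0, noise_sd)` when promoter
#' means are uniform on `[mean_min, mean_max]`.
#'
#' @param slope,noise_sd Coupling parameters (delta-Ct per percent; delta-Ct).
#' @param mean_min,mean_max Range of promoter mean methylation (percent).
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed for the evaluation.
#' @return The implied Spearman rho (against delta-Ct).
#' @export
coupling_rho <- function(slope, noise_sd, mean_min = 10, mean_max = 90,
                         n_mc = 1e5, seed = 1L) {
  withr::with_seed(seed, {
    x <- stats::runif(n_mc, mean_min, mean_max)
    y <- slope * x + stats::rnorm(n_mc, 0, noise_sd)
    stats::cor(x, y, method = "spearman")
  })
}

#' Simulate a cell-line methylation + expression panel
#'
#' Emulates replicated bisulfite pyrosequencing and qPCR over a cell-line
#' panel. For each (sample, replicate, CpG) the true methylation proportion
#' is `clip(line_mean * cpg_effect, 0, 100) / 100`; a Beta draw with
#' precision `precision` adds replicate overdispersion (`Inf` disables it),
#' and the observed percentage is `100 * Binomial(read_depth, q) /
#' read_depth`. Per sample, `dct = coupling_intercept + coupling_slope *
#' true_promoter_mean + N(0, coupling_noise_sd)`: a positive slope couples
#' methylation positively with delta-Ct, i.e. negatively with expression.
#'
#' Defaults mirror the assayed panel's shape: 13 cell lines, 3 biological
#' replicates, promoter means spread over 15-90 percent, and coupling
#' parameters whose implied population Spearman (vs delta-Ct) is about 0.7
#' (see [coupling_rho()]).
#'
#' @param n_samples,n_cpgs,n_replicates Panel dimensions (>= 3, >= 2, >= 1).
#' @param line_means Per-sample promoter mean methylation (percent); default
#'   an even spread over 15-90.
#' @param cpg_effects Per-CpG multiplicative effect (1 neutral, > 1 planted
#'   high, < 1 planted low); default all 1.
#' @param read_depth Pyrosequencing depth per CpG per replicate.
#' @param precision Beta overdispersion precision (Inf = none).
#' @param coupling_intercept,coupling_slope,coupling_noise_sd Expression
#'   coupling (delta-Ct units).
#' @param transcript Transcript name used in the expression table.
#' @param seed RNG seed; identical seeds reproduce identical output.
#' @return List with `methylation` (long tibble `sample`, `replicate`,
#'   `cpg`, `percent`), `expression` (tibble `sample`, `replicate`,
#'   `transcript`, `dct`), and `truth` (list with `line_means`,
#'   `cpg_effects`, `true_promoter_means`, coupling parameters, and
#'   `planted_rho`, the Monte-Carlo implied coupling Spearman).
#' @export
generate_panel <- function(n_samples = 13, n_cpgs = 20, n_replicates = 3,
                           line_means = NULL, cpg_effects = NULL,
                           read_depth = 500, precision = 100,
                           coupling_intercept = 4, coupling_slope = 0.12,
                           coupling_noise_sd = 2.9,
                           transcript = "target", seed = NULL) {
  stopifnot(n_samples >= 3, n_cpgs >= 2, n_replicates >= 1, read_depth >= 1)
  if (is.null(line_means)) line_means <- seq(15, 90, length.out = n_samples)
  if (is.null(cpg_effects)) cpg_effects <- rep(1, n_cpgs)
  if (length(line_means) != n_samples) {
    stop("line_means must have length n_samples", call. = FALSE)
  }
  if (length(cpg_effects) != n_cpgs) {
    stop("cpg_effects must have length n_cpgs", call. = FALSE)
  }
  if (any(cpg_effects <= 0)) stop("cpg_effects must be positive", call. = FALSE)

  samples <- sprintf("line%02d", seq_len(n_samples))
  run <- function() {
    grid <- tidyr::expand_grid(
      sample_i = seq_len(n_samples),
      replicate = seq_len(n_replicates),
      cpg = seq_len(n_cpgs)
    )
    true_pct <- pmin(pmax(line_means[grid$sample_i] * cpg_effects[grid$cpg], 0), 100)
    prop <- true_pct / 100
    q <- if (is.finite(precision)) {
      # Beta(precision * p, precision * (1 - p)); degenerate at 0/1 kept fixed
      inner <- prop > 0 & prop < 1
      out <- prop
      out[inner] <- stats::rbeta(
        sum(inner), precision * prop[inner], precision * (1 - prop[inner])
      )
      out
    } else {
      prop
    }
    observed <- 100 * stats::rbinom(nrow(grid), read_depth, q) / read_depth
    meth <- tibble::tibble(
      sample = samples[grid$sample_i],
      replicate = as.integer(grid$replicate),
      cpg = as.integer(grid$cpg),
      percent = observed
    )
    true_means <- vapply(
      seq_len(n_samples),
      function(i) mean(pmin(pmax(line_means[i] * cpg_effects, 0), 100)),
      numeric(1)
    )
    dct_sample <- coupling_intercept + coupling_slope * true_means +
      stats::rnorm(n_samples, 0, coupling_noise_sd)
    expr <- tibble::tibble(
      sample = samples,
      replicate = 1L,
      transcript = transcript,
      dct = dct_sample
    )
    list(meth = meth, expr = expr, true_means = true_means)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  list(
    methylation = res$meth,
    expression = res$expr,
    truth = list(
      line_means = stats::setNames(line_means, samples),
      cpg_effects = cpg_effects,
      true_promoter_means = stats::setNames(res$true_means, samples),
      read_depth = read_depth,
      precision = precision,
      coupling_intercept = coupling_intercept,
      coupling_slope = coupling_slope,
      coupling_noise_sd = coupling_noise_sd,
      planted_rho = coupling_rho(
        coupling_slope, coupling_noise_sd,
        min(line_means), max(line_means),
        n_mc = 2e4, seed = 7L
      ),
      seed = seed
    )
  )
}

# sample a random DNA string; when avoid_cpg, G is never placed right after C
random_dna <- function(length,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       avoid_cpg = FALSE) {
  if (!avoid_cpg) {
    return(paste(sample(BASES, length, replace = TRUE, prob = base_probs),
                 collapse = ""))
  }
  out <- character(length)
  no_g <- base_probs
  no_g["G"] <- 0
  prev_c <- FALSE
  for (i in seq_len(length)) {
    p <- if (prev_c) no_g else base_probs
    out[i] <- sample(BASES, 1, prob = p)
    prev_c <- out[i] == "C"
  }
  paste(out, collapse = "")
}

# CpG-rich island fill satisfying the default island criterion comfortably:
# ~70% CG dinucleotide units, remainder random AT-leaning pairs
island_fill <- function(length) {
  n_units <- ceiling(length / 2)
  units <- ifelse(
    stats::runif(n_units) < 0.7, "CG",
    paste0(sample(c("A", "T", "C", "G"), n_units, replace = TRUE),
           sample(c("A", "T"), n_units, replace = TRUE))
  )
  substr(paste(units, collapse = ""), 1, length)
}

#' Simulate a promoter sequence with planted islands and motif occurrences
#'
#' Draws a background sequence from a stated base composition, rewrites each
#' island span with CpG-rich sequence satisfying the default island
#' criterion, and writes the consensus of each planted motif at its start
#' (reverse complement for minus-strand plants). Planted hits must not
#' overlap one another.
#'
#' @param length Sequence length (nt).
#' @param islands Optional tibble/data frame with `start`, `end` (0-based,
#'   half-open) spans to rewrite as CpG islands.
#' @param motifs Named list of [pfm_to_pwm()] objects for the planted hits.
#' @param planted_hits Optional tibble with `motif_id`, `start` (0-based),
#'   `strand`.
#' @param base_probs Background base composition (A, C, G, T).
#' @param avoid_background_cpg Suppress CpG dinucleotides in the background
#'   (used when the CpG panel must consist of planted sites only).
#' @param name Region name.
#' @param seed RNG seed.
#' @return List with `region` ([promoter_region()]) and `truth` (list:
#'   `island_intervals`, `planted_hits` with inserted sequences,
#'   `cpg_positions`).
#' @export
generate_promoter <- function(length = 300, islands = NULL, motifs = NULL,
                              planted_hits = NULL,
                              base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                              avoid_background_cpg = FALSE,
                              name = "promoter", seed = NULL) {
  build <- function() {
    seq_chr <- random_dna(length, base_probs, avoid_cpg = avoid_background_cpg)
    if (!is.null(islands)) {
      for (i in seq_len(nrow(islands))) {
        s <- islands$start[i]; e <- islands$end[i]
        stopifnot(s >= 0, e <= length, e > s)
        substr(seq_chr, s + 1, e) <- island_fill(e - s)
      }
    }
    planted <- NULL
    if (!is.null(planted_hits) && nrow(planted_hits) > 0) {
      ph <- planted_hits
      widths <- vapply(ph$motif_id, function(id) motifs[[id]]$width, numeric(1))
      ends <- ph$start + widths
      ord <- order(ph$start)
      if (any(ph$start[ord][-1] < ends[ord][-length(ord)])) {
        stop("planted hits overlap", call. = FALSE)
      }
      if (any(ph$start < 0) || any(ends > length)) {
        stop("planted hits out of sequence bounds", call. = FALSE)
      }
      ins <- character(nrow(ph))
      for (i in seq_len(nrow(ph))) {
        cons <- motifs[[ph$motif_id[i]]]$consensus
        ins[i] <- if (ph$strand[i] == "-") reverse_complement(cons) else cons
        substr(seq_chr, ph$start[i] + 1, ends[i]) <- ins[i]
      }
      planted <- tibble::tibble(
        motif_id = ph$motif_id, start = as.integer(ph$start),
        end = as.integer(ends), strand = ph$strand, inserted = ins
      )
    }
    list(seq_chr = seq_chr, planted = planted)
  }
  res <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  region <- promoter_region(name, res$seq_chr)
  list(
    region = region,
    truth = list(
      island_intervals = if (is.null(islands)) {
        tibble::tibble(start = integer(0), end = integer(0))
      } else {
        tibble::as_tibble(islands)
      },
      planted_hits = res$planted,
      cpg_positions = region$cpg_positions
    )
  )
}

#' Simulate a qMSP cohort with a background control
#'
#' Builds a quantitative methylation-specific PCR table: a fully methylated
#' control (`C_plus`), the unmethylated background control (`C_minus`, fixed
#' at `background_dct`), and case/control samples. Truly methylated samples
#' get `dct = background_dct - effect_dct + N(0, noise_sd)` (signal above
#' background, since lower delta-Ct means more methylation signal); truly
#' unmethylated samples sit at `background_dct + |N(0, noise_sd)|`, never
#' below background. The number of methylated cases is
#' `round(frac_methylated_cases * n_cases)` exactly, so construction
#' determines the detection rate at zero noise.
#'
#' @param n_cases,n_controls Cohort sizes (at least one must be positive).
#' @param frac_methylated_cases,frac_methylated_controls Fractions in
#'   \[0, 1\] of truly methylated samples per arm.
#' @param background_dct delta-Ct of the unmethylated control.
#' @param effect_dct Positive delta-Ct separation of methylated samples.
#' @param noise_sd delta-Ct noise.
#' @param case_group,control_group Group labels for the two arms.
#' @param ct_reference Input-DNA control Ct assigned to every sample.
#' @param seed RNG seed.
#' @return List with `qmsp` (tibble `sample`, `group`, `ct_target`,
#'   `ct_reference`, `dct`) and `truth` (tibble `sample`, `methylated`).
#' @export
generate_qmsp_cohort <- function(n_cases = 13, n_controls = 0,
                                 frac_methylated_cases = 7 / 13,
                                 frac_methylated_controls = 0,
                                 background_dct = 12, effect_dct = 5,
                                 noise_sd = 0.5,
                                 case_group = "case_tissue",
                                 control_group = "control_smoker",
                                 ct_reference = 25, seed = NULL) {
  if (n_cases == 0 && n_controls == 0) {
    stop("cohort must contain at least one sample", call. = FALSE)
  }
  stopifnot(
    frac_methylated_cases >= 0, frac_methylated_cases <= 1,
    frac_methylated_controls >= 0, frac_methylated_controls <= 1,
    effect_dct > 0, noise_sd >= 0
  )
  build <- function() {
    arm <- function(n, frac, group, prefix) {
      if (n == 0) return(NULL)
      k <- round(frac * n)
      methylated <- sample(rep(c(TRUE, FALSE), c(k, n - k)))
      dct <- ifelse(
        methylated,
        background_dct - effect_dct + stats::rnorm(n, 0, noise_sd),
        background_dct + abs(stats::rnorm(n, 0, noise_sd))
      )
      tibble::tibble(
        sample = sprintf("%s%02d", prefix, seq_len(n)),
        group = group, dct = dct, methylated = methylated
      )
    }
    dplyr::bind_rows(
      arm(n_cases, frac_methylated_cases, case_group, "case"),
      arm(n_controls, frac_methylated_controls, control_group, "ctrl")
    )
  }
  body <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  controls <- tibble::tibble(
    sample = c("C_plus", "C_minus"),
    group = c("C_plus", "C_minus"),
    dct = c(background_dct - 2 * effect_dct, background_dct),
    methylated = c(TRUE, FALSE)
  )
  all <- dplyr::bind_rows(controls, body)
  qmsp <- tibble::tibble(
    sample = all$sample,
    group = all$group,
    ct_target = all$dct + ct_reference,
    ct_reference = ct_reference,
    dct = all$dct
  )
  list(qmsp = qmsp, truth = all[c("sample", "methylated")])
}

#' Simulate per-cluster expression archetypes
#'
#' Draws sample delta-Ct profiles around planted archetype centroids with
#' isotropic Gaussian noise — the ground truth for validating hierarchical
#' clustering of transcript profiles.
#'
#' @param centroids k x t matrix of delta-Ct centroids (rows = archetypes,
#'   columns = transcripts).
#' @param n_per_cluster Samples per archetype (scalar or length-k vector).
#' @param noise_sd Within-cluster delta-Ct standard deviation.
#' @param seed RNG seed.
#' @return List with `dct` (wide tibble, `sample` + one column per
#'   transcript) and `truth` (tibble `sample`, `cluster`).
#' @export
generate_expression_archetypes <- function(centroids, n_per_cluster = 3,
                                           noise_sd = 0.5, seed = NULL) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  sizes <- rep_len(n_per_cluster, k)
  build <- function() {
    rows <- purrr::map_dfr(seq_len(k), function(ci) {
      m <- matrix(
        stats::rnorm(sizes[ci] * ncol(centroids), 0, noise_sd),
        nrow = sizes[ci]
      )
      m <- sweep(m, 2, centroids[ci, ], "+")
      out <- tibble::as_tibble(m, .name_repair = "minimal")
      names(out) <- colnames(centroids) %||%
        paste0("transcript", seq_len(ncol(centroids)))
      out$cluster <- ci
      out
    })
    rows$sample <- sprintf("s%02d", seq_len(nrow(rows)))
    rows
  }
  rows <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  list(
    dct = rows[c("sample", setdiff(names(rows), c("sample", "cluster")))],
    truth = rows[c("sample", "cluster")]
  )
}

#' Simulate a full coherent study
#'
#' Generates a promoter whose CpG panel is fully controlled (a CpG-free
#' background with bare CpG insertions at neutral panel sites and
#' motif-consensus cassettes containing the CpG at the planted candidate
#' sites), a methylation + expression panel whose planted low-methylation
#' CpGs are exactly the cassette CpGs, a motif set in which two distinct
#' PWMs share each cassette consensus (so every candidate CpG lies inside
#' at least two retained motif occurrences), and a qMSP cohort. The
#' downstream candidate set is therefore determined by construction.
#'
#' @param n_cpgs Panel size (number of CpG sites).
#' @param candidate_cpgs 1-based indices of the planted low-methylation,
#'   motif-bearing CpGs.
#' @param low_effect Multiplicative effect at candidate CpGs (< 1).
#' @param n_samples,n_replicates,read_depth,precision Panel parameters
#'   passed to [generate_panel()].
#' @param out_dir Optional directory: writes `methylation.tsv`,
#'   `expression.tsv`, `promoter.fasta`, `motifs.jaspar`, `qmsp.tsv`,
#'   `truth.json`.
#' @param seed RNG seed driving every stage.
#' @return List with `region`, `pwms`, `panel`, `qmsp`, `truth`.
#' @export
simulate_study <- function(n_cpgs = 20, candidate_cpgs = c(3, 9, 15),
                           low_effect = 0.5, n_samples = 12,
                           n_replicates = 3, read_depth = 500,
                           precision = 100, out_dir = NULL, seed = 1L) {
  stopifnot(all(candidate_cpgs >= 1), all(candidate_cpgs <= n_cpgs))
  # Cassette: consensus with one CpG at offset 3 (0-based), no other CpG
  cassette <- "TTACGTAA"
  counts <- matrix(1, 4, nchar(cassette), dimnames = list(BASES, NULL))
  idx <- match(strsplit(cassette, "")[[1]], BASES)
  counts[cbind(idx, seq_along(idx))] <- 97
  pwm_a <- pfm_to_pwm(list(motif_id = "SYN1", motif_name = "synthA", counts = counts))
  counts_b <- counts
  counts_b[cbind(idx, seq_along(idx))] <- 85 # same consensus, softer matrix
  counts_b[counts_b == 1] <- 5
  pwm_b <- pfm_to_pwm(list(motif_id = "SYN2", motif_name = "synthB", counts = counts_b))
  pwms <- list(SYN1 = pwm_a, SYN2 = pwm_b)

  spacing <- 16L
  margin <- 20L
  length_total <- margin * 2L + spacing * n_cpgs
  site_anchor <- margin + spacing * (seq_len(n_cpgs) - 1L) # cassette/CpG slot
  is_candidate <- seq_len(n_cpgs) %in% candidate_cpgs

  build_seq <- function() {
    seq_chr <- random_dna(length_total, avoid_cpg = TRUE)
    for (i in seq_len(n_cpgs)) {
      if (is_candidate[i]) {
        substr(seq_chr, site_anchor[i] + 1, site_anchor[i] + nchar(cassette)) <-
          cassette
      } else {
        substr(seq_chr, site_anchor[i] + 1, site_anchor[i] + 2) <- "CG"
      }
    }
    seq_chr
  }
  seq_chr <- withr::with_seed(seed, build_seq())
  region <- promoter_region("synthetic_promoter", seq_chr)
  cpg_pos_expected <- as.integer(site_anchor + ifelse(is_candidate, 3L, 0L))
  stopifnot(identical(region$cpg_positions, cpg_pos_expected))

  effects <- rep(1, n_cpgs)
  effects[candidate_cpgs] <- low_effect
  panel <- generate_panel(
    n_samples = n_samples, n_cpgs = n_cpgs, n_replicates = n_replicates,
    cpg_effects = effects, read_depth = read_depth, precision = precision,
    line_means = seq(20, 85, length.out = n_samples),
    seed = seed + 1L
  )
  qmsp <- generate_qmsp_cohort(seed = seed + 2L)

  truth <- list(
    candidate_cpgs = as.integer(candidate_cpgs),
    low_effect = low_effect,
    cpg_positions = region$cpg_positions,
    cassette = cassette,
    panel = panel$truth,
    qmsp = qmsp$truth
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_methylation_table(panel$methylation, file.path(out_dir, "methylation.tsv"))
    expr_wide <- tidyr::pivot_wider(
      panel$expression, id_cols = c("sample", "replicate"),
      names_from = "transcript", values_from = "dct"
    )
    readr::write_tsv(expr_wide, file.path(out_dir, "expression.tsv"), progress = FALSE)
    write_promoter_fasta(region, file.path(out_dir, "promoter.fasta"))
    writeLines(
      unlist(purrr::map(pwms, function(p) {
        c(paste0(">", p$motif_id, " ", p$motif_name),
          vapply(1:4, function(b) {
            paste0(BASES[b], " [ ",
                   paste(round(p$probs[b, ] * 100), collapse = " "), " ]")
          }, character(1)))
      })),
      file.path(out_dir, "motifs.jaspar")
    )
    readr::write_tsv(
      qmsp$qmsp[c("sample", "group", "ct_target", "ct_reference")],
      file.path(out_dir, "qmsp.tsv"), na = "NA", progress = FALSE
    )
    jsonlite::write_json(
      truth, file.path(out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(region = region, pwms = pwms, panel = panel, qmsp = qmsp$qmsp, truth = truth)
}
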