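#' TFBS frequency per CpG site
#'
#' For each CpG of a region, counts the retained motif hits whose contained
#' CpG set includes it (per-occurrence counting: a hit spanning several CpGs
#' increments each of them, and overlapping or duplicate hits all count).
#' CpGs with no hits report 0.
#'
#' @param hits Retained hit tibble ([retain_cpg_overlapping()]).
#' @param region The [promoter_region()] the hits refer to.
#' @return Tibble with `cpg` (1-based label), `position` (0-based C
#'   position), `tfbs_frequency`.
#' @export
tfbs_frequency_per_cpg <- function(hits, region) {
  stopifnot(inherits(region, "promoter_region"))
  if (nrow(hits) > 0 && any(hits$region != region$name)) {
    stop(
      "hits reference region(s) ",
      paste(unique(setdiff(hits$region, region$name)), collapse = ", "),
      " but '", region$name, "' was supplied",
      call. = FALSE
    )
  }
  n <- length(region$cpg_positions)
  counts <- tabulate(as.integer(unlist(hits$contained_cpgs)), nbins = n)
  tibble::tibble(
    cpg = seq_len(n),
    position = region$cpg_positions,
    tfbs_frequency = as.integer(counts)
  )
}

#' Integrated per-CpG report
#'
#' Joins the relative-index summary, the criticality flags and the TFBS
#' frequencies into one row per CpG, and marks candidate regulatory CpGs:
#' sites whose median relative index is below `candidate_index_max` (locally
#' under-methylated) and whose TFBS frequency is at least
#' `candidate_freq_min` — the pattern of low-methylation CpGs enriched for
#' predicted binding sites.
#'
#' @param index_tbl Output of [relative_methylation_index()].
#' @param flags Output of [flag_critical_cpgs()].
#' @param frequencies Output of [tfbs_frequency_per_cpg()].
#' @param candidate_index_max Median-index ceiling for candidates.
#' @param candidate_freq_min Minimum TFBS frequency for candidates.
#' @return Tibble of class `cpg_report` with columns `cpg`, `position`,
#'   `mean_methylation_panel`, `median_index`, `direction`, `p`, `q`,
#'   `tfbs_frequency`, `candidate`.
#' @export
build_cpg_report <- function(index_tbl, flags, frequencies,
                             candidate_index_max = 1.0,
                             candidate_freq_min = 1L) {
  lab_i <- sort(unique(index_tbl$cpg))
  if (!setequal(lab_i, flags$cpg) || !setequal(lab_i, frequencies$cpg)) {
    missing_lab <- unique(c(
      setdiff(lab_i, flags$cpg), setdiff(flags$cpg, lab_i),
      setdiff(lab_i, frequencies$cpg), setdiff(frequencies$cpg, lab_i)
    ))
    stop("CpG labels do not match across inputs: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  panel_mean <- index_tbl |>
    dplyr::group_by(.data$cpg) |>
    dplyr::summarise(
      mean_methylation_panel = mean(.data$percent, na.rm = TRUE),
      .groups = "drop"
    )
  out <- flags |>
    dplyr::left_join(panel_mean, by = "cpg") |>
    dplyr::left_join(frequencies, by = "cpg") |>
    dplyr::mutate(
      candidate = !is.na(.data$median_index) &
        .data$median_index < candidate_index_max &
        .data$tfbs_frequency >= candidate_freq_min
    ) |>
    dplyr::select(
      "cpg", "position", "mean_methylation_panel", "median_index",
      "direction", "p", "q", "tfbs_frequency", "candidate"
    ) |>
    dplyr::arrange(.data$cpg)
  class(out) <- c("cpg_report", class(out))
  attr(out, "params") <- list(
    candidate_index_max = candidate_index_max,
    candidate_freq_min = candidate_freq_min
  )
  out
}

#' Call qMSP methylation against the unmethylated-control background
#'
#' In qMSP, lower delta-Ct means stronger methylation signal. A sample is
#' called positive when its delta-Ct is strictly below the background
#' delta-Ct of the unmethylated control (`C_minus`) minus a guard `margin`;
#' equality or weaker signal is negative (technical variation around the
#' baseline is not meaningful methylation). A sample whose target amplicon
#' did not amplify but whose input-DNA control is valid is called
#' `undetected` (counted negative); a sample without valid input control is
#' `invalid` and excluded from rates.
#'
#' @param qmsp Tibble from [read_qmsp_table()] or [generate_qmsp_cohort()]
#'   (`sample`, `group`, `dct`, optionally `ct_target`, `ct_reference`).
#' @param margin Non-negative delta-Ct guard band (default 0).
#' @param invert_background_rule Flip the rule to call positives *above*
#'   background (an alternative reading of the background convention).
#' @return Object of class `qmsp_calls`: list with `calls` (tibble `sample`,
#'   `group`, `dct`, `call` in positive/negative/undetected/invalid),
#'   `background_dct`, `margin`.
#' @export
call_qmsp <- function(qmsp, margin = 0, invert_background_rule = FALSE) {
  stopifnot(margin >= 0)
  bg_rows <- qmsp[qmsp$group == "C_minus", , drop = FALSE]
  if (nrow(bg_rows) != 1) {
    stop("calling requires exactly one C_minus control row (found ",
         nrow(bg_rows), ")", call. = FALSE)
  }
  background <- bg_rows$dct[[1]]
  if (!is.finite(background)) {
    stop("C_minus control has no valid delta-Ct", call. = FALSE)
  }
  body <- qmsp[!qmsp$group %in% c("C_minus", "C_plus"), , drop = FALSE]
  has_ct <- all(c("ct_target", "ct_reference") %in% names(body))
  ref_ok <- if (has_ct) is.finite(body$ct_reference) else rep(TRUE, nrow(body))
  signal <- is.finite(body$dct)
  positive <- if (invert_background_rule) {
    body$dct > background + margin
  } else {
    body$dct < background - margin
  }
  call <- dplyr::case_when(
    !ref_ok ~ "invalid",
    !signal ~ "undetected",
    positive ~ "positive",
    TRUE ~ "negative"
  )
  structure(
    list(
      calls = tibble::tibble(
        sample = body$sample, group = body$group, dct = body$dct, call = call
      ),
      background_dct = background,
      margin = margin
    ),
    class = "qmsp_calls"
  )
}

#' @export
print.qmsp_calls <- function(x, ...) {
  cat("<qmsp_calls> background delta-Ct ", x$background_dct,
      ", margin ", x$margin, "\n", sep = "")
  print(table(x$calls$group, x$calls$call))
  invisible(x)
}

#' Per-group qMSP detection rates
#'
#' Fraction of positive calls among valid samples per group (undetected
#' counts negative, invalid samples are excluded), with a Clopper-Pearson
#' 95% confidence interval. Empty groups are omitted with a warning.
#'
#' @param calls A [call_qmsp()] object.
#' @param groups Optional subset of groups to report.
#' @return Tibble with `group`, `n_valid`, `n_positive`, `rate`, `ci_low`,
#'   `ci_high`, `n_invalid`.
#' @export
cohort_rates <- function(calls, groups = NULL) {
  stopifnot(inherits(calls, "qmsp_calls"))
  tab <- calls$calls
  if (is.null(groups)) groups <- unique(tab$group)
  missing_groups <- setdiff(groups, tab$group)
  if (length(missing_groups) > 0) {
    warning("empty group(s) omitted: ", paste(missing_groups, collapse = ", "),
            call. = FALSE)
    groups <- setdiff(groups, missing_groups)
  }
  purrr::map_dfr(groups, function(g) {
    sub <- tab[tab$group == g, , drop = FALSE]
    valid <- sub$call != "invalid"
    n_valid <- sum(valid)
    n_pos <- sum(sub$call == "positive")
    ci <- if (n_valid > 0) {
      stats::binom.test(n_pos, n_valid)$conf.int
    } else {
      c(NA_real_, NA_real_)
    }
    tibble::tibble(
      group = g, n_valid = n_valid, n_positive = n_pos,
      rate = if (n_valid > 0) n_pos / n_valid else NA_real_,
      ci_low = ci[1], ci_high = ci[2],
      n_invalid = sum(!valid)
    )
  })
}
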