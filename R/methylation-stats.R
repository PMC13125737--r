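#' Aggregate pyrosequencing replicates per (sample, CpG)
#'
#' Collapses replicate measurements with the median (the panel's summary of
#' choice; the mean is available). A (sample, CpG) cell missing in more than
#' `max_missing_frac` of its replicates is reported missing, reflecting the
#' treatment of pyrosequencing dropouts.
#'
#' @param meth Long methylation tibble (`sample`, `replicate`, `cpg`,
#'   `percent`).
#' @param aggregate `"median"` or `"mean"`.
#' @param max_missing_frac Missingness fraction above which a cell is NA.
#' @return Tibble with columns `sample`, `cpg`, `percent`.
#' @export
aggregate_replicates <- function(meth, aggregate = c("median", "mean"),
                                 max_missing_frac = 0.5) {
  aggregate <- match.arg(aggregate)
  fun <- if (aggregate == "median") stats::median else mean
  meth |>
    dplyr::group_by(.data$sample, .data$cpg) |>
    dplyr::summarise(
      percent = if (mean(is.na(.data$percent)) > max_missing_frac) {
        NA_real_
      } else {
        fun(.data$percent, na.rm = TRUE)
      },
      .groups = "drop"
    )
}

#' Per-sample mean promoter methylation
#'
#' Arithmetic mean of the replicate-aggregated per-CpG percentages within
#' each sample, with missing CpGs excluded pairwise.
#'
#' @inheritParams aggregate_replicates
#' @return Tibble with columns `sample`, `promoter_mean`, `n_cpgs_used`.
#' @export
promoter_mean_methylation <- function(meth, aggregate = "median") {
  agg <- aggregate_replicates(meth, aggregate)
  out <- agg |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      promoter_mean = mean(.data$percent, na.rm = TRUE),
      n_cpgs_used = sum(!is.na(.data$percent)),
      .groups = "drop"
    )
  if (any(out$n_cpgs_used == 0)) {
    stop(
      "all CpG values missing for sample(s): ",
      paste(out$sample[out$n_cpgs_used == 0], collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Relative methylation index per CpG site
#'
#' Divides each CpG's (replicate-aggregated) percent methylation by the mean
#' promoter methylation of the same sample. Values above 1 mark CpGs locally
#' more methylated than their promoter average; with complete data the mean
#' index within a sample is exactly 1 because the denominator is computed
#' from the same aggregated values over the same CpG set.
#'
#' Samples whose promoter mean is 0 (fully unmethylated promoter) get missing
#' indices with a warning rather than infinities.
#'
#' @inheritParams aggregate_replicates
#' @return Tibble with columns `sample`, `cpg`, `percent`, `index`, carrying
#'   the per-sample denominators as the `promoter_means` attribute.
#' @examples
#' meth <- tibble::tibble(
#'   sample = "s1", replicate = 1L, cpg = 1:3, percent = c(80, 100, 120) * 0.5
#' )
#' relative_methylation_index(meth)$index
#' @export
relative_methylation_index <- function(meth, aggregate = "median") {
  agg <- aggregate_replicates(meth, aggregate)
  means <- promoter_mean_methylation(meth, aggregate)
  zero <- means$sample[means$promoter_mean == 0]
  if (length(zero) > 0) {
    warning(
      "promoter mean is 0 for sample(s) ",
      paste(zero, collapse = ", "),
      "; their indices are reported missing",
      call. = FALSE
    )
  }
  out <- agg |>
    dplyr::left_join(means, by = "sample") |>
    dplyr::mutate(
      index = dplyr::if_else(
        .data$promoter_mean > 0, .data$percent / .data$promoter_mean, NA_real_
      )
    ) |>
    dplyr::select("sample", "cpg", "percent", "index")
  attr(out, "promoter_means") <- means
  out
}

#' Flag critical CpG sites
#'
#' Tests, for every CpG, whether its relative methylation index differs from
#' 1 across the sample panel: a two-sided one-sample Wilcoxon signed-rank
#' test against 1 (exact, ties handled by midrank convolution), with
#' Benjamini-Hochberg adjustment across CpGs reported alongside the raw
#' p-value. Direction is taken from the median index; a CpG is `neutral`
#' when the raw p-value is at or above `alpha`, and untestable (direction
#' `neutral`, missing p) with fewer than 3 usable samples.
#'
#' @param index_tbl Output of [relative_methylation_index()].
#' @param alpha Significance level for the direction call.
#' @return Tibble with columns `cpg`, `n`, `median_index`, `p`, `q`,
#'   `direction` (`high`, `low`, `neutral`).
#' @export
flag_critical_cpgs <- function(index_tbl, alpha = 0.05) {
  out <- index_tbl |>
    dplyr::group_by(.data$cpg) |>
    dplyr::summarise(
      n = sum(!is.na(.data$index)),
      median_index = stats::median(.data$index, na.rm = TRUE),
      p = if (sum(!is.na(.data$index)) >= 3) {
        wilcoxon_signed_rank(.data$index[!is.na(.data$index)], mu = 1)$p
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$direction <- dplyr::case_when(
    is.na(out$p) | out$p >= alpha ~ "neutral",
    out$median_index > 1 ~ "high",
    out$median_index < 1 ~ "low",
    TRUE ~ "neutral"
  )
  out
}

#' Methylation and expression contrast after demethylating treatment
#'
#' Compares a treated condition (e.g. 5-aza-2'-deoxycytidine) with its
#' vehicle control: per CpG, the difference of medians (treated - vehicle)
#' over all replicate measurements with a Mann-Whitney p-value, and, when
#' expression tables are supplied, the expression shift
#' ddCt = median dCt(treated) - median dCt(vehicle) per transcript with a
#' Mann-Whitney p-value. Negative ddCt means re-expression.
#'
#' @param treated_meth,vehicle_meth Long methylation tibbles with identical
#'   CpG labels.
#' @param treated_expr,vehicle_expr Optional long expression tibbles
#'   (`sample`, `replicate`, `transcript`, `dct`).
#' @return List with `methylation` (tibble `cpg`, `delta`, `p`) and
#'   `expression` (tibble `transcript`, `ddct`, `p`, or NULL).
#' @export
demethylation_contrast <- function(treated_meth, vehicle_meth,
                                   treated_expr = NULL, vehicle_expr = NULL) {
  if (!setequal(unique(treated_meth$cpg), unique(vehicle_meth$cpg))) {
    stop("treated and vehicle matrices have mismatched CpG labels", call. = FALSE)
  }
  meth <- purrr::map_dfr(sort(unique(treated_meth$cpg)), function(cg) {
    tv <- treated_meth$percent[treated_meth$cpg == cg]
    vv <- vehicle_meth$percent[vehicle_meth$cpg == cg]
    tv <- tv[!is.na(tv)]; vv <- vv[!is.na(vv)]
    tibble::tibble(
      cpg = cg,
      delta = stats::median(tv) - stats::median(vv),
      p = if (length(tv) >= 3 && length(vv) >= 3) mann_whitney(tv, vv)$p else NA_real_
    )
  })
  expr <- NULL
  if (!is.null(treated_expr) && !is.null(vehicle_expr)) {
    expr <- purrr::map_dfr(sort(unique(treated_expr$transcript)), function(tr) {
      td <- treated_expr$dct[treated_expr$transcript == tr]
      vd <- vehicle_expr$dct[vehicle_expr$transcript == tr]
      td <- td[!is.na(td)]; vd <- vd[!is.na(vd)]
      tibble::tibble(
        transcript = tr,
        ddct = stats::median(td) - stats::median(vd),
        p = if (length(td) >= 3 && length(vd) >= 3) mann_whitney(td, vd)$p else NA_real_
      )
    })
  }
  list(methylation = meth, expression = expr)
}
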