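#' Reference delta-Ct tertile cutoffs for the RASSF1 locus panel
#'
#' The published cell-line panel stratified expression at the 33rd and 66th
#' delta-Ct percentiles, 9.083 and 15.308. Supplied as an opaque preset for
#' [classify_expression()]; the underlying delta-Ct distribution is not
#' re-derivable, so these are constants, not computed values.
#'
#' @format Named numeric vector with elements `low` and `high`.
#' @export
rassf1_tertile_cutoffs <- c(low = 9.083, high = 15.308)

#' Delta-Ct tertile cutoffs
#'
#' 33rd and 66th percentiles of a delta-Ct collection, using linear
#' interpolation between order statistics (`h = (n - 1) p + 1`; R's default
#' quantile type 7).
#'
#' @param dct Numeric vector of delta-Ct values (NA dropped).
#' @return Named numeric vector `c(low = q33, high = q66)`.
#' @examples
#' tertile_cutoffs(c(0, 50, 100))
#' @export
tertile_cutoffs <- function(dct) {
  dct <- dct[is.finite(dct)]
  if (length(dct) < 3) stop("need at least 3 finite delta-Ct values", call. = FALSE)
  q <- stats::quantile(dct, probs = c(0.33, 0.66), type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Classify expression from delta-Ct
#'
#' Lower delta-Ct means higher expression, so values at or below the low
#' cutoff are `high`, values at or above the high cutoff are `low`, and
#' values strictly between are `intermediate`. Boundary values are inclusive
#' on the outer classes. Missing delta-Ct yields a missing label.
#'
#' @param dct Numeric vector of delta-Ct values.
#' @param cutoffs Named vector `c(low=, high=)` from [tertile_cutoffs()] or
#'   the preset [rassf1_tertile_cutoffs].
#' @return Character vector over `high`, `intermediate`, `low`.
#' @examples
#' classify_expression(c(5, 12, 20), rassf1_tertile_cutoffs)
#' @export
classify_expression <- function(dct, cutoffs) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] <= cutoffs[2])
  dplyr::case_when(
    is.na(dct) ~ NA_character_,
    dct <= cutoffs[[1]] ~ "high",
    dct >= cutoffs[[2]] ~ "low",
    TRUE ~ "intermediate"
  )
}

#' Classify an expression table by delta-Ct tertiles
#'
#' Tibble-first wrapper: computes (or accepts) tertile cutoffs and labels
#' every (sample, transcript) after aggregating replicates by median.
#'
#' @param expr Long expression tibble (`sample`, `replicate`, `transcript`,
#'   `dct`).
#' @param cutoffs Optional preset cutoffs; derived from the data's pooled
#'   delta-Ct distribution when NULL.
#' @return Tibble `sample`, `transcript`, `dct`, `label`, with the cutoffs in
#'   the `cutoffs` attribute.
#' @export
classify_expression_table <- function(expr, cutoffs = NULL) {
  agg <- expr |>
    dplyr::group_by(.data$sample, .data$transcript) |>
    dplyr::summarise(dct = stats::median(.data$dct, na.rm = TRUE), .groups = "drop")
  if (is.null(cutoffs)) cutoffs <- tertile_cutoffs(agg$dct)
  agg$label <- classify_expression(agg$dct, cutoffs)
  attr(agg, "cutoffs") <- cutoffs
  agg
}

#' Spearman correlation between promoter methylation and expression
#'
#' Rank correlation (midrank ties) between per-sample mean promoter
#' methylation and per-sample delta-Ct, with a two-sided p-value: exact
#' permutation for 9 or fewer pairs, t-approximation otherwise. Pairs with a
#' missing value are dropped.
#'
#' Because the expression axis is delta-Ct (inverse of abundance), a
#' *positive* `rho_vs_dct` corresponds to a *negative* methylation-expression
#' relationship; both orientations are reported explicitly.
#'
#' @param methylation Per-sample mean promoter methylation (percent).
#' @param dct Per-sample delta-Ct, same order.
#' @return Object of class `cpg_spearman`: list with `rho_vs_dct`,
#'   `rho_vs_expression`, `p`, `n`, `method`, `orientation_note`.
#' @examples
#' spearman_methylation_expression(c(10, 20, 30), c(5, 10, 15))
#' @export
spearman_methylation_expression <- function(methylation, dct) {
  stopifnot(length(methylation) == length(dct))
  res <- spearman_test(methylation, dct)
  structure(
    list(
      rho_vs_dct = res$rho,
      rho_vs_expression = -res$rho,
      p = res$p,
      n = res$n,
      method = res$method,
      orientation_note = paste(
        "rho_vs_dct is computed against delta-Ct;",
        "delta-Ct is inversely related to expression, so the sign against",
        "expression is the negative of rho_vs_dct"
      )
    ),
    class = "cpg_spearman"
  )
}

#' @export
print.cpg_spearman <- function(x, ...) {
  cat(
    "Spearman correlation (n = ", x$n, ", ", x$method, ")\n",
    "  rho vs delta-Ct:    ", formatC(x$rho_vs_dct, digits = 4, format = "f"), "\n",
    "  rho vs expression:  ", formatC(x$rho_vs_expression, digits = 4, format = "f"), "\n",
    "  two-sided p:        ", format.pval(x$p, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Hierarchically cluster samples by transcript delta-Ct profiles
#'
#' Agglomerative clustering of samples on raw delta-Ct values (no
#' transformation or per-gene normalization), Euclidean distance, complete
#' linkage; the tree is cut at `k` clusters.
#'
#' @param expr Long tibble (`sample`, `transcript`, `dct`, replicates
#'   aggregated by median if a `replicate` column is present) or a wide
#'   sample-by-transcript data frame with a `sample` column.
#' @param k Number of clusters to cut.
#' @return Object of class `expr_clust`: list with `hclust`, `labels_at_k`
#'   (named integer vector), `k`, `matrix`.
#' @export
cluster_expression <- function(expr, k) {
  if (all(c("transcript", "dct") %in% names(expr))) {
    grouping <- c("sample", "transcript")
    agg <- expr |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::summarise(dct = stats::median(.data$dct, na.rm = TRUE), .groups = "drop")
    wide <- tidyr::pivot_wider(agg, names_from = "transcript", values_from = "dct")
  } else {
    wide <- tibble::as_tibble(expr)
  }
  m <- as.matrix(wide[setdiff(names(wide), "sample")])
  rownames(m) <- wide$sample
  if (anyNA(m)) {
    stop("delta-Ct matrix has missing cells; impute or drop before clustering",
         call. = FALSE)
  }
  if (k > nrow(m)) stop("k exceeds the number of samples", call. = FALSE)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  structure(
    list(
      hclust = hc,
      labels_at_k = stats::cutree(hc, k = k),
      k = as.integer(k),
      matrix = m
    ),
    class = "expr_clust"
  )
}

#' @export
print.expr_clust <- function(x, ...) {
  cat("<expr_clust> ", nrow(x$matrix), " samples, ", ncol(x$matrix),
      " transcripts, k = ", x$k, "\n", sep = "")
  sizes <- table(x$labels_at_k)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a clustering tree as Newick
#'
#' @param x An `expr_clust` object.
#' @param file Optional path; when NULL the Newick string is returned.
#' @return The Newick string (invisibly when written to `file`).
#' @export
export_newick <- function(x, file = NULL) {
  stopifnot(inherits(x, "expr_clust"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}
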