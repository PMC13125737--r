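# broom-style tidiers for the package's fitted objects

#' Tidy a methylation-expression Spearman result
#'
#' @param x A `cpg_spearman` object.
#' @param ... Unused.
#' @return One-row tibble with `rho_vs_dct`, `rho_vs_expression`, `p.value`,
#'   `n`, `method`.
#' @method tidy cpg_spearman
#' @export
tidy.cpg_spearman <- function(x, ...) {
  tibble::tibble(
    rho_vs_dct = x$rho_vs_dct,
    rho_vs_expression = x$rho_vs_expression,
    p.value = x$p,
    n = x$n,
    method = x$method
  )
}

#' @rdname tidy.cpg_spearman
#' @method glance cpg_spearman
#' @export
glance.cpg_spearman <- function(x, ...) tidy.cpg_spearman(x)

#' Tidy an expression clustering
#'
#' @param x An `expr_clust` object.
#' @param ... Unused.
#' @return Tibble with one row per sample: `sample`, `cluster`.
#' @method tidy expr_clust
#' @export
tidy.expr_clust <- function(x, ...) {
  tibble::tibble(
    sample = names(x$labels_at_k),
    cluster = unname(x$labels_at_k)
  )
}

#' Summary of an expression clustering
#'
#' @param x An `expr_clust` object.
#' @param ... Unused.
#' @return One-row tibble with `n_samples`, `n_transcripts`, `k`,
#'   `max_height`, `heights_monotone` (complete linkage is monotone, so
#'   merge heights never decrease).
#' @method glance expr_clust
#' @export
glance.expr_clust <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$matrix),
    n_transcripts = ncol(x$matrix),
    k = x$k,
    max_height = max(x$hclust$height),
    heights_monotone = !is.unsorted(x$hclust$height)
  )
}

#' Tidy qMSP calls
#'
#' @param x A `qmsp_calls` object.
#' @param ... Unused.
#' @return The per-sample call tibble with the background delta-Ct attached.
#' @method tidy qmsp_calls
#' @export
tidy.qmsp_calls <- function(x, ...) {
  dplyr::mutate(x$calls, background_dct = x$background_dct, margin = x$margin)
}

#' @rdname tidy.qmsp_calls
#' @method glance qmsp_calls
#' @export
glance.qmsp_calls <- function(x, ...) {
  tibble::tibble(
    background_dct = x$background_dct,
    margin = x$margin,
    n_samples = nrow(x$calls),
    n_positive = sum(x$calls$call == "positive"),
    n_invalid = sum(x$calls$call == "invalid")
  )
}
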