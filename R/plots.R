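# ggplot2 views of the pipeline's main result types

#' Plot relative methylation indices per CpG
#'
#' One point per (sample, CpG) with the per-CpG median highlighted and the
#' neutral index 1 marked: values above the line are locally
#' hyper-methylated relative to the promoter mean, values below locally
#' hypo-methylated.
#'
#' @param index_tbl Output of [relative_methylation_index()].
#' @return A ggplot object.
#' @export
plot_relative_index <- function(index_tbl) {
  med <- index_tbl |>
    dplyr::group_by(.data$cpg) |>
    dplyr::summarise(index = stats::median(.data$index, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(index_tbl, ggplot2::aes(x = factor(.data$cpg), y = .data$index)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = med, colour = "firebrick", size = 2.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "CpG site", y = "relative methylation index",
      title = "Per-CpG methylation relative to the promoter mean"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an integrated CpG report
#'
#' Mirrors the integration view of the pipeline: bars for panel mean
#' methylation per CpG and a dotted line for the TFBS frequency (right
#' axis), with candidate CpGs highlighted.
#'
#' @param object A `cpg_report` tibble from [build_cpg_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cpg_report
#' @export
autoplot.cpg_report <- function(object, ...) {
  scale <- max(object$mean_methylation_panel, 1, na.rm = TRUE) /
    max(object$tfbs_frequency, 1)
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$cpg))) +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$mean_methylation_panel, fill = .data$candidate),
      width = 0.7
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$tfbs_frequency * scale, group = 1),
      linetype = "dotted"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$tfbs_frequency * scale), size = 1) +
    ggplot2::scale_y_continuous(
      "panel mean methylation (%)",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "TFBS frequency")
    ) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "CpG site", fill = "candidate") +
    ggplot2::theme_minimal()
}

#' Plot qMSP calls against the assay background
#'
#' Per-sample delta-Ct by cohort group, coloured by call, with the
#' unmethylated-control background (and margin band) marked. Lower delta-Ct
#' means stronger methylation signal.
#'
#' @param calls A [call_qmsp()] object.
#' @return A ggplot object.
#' @export
plot_qmsp_calls <- function(calls) {
  stopifnot(inherits(calls, "qmsp_calls"))
  df <- calls$calls[is.finite(calls$calls$dct), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$dct,
                                   colour = .data$call)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2) +
    ggplot2::geom_hline(yintercept = calls$background_dct, linetype = "dashed") +
    ggplot2::geom_hline(
      yintercept = calls$background_dct - calls$margin, linetype = "dotted"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = NULL, y = "delta-Ct (reversed: up = more methylation signal)",
      title = "qMSP methylation calls vs unmethylated-control background"
    ) +
    ggplot2::theme_minimal()
}

#' Dendrogram of an expression clustering
#'
#' @param object An `expr_clust` object.
#' @param ... Unused.
#' @return A ggplot object drawing the complete-linkage tree with cluster
#'   assignments at the cut.
#' @method autoplot expr_clust
#' @export
autoplot.expr_clust <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  # flatten the dendrogram into segments
  seg <- dend_segments(dend, x_at = new.env(parent = emptyenv()))$seg
  labs <- tibble::tibble(
    sample = hc$labels[hc$order],
    x = seq_along(hc$order),
    cluster = factor(object$labels_at_k[hc$labels[hc$order]])
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                               xend = .data$xend, yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = .data$x, y = -0.02 * max(hc$height),
                   label = .data$sample, colour = .data$cluster),
      angle = 90, hjust = 1, size = 3
    ) +
    ggplot2::scale_y_continuous("Euclidean distance (complete linkage)") +
    ggplot2::labs(x = NULL, colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

# recursive dendrogram -> segment table; leaves at x = 1..n in plot order
dend_segments <- function(node, x_at) {
  if (stats::is.leaf(node)) {
    n_seen <- length(ls(x_at))
    x <- n_seen + 1
    assign(as.character(x), TRUE, envir = x_at)
    return(list(x = x, h = 0, seg = NULL))
  }
  left <- dend_segments(node[[1]], x_at)
  right <- dend_segments(node[[2]], x_at)
  h <- attr(node, "height")
  seg <- dplyr::bind_rows(
    left$seg, right$seg,
    tibble::tibble(
      x = c(left$x, right$x, left$x),
      y = c(left$h, right$h, h),
      xend = c(left$x, right$x, right$x),
      yend = c(h, h, h)
    )
  )
  list(x = (left$x + right$x) / 2, h = h, seg = seg)
}
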