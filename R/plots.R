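#' Violin plot of nuclei-per-myotube distributions
#'
#' The standard presentation of fusion phenotypes: one violin per condition
#' over the per-myotube nucleus counts, on a log2 axis, with the median
#' marked.
#'
#' @param per_myotube Tibble with columns `condition` and `n_nuclei` (as
#'   produced by [run_fusion_pipeline()]; any tidy per-myotube table works).
#' @return A ggplot object.
#' @export
plot_fusion_distribution <- function(per_myotube) {
  ggplot2::ggplot(per_myotube,
                  ggplot2::aes(x = .data$condition, y = .data$n_nuclei,
                               fill = .data$condition)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::stat_summary(fun = median, geom = "point", size = 2,
                          show.legend = FALSE) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "nuclei per myotube (log2 scale)") +
    ggplot2::theme_minimal()
}

#' Bar chart of myotube size-class fractions
#'
#' @param x A `fusion_report`.
#' @param ... Unused.
#' @return A ggplot object showing the 2-14 / 15-49 / >=50 nuclei fractions.
#' @export
autoplot.fusion_report <- function(x, ...) {
  ggplot2::ggplot(x$bin_fractions,
                  ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "nuclei per myotube", y = "fraction of myotubes") +
    ggplot2::theme_minimal()
}

#' Volcano plot of one DE contrast
#'
#' @param table DE tibble (`gene_id, log2fc, pvalue[, padj]`).
#' @param thresholds A [deg_thresholds()] drawn as dashed cutoff lines.
#' @return A ggplot object; significant genes are coloured by direction.
#' @export
plot_volcano <- function(table, thresholds = deg_thresholds()) {
  check_deg_table(table)
  tbl <- tibble::as_tibble(table)
  if (!"padj" %in% names(tbl)) tbl$padj <- bh_adjust(tbl$pvalue)
  tbl <- dplyr::mutate(tbl, status = dplyr::case_when(
    abs(.data$log2fc) >= thresholds$min_abs_log2fc &
      .data$padj <= thresholds$max_padj & .data$log2fc > 0 ~ "up",
    abs(.data$log2fc) >= thresholds$min_abs_log2fc &
      .data$padj <= thresholds$max_padj ~ "down",
    TRUE ~ "ns"))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$padj),
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thresholds$min_abs_log2fc,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$max_padj),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#d95f02", down = "#1b9e77",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Scatter of shared genes by direction quadrant
#'
#' Log2 fold-change in contrast A against contrast B for the shared
#' significant genes, coloured by quadrant; the down-in-A / up-in-B quadrant
#' holds the opposing-regulation candidates.
#'
#' @param x An `opposing_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opposing_classification <- function(x, ...) {
  ggplot2::ggplot(x$genes, ggplot2::aes(x = .data$log2fc_a, y = .data$log2fc_b,
                                        colour = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = paste0("log2FC (", x$name_a, ")"),
                  y = paste0("log2FC (", x$name_b, ")")) +
    ggplot2::theme_minimal()
}
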