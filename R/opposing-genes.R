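#' Differential-expression significance thresholds
#'
#' Defaults follow the conventions used for the two splice-isoform knockdown
#' contrasts: absolute log2 fold-change of at least 0.8 (a 1.74-fold change
#' on the linear scale) and Benjamini–Hochberg adjusted p-value of at most
#' 0.05. Both boundaries are inclusive.
#'
#' @param min_abs_log2fc Minimum |log2 fold-change| (>= 0).
#' @param max_padj Maximum adjusted p-value (in `(0, 1]`).
#' @return A `deg_thresholds` object.
#' @export
deg_thresholds <- function(min_abs_log2fc = 0.8, max_padj = 0.05) {
  if (!is.numeric(min_abs_log2fc) || min_abs_log2fc < 0) {
    abort("`min_abs_log2fc` must be >= 0")
  }
  if (!is.numeric(max_padj) || max_padj <= 0 || max_padj > 1) {
    abort("`max_padj` must be in (0, 1]")
  }
  structure(list(min_abs_log2fc = min_abs_log2fc, max_padj = max_padj),
            class = "deg_thresholds")
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: sort ascending, scale
#' `p_(i) * m / i`, enforce monotonicity by cumulative minimum from the
#' largest rank down, cap at 1, and return in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("`pvalues` must be numeric")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(pvalues, method = "BH")
}

check_deg_table <- function(table, require_padj = FALSE) {
  need <- c("gene_id", "log2fc", "pvalue")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    abort(paste0("DE table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(table$gene_id)) abort("duplicate gene ids in DE table")
  if (any(table$pvalue < 0 | table$pvalue > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  if (require_padj && !"padj" %in% names(table)) abort("`padj` column required")
  invisible(table)
}

#' Filter a differential-expression table
#'
#' Keeps genes passing `|log2fc| >= min_abs_log2fc` and
#' `padj <= max_padj` (both inclusive) and labels each with its regulation
#' direction (`"up"` if `log2fc > 0`, else `"down"`; a log2 fold-change of
#' exactly 0 can never pass a positive cutoff). When the table has no `padj`
#' column it is computed with [bh_adjust()] over the *full* table first,
#' since the adjustment depends on the number of tests.
#'
#' @param table Data frame with columns `gene_id`, `log2fc`, `pvalue` and
#'   optionally `padj`.
#' @param thresholds A [deg_thresholds()].
#' @return Tibble of significant genes: `gene_id, log2fc, pvalue, padj,
#'   direction`.
#' @export
filter_deg <- function(table, thresholds = deg_thresholds()) {
  stopifnot(inherits(thresholds, "deg_thresholds"))
  check_deg_table(table)
  tbl <- tibble::as_tibble(table)
  if (!"padj" %in% names(tbl) || all(is.na(tbl$padj))) {
    tbl$padj <- bh_adjust(tbl$pvalue)
  }
  dplyr::filter(
    dplyr::mutate(tbl, direction = ifelse(.data$log2fc > 0, "up", "down")),
    abs(.data$log2fc) >= thresholds$min_abs_log2fc,
    .data$padj <= thresholds$max_padj
  )
}

#' Classify shared significant genes by direction quadrant
#'
#' Intersects two filtered differential-expression tables on gene id and
#' assigns each shared gene to a quadrant from its two direction labels:
#' `down_a_up_b`, `up_a_down_b`, `up_both` or `down_both`. The
#' `down_a_up_b` set — genes down in contrast A and up in contrast B — is
#' the candidate set for genes under opposing isoform control ("fusion
#' genes").
#'
#' @param sig_a,sig_b Filtered tables from [filter_deg()] (must carry
#'   `gene_id`, `log2fc`, `direction`).
#' @param name_a,name_b Labels for the two contrasts (cosmetic).
#' @return An `opposing_classification`: list with `genes` (tibble
#'   `gene_id, log2fc_a, log2fc_b, direction_a, direction_b, quadrant`),
#'   `summary` (quadrant counts), `overlap`, and the contrast names.
#' @export
classify_opposing <- function(sig_a, sig_b, name_a = "A", name_b = "B") {
  for (s in list(sig_a, sig_b)) {
    if (!all(c("gene_id", "log2fc", "direction") %in% names(s))) {
      abort("inputs must be filter_deg() outputs with gene_id, log2fc, direction")
    }
    if (anyDuplicated(s$gene_id)) abort("duplicate gene ids in a filtered table")
  }
  genes <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(sig_a), "gene_id",
                  log2fc_a = "log2fc", direction_a = "direction"),
    dplyr::select(tibble::as_tibble(sig_b), "gene_id",
                  log2fc_b = "log2fc", direction_b = "direction"),
    by = "gene_id"
  )
  genes <- dplyr::mutate(genes, quadrant = dplyr::case_when(
    .data$direction_a == "down" & .data$direction_b == "up" ~ "down_a_up_b",
    .data$direction_a == "up" & .data$direction_b == "down" ~ "up_a_down_b",
    .data$direction_a == "up" ~ "up_both",
    TRUE ~ "down_both"
  ))
  genes <- dplyr::arrange(genes, .data$gene_id)
  quadrants <- c("down_a_up_b", "up_a_down_b", "up_both", "down_both")
  summary <- tibble::tibble(
    quadrant = quadrants,
    n = vapply(quadrants, function(q) sum(genes$quadrant == q), 0L)
  )
  structure(list(genes = genes, summary = summary, overlap = nrow(genes),
                 name_a = name_a, name_b = name_b),
            class = "opposing_classification")
}

#' @export
print.opposing_classification <- function(x, ...) {
  cat(sprintf("<opposing_classification> %s vs %s: %d shared significant genes\n",
              x$name_a, x$name_b, x$overlap))
  print(x$summary)
  invisible(x)
}

#' Per-gene quadrant table of an opposing classification
#' @param x An `opposing_classification`.
#' @param ... Unused.
#' @return Tibble, one row per shared gene.
#' @export
tidy.opposing_classification <- function(x, ...) x$genes

#' One-row summary of an opposing classification
#' @param x An `opposing_classification`.
#' @param ... Unused.
#' @return One-row tibble: overlap and the four quadrant counts.
#' @export
glance.opposing_classification <- function(x, ...) {
  tibble::tibble(overlap = x$overlap,
                 !!!setNames(as.list(x$summary$n), x$summary$quadrant))
}
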