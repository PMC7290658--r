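#' Parameters for simulated two-contrast DE tables
#'
#' Describes a gene universe with a planted subset of genes significant in
#' both of two contrasts, of which a planted sub-subset is regulated in
#' opposing directions (down in contrast A, up in contrast B). Defaults
#' mirror a two-knockdown comparison with 98 shared significant genes, 46 of
#' them opposing, among 1,000 genes.
#'
#' @param n_genes Size of the gene universe (> 0).
#' @param n_shared_planted Number of genes planted significant in both
#'   contrasts.
#' @param n_opposing_planted Of the shared genes, how many are planted
#'   down-in-A / up-in-B (<= `n_shared_planted`).
#' @param planted_abs_lfc_min Minimum |log2 fold-change| of planted genes.
#' @param null_lfc_sd Standard deviation of the null log2 fold-changes.
#' @param planted_p_max Upper end of the planted p-value range; planted
#'   p-values are drawn log-uniform on `[1e-12, planted_p_max]`. The default
#'   1e-3 keeps planted genes significant after Benjamini–Hochberg
#'   adjustment at the default gene-universe size.
#' @param seed Integer seed.
#' @return A `deg_sim_params` object.
#' @export
deg_sim_params <- function(n_genes = 1000L,
                           n_shared_planted = 98L,
                           n_opposing_planted = 46L,
                           planted_abs_lfc_min = 0.8,
                           null_lfc_sd = 0.3,
                           planted_p_max = 1e-3,
                           seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            n_shared_planted = as.integer(n_shared_planted),
            n_opposing_planted = as.integer(n_opposing_planted),
            planted_abs_lfc_min = as.numeric(planted_abs_lfc_min),
            null_lfc_sd = as.numeric(null_lfc_sd),
            planted_p_max = as.numeric(planted_p_max),
            seed = as.integer(seed))
  if (p$n_genes <= 0) abort("`n_genes` must be > 0")
  if (p$n_shared_planted < 0 || p$n_shared_planted > p$n_genes) {
    abort("`n_shared_planted` must be in [0, n_genes]")
  }
  if (p$n_opposing_planted < 0 || p$n_opposing_planted > p$n_shared_planted) {
    abort("`n_opposing_planted` must be in [0, n_shared_planted]")
  }
  if (p$null_lfc_sd <= 0) abort("`null_lfc_sd` must be > 0")
  if (p$planted_p_max <= 0 || p$planted_p_max >= 1) abort("`planted_p_max` must be in (0, 1)")
  structure(p, class = "deg_sim_params")
}

#' Generate two-contrast DE tables with planted opposing regulation
#'
#' Builds two per-gene tables (`gene_id, log2fc, pvalue`) over the same gene
#' universe. Planted shared genes get |log2fc| >= `planted_abs_lfc_min` and
#' p-values log-uniform on `[1e-12, planted_p_max]` in *both* contrasts;
#' planted opposing genes additionally have a negative log2fc in contrast A
#' and positive in contrast B; remaining planted shared genes are concordant
#' (up-both or down-both, equal odds). All other genes draw log2fc from
#' `Normal(0, null_lfc_sd)` and p-values from `Uniform(0, 1)`.
#'
#' @param params A [deg_sim_params()].
#' @return List with `contrast_a`, `contrast_b` (tibbles
#'   `gene_id, log2fc, pvalue`) and `planted` (tibble
#'   `gene_id, planted, quadrant`, the intended truth labels).
#' @export
generate_deg_tables <- function(params = deg_sim_params()) {
  stopifnot(inherits(params, "deg_sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  ids <- sprintf("gene%05d", seq_len(n))
  planted_idx <- if (params$n_shared_planted > 0) {
    sort(sample(n, params$n_shared_planted))
  } else integer(0)
  opposing_idx <- if (params$n_opposing_planted > 0) {
    sort(sample(planted_idx, params$n_opposing_planted))
  } else integer(0)
  concordant_idx <- setdiff(planted_idx, opposing_idx)

  rlfc <- function(k, sign) {
    sign * (params$planted_abs_lfc_min + runif(k, 0, 2))
  }
  rp <- function(k) exp(runif(k, log(1e-12), log(params$planted_p_max)))

  lfc_a <- rnorm(n, 0, params$null_lfc_sd)
  lfc_b <- rnorm(n, 0, params$null_lfc_sd)
  p_a <- runif(n); p_b <- runif(n)

  quadrant <- rep(NA_character_, n)
  if (length(opposing_idx) > 0) {
    k <- length(opposing_idx)
    lfc_a[opposing_idx] <- rlfc(k, -1)
    lfc_b[opposing_idx] <- rlfc(k, +1)
    quadrant[opposing_idx] <- "down_a_up_b"
  }
  if (length(concordant_idx) > 0) {
    k <- length(concordant_idx)
    s <- sample(c(-1, 1), k, replace = TRUE)
    lfc_a[concordant_idx] <- rlfc(k, s)
    lfc_b[concordant_idx] <- rlfc(k, s)
    quadrant[concordant_idx] <- ifelse(s > 0, "up_both", "down_both")
  }
  if (length(planted_idx) > 0) {
    p_a[planted_idx] <- rp(length(planted_idx))
    p_b[planted_idx] <- rp(length(planted_idx))
  }

  list(
    contrast_a = tibble::tibble(gene_id = ids, log2fc = lfc_a, pvalue = p_a),
    contrast_b = tibble::tibble(gene_id = ids, log2fc = lfc_b, pvalue = p_b),
    planted = tibble::tibble(gene_id = ids,
                             planted = seq_len(n) %in% planted_idx,
                             quadrant = quadrant)
  )
}
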