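#' Region-of-interest set
#'
#' A set of polygonal regions, each delimiting one cell (typically a myotube
#' drawn on the eMHC channel), with an eMHC-positivity flag per region.
#'
#' @param polygons List of two-column vertex matrices.
#' @param emhc_positive Logical vector, one flag per polygon.
#' @param width,height Field dimensions in pixels.
#' @param pixel_size_um Micrometers per pixel.
#' @param ids Optional integer ids (default sequential).
#' @return A `roi_set`: tibble `roi_id, emhc_positive, polygon` (list-column)
#'   with field metadata attributes.
#' @export
roi_set <- function(polygons, emhc_positive, width, height,
                    pixel_size_um = NA_real_, ids = seq_along(polygons)) {
  if (length(polygons) != length(emhc_positive)) {
    abort("`polygons` and `emhc_positive` must have equal length")
  }
  polygons <- lapply(polygons, validate_polygon)
  for (p in polygons) {
    if (!polygon_is_simple(p)) abort("ROI polygons must be simple (non-self-intersecting)")
  }
  structure(
    tibble::tibble(roi_id = as.integer(ids),
                   emhc_positive = as.logical(emhc_positive),
                   polygon = polygons),
    class = c("roi_set", class(tibble::tibble())),
    field_width_px = as.integer(width), field_height_px = as.integer(height),
    pixel_size_um = as.numeric(pixel_size_um)
  )
}

#' Ground-truth ROIs of a simulated scene
#'
#' Converts a scene's myotube polygons (and, optionally, disks around
#' eMHC-positive mononucleated cells) into a [roi_set()] — the simulated
#' counterpart of regions drawn by hand on the eMHC channel.
#'
#' @param scene A [generate_scene()] result.
#' @param include_mono_positive Also emit a polygonal ROI (12-gon around the
#'   cell body) for each eMHC-positive mononucleated cell?
#' @return A [roi_set()]. All myotube ROIs are eMHC-positive.
#' @export
scene_rois <- function(scene, include_mono_positive = TRUE) {
  stopifnot(inherits(scene, "scene"))
  polys <- lapply(scene$myotubes, function(m) m$polygon)
  pos <- rep(TRUE, length(polys))
  if (include_mono_positive && any(scene$mono_cells$emhc_positive)) {
    mp <- scene$mono_cells[scene$mono_cells$emhc_positive, , drop = FALSE]
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    rc <- scene$mono_cell_radius_px
    for (i in seq_len(nrow(mp))) {
      polys <- c(polys, list(cbind(mp$x[i] + rc * cos(ang), mp$y[i] + rc * sin(ang))))
      pos <- c(pos, TRUE)
    }
  }
  roi_set(polys, pos, scene$field_width_px, scene$field_height_px,
          scene$pixel_size_um)
}

#' Assign nuclear centroids to regions of interest
#'
#' Each nucleus is assigned by a centroid-in-polygon test (even-odd rule,
#' boundary counts as inside). A centroid contained in several ROIs goes to
#' the ROI whose polygon centroid is nearest (ties to the lowest ROI id).
#' Per-ROI counts plus the unassigned count always total the number of
#' nuclei.
#'
#' @param nuclei A `nucleus_set` from [segment_nuclei()] / [find_particles()],
#'   or any data frame with `x`, `y` columns.
#' @param rois A [roi_set()].
#' @return A `roi_assignment`: list with `counts` (tibble
#'   `roi_id, emhc_positive, n_nuclei`), `unassigned`, `total`, and
#'   `roi_of_nucleus` (per-nucleus ROI id, `NA` when unassigned).
#' @export
assign_nuclei_to_rois <- function(nuclei, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (inherits(nuclei, "nucleus_set")) {
    nw <- attr(nuclei, "field_width_px"); nh <- attr(nuclei, "field_height_px")
    rw <- attr(rois, "field_width_px"); rh <- attr(rois, "field_height_px")
    if (!is.na(nw) && !is.na(rw) && (nw != rw || nh != rh)) {
      abort("nuclei and ROIs come from fields of different dimensions")
    }
  }
  x <- nuclei$x; y <- nuclei$y
  n <- length(x)
  roi_of <- rep(NA_integer_, n)
  if (nrow(rois) > 0 && n > 0) {
    inside <- vapply(rois$polygon, function(p) point_in_polygon(x, y, p),
                     logical(n))
    inside <- matrix(inside, nrow = n) # n x n_roi
    cents <- t(vapply(rois$polygon, polygon_centroid, numeric(2)))
    for (i in seq_len(n)) {
      hits <- which(inside[i, ])
      if (length(hits) == 1) {
        roi_of[i] <- rois$roi_id[hits]
      } else if (length(hits) > 1) {
        d2 <- (cents[hits, 1] - x[i])^2 + (cents[hits, 2] - y[i])^2
        best <- hits[d2 == min(d2)]
        roi_of[i] <- min(rois$roi_id[best]) # tie: lowest ROI id
      }
    }
  }
  counts <- tibble::tibble(
    roi_id = rois$roi_id,
    emhc_positive = rois$emhc_positive,
    n_nuclei = vapply(rois$roi_id, function(id) sum(roi_of == id, na.rm = TRUE), 0L)
  )
  structure(list(counts = counts,
                 unassigned = sum(is.na(roi_of)),
                 total = n,
                 roi_of_nucleus = roi_of),
            class = "roi_assignment")
}

#' Nuclei density per square millimeter
#'
#' Total nucleus count normalized to the imaged surface:
#' `count / (width * height * pixel_size_um^2)`, converted to nuclei per mm^2
#' (1 mm^2 = 1e6 um^2).
#'
#' @param nuclei A `nucleus_set` carrying field dimensions and pixel size, or
#'   a data frame plus explicit `width`, `height`, `pixel_size_um`.
#' @param width,height,pixel_size_um Overrides for the field metadata.
#' @return Nuclei per mm^2 (numeric scalar).
#' @export
nuclei_density <- function(nuclei, width = attr(nuclei, "field_width_px"),
                           height = attr(nuclei, "field_height_px"),
                           pixel_size_um = attr(nuclei, "pixel_size_um")) {
  if (is.null(width) || is.null(height) || is.null(pixel_size_um) ||
      is.na(width) || is.na(height) || is.na(pixel_size_um)) {
    abort("field dimensions and pixel size are required")
  }
  area_mm2 <- width * height * pixel_size_um^2 / 1e6
  if (area_mm2 <= 0) abort("imaged area must be > 0")
  nrow(nuclei) / area_mm2
}

#' Differentiation index
#'
#' Fraction of all nuclei residing in eMHC-positive cells: the count of
#' nuclei assigned to eMHC-positive ROIs (mono- or multinucleated) over the
#' total nucleus count. Returns 0 with a warning when no nuclei were
#' detected.
#'
#' @param assignment A [assign_nuclei_to_rois()] result.
#' @return Numeric in `[0, 1]`.
#' @export
differentiation_index <- function(assignment) {
  stopifnot(inherits(assignment, "roi_assignment"))
  if (assignment$total == 0) {
    warn("no nuclei: differentiation index undefined, returning 0")
    return(0)
  }
  sum(assignment$counts$n_nuclei[assignment$counts$emhc_positive]) / assignment$total
}

fusion_bins <- tibble::tibble(
  bin = factor(c("2-14", "15-49", ">=50"), levels = c("2-14", "15-49", ">=50")),
  lo = c(2, 15, 50), hi = c(14, 49, Inf)
)

#' Nuclei-per-myotube distribution and size-class fractions
#'
#' A myotube is operationally an eMHC-positive ROI containing at least 2
#' nuclei. Summarizes the multiset of per-myotube nucleus counts by its
#' median and log2(median), and by the fraction of myotubes in the size
#' classes 2–14, 15–49 and >= 50 nuclei (a partition of `[2, Inf)`).
#'
#' @param assignment A [assign_nuclei_to_rois()] result.
#' @return List with `myotube_counts` (integer vector),
#'   `median_nuclei_per_myotube`, `log2_median`, and `bin_fractions` (tibble
#'   `bin, n, fraction`). With no qualifying myotube the summaries are `NA`
#'   with a warning and fractions are `NaN`.
#' @export
fusion_distribution <- function(assignment) {
  stopifnot(inherits(assignment, "roi_assignment"))
  cnt <- assignment$counts
  counts <- cnt$n_nuclei[cnt$emhc_positive & cnt$n_nuclei >= 2]
  if (length(counts) == 0) {
    warn("no eMHC-positive region with >= 2 nuclei: fusion distribution undefined")
    med <- NA_real_
  } else {
    med <- median(counts)
  }
  bins <- dplyr::mutate(
    fusion_bins,
    n = vapply(seq_len(nrow(fusion_bins)),
               function(i) sum(counts >= fusion_bins$lo[i] & counts <= fusion_bins$hi[i]),
               0L),
    fraction = .data$n / length(counts)
  )
  list(myotube_counts = as.integer(counts),
       median_nuclei_per_myotube = med,
       log2_median = if (is.na(med)) NA_real_ else log2(med),
       bin_fractions = bins[, c("bin", "lo", "hi", "n", "fraction")])
}

#' Two-group comparison (Student t or rank-sum)
#'
#' The two statistics used throughout fusion phenotyping: a two-sample
#' pooled-variance Student t-test for metrics that are approximately normal
#' (total nuclei, differentiation index), and the two-sided two-sample
#' Wilcoxon rank-sum (Mann–Whitney) test for skewed fusion metrics such as
#' nuclei-per-myotube counts. The rank-sum p-value is exact — computed by
#' full enumeration of rank assignments, with midranks for ties — whenever
#' `n_a + n_b <= 12`, and otherwise uses the normal approximation with
#' continuity and tie correction.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each for the t-test,
#'   >= 1 for the rank-sum test).
#' @param test_name `"student_t"` or `"wilcoxon_rank_sum"`.
#' @param welch Use the Welch (unequal-variance) t-test instead of pooled.
#' @return A `group_comparison`: list with `test_name`, `statistic`
#'   (t statistic, or Mann–Whitney U of group A), `p_value`, `n_a`, `n_b`,
#'   `two_sided = TRUE`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6), "wilcoxon_rank_sum")$p_value # 0.1
#' @export
compare_groups <- function(values_a, values_b,
                           test_name = c("student_t", "wilcoxon_rank_sum"),
                           welch = FALSE) {
  test_name <- match.arg(test_name)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (anyNA(a) || anyNA(b)) abort("missing values are not allowed")
  if (test_name == "student_t") {
    if (length(a) < 2 || length(b) < 2) {
      abort("student_t requires >= 2 values per group")
    }
    ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    if (length(a) < 1 || length(b) < 1) {
      abort("wilcoxon_rank_sum requires >= 1 value per group")
    }
    rs <- rank_sum_test(a, b)
    stat <- rs$u; p <- rs$p
  }
  structure(list(test_name = test_name, statistic = stat, p_value = p,
                 n_a = length(a), n_b = length(b), two_sided = TRUE),
            class = "group_comparison")
}

# two-sided Mann-Whitney with midrank ties; exact by enumeration when
# n <= 12, normal approximation with continuity + tie correction otherwise
rank_sum_test <- function(a, b, exact_limit = 12L) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b)) # midranks
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_limit) {
    combs <- utils::combn(n, na)
    us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(u = u_obs, p = p)
}

#' Build a per-field fusion report
#'
#' Composes the fusion phenotyping metrics for one imaged field: total
#' nuclei, imaged area and nuclei density, differentiation index,
#' nuclei-per-myotube distribution with size-class fractions.
#'
#' @param nuclei A `nucleus_set` (detected or ground-truth centroids).
#' @param rois A [roi_set()].
#' @return A `fusion_report` object; see [tidy.fusion_report()] and
#'   [glance.fusion_report()] for tabular views.
#' @export
build_fusion_report <- function(nuclei, rois) {
  assignment <- assign_nuclei_to_rois(nuclei, rois)
  px <- attr(nuclei, "pixel_size_um") %||% attr(rois, "pixel_size_um")
  w <- attr(nuclei, "field_width_px") %||% attr(rois, "field_width_px")
  h <- attr(nuclei, "field_height_px") %||% attr(rois, "field_height_px")
  dens <- nuclei_density(nuclei, width = w, height = h, pixel_size_um = px)
  di <- differentiation_index(assignment)
  fd <- suppressWarnings(fusion_distribution(assignment))
  structure(list(
    total_nuclei = assignment$total,
    imaged_area_mm2 = w * h * px^2 / 1e6,
    nuclei_density_mm2 = dens,
    nuclei_in_emhc_positive = sum(assignment$counts$n_nuclei[assignment$counts$emhc_positive]),
    differentiation_index = di,
    myotube_counts = fd$myotube_counts,
    median_nuclei_per_myotube = fd$median_nuclei_per_myotube,
    log2_median = fd$log2_median,
    bin_fractions = fd$bin_fractions,
    assignment = assignment
  ), class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat(sprintf(
    paste0("<fusion_report> %d nuclei over %.4g mm^2 (%.4g /mm^2)\n",
           "  differentiation index %.3f; %d myotubes (median %.4g nuclei, log2 %.3g)\n"),
    x$total_nuclei, x$imaged_area_mm2, x$nuclei_density_mm2,
    x$differentiation_index, length(x$myotube_counts),
    x$median_nuclei_per_myotube, x$log2_median))
  print(x$bin_fractions[, c("bin", "n", "fraction")])
  invisible(x)
}

#' Tidy a fusion report into a per-myotube table
#'
#' @param x A `fusion_report`.
#' @param ... Unused.
#' @return Tibble `roi_id, emhc_positive, n_nuclei, is_myotube` — one row per
#'   ROI.
#' @export
tidy.fusion_report <- function(x, ...) {
  dplyr::mutate(x$assignment$counts,
                is_myotube = .data$emhc_positive & .data$n_nuclei >= 2)
}

#' One-row summary of a fusion report
#'
#' @param x A `fusion_report`.
#' @param ... Unused.
#' @return One-row tibble with the headline metrics and bin fractions.
#' @export
glance.fusion_report <- function(x, ...) {
  bf <- setNames(as.list(x$bin_fractions$fraction),
                 paste0("frac_", c("2_14", "15_49", "ge50")))
  tibble::tibble(
    total_nuclei = x$total_nuclei,
    imaged_area_mm2 = x$imaged_area_mm2,
    nuclei_density_mm2 = x$nuclei_density_mm2,
    nuclei_in_emhc_positive = x$nuclei_in_emhc_positive,
    differentiation_index = x$differentiation_index,
    n_myotubes = length(x$myotube_counts),
    median_nuclei_per_myotube = x$median_nuclei_per_myotube,
    log2_median = x$log2_median,
    !!!bf
  )
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p_value = x$p_value, n_a = x$n_a, n_b = x$n_b)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g (n = %d vs %d)\n",
              x$test_name, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
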