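make_nuclei <- function(x, y, w = 100L, h = 100L, px = 1) {
  ns <- tibble::tibble(label = seq_along(x), x = x, y = y,
                       area_px = rep(50L, length(x)))
  structure(ns, class = c("nucleus_set", class(tibble::tibble())),
            field_width_px = w, field_height_px = h, pixel_size_um = px)
}

square_roi <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

test_that("nuclei are assigned by centroid-in-polygon with a correct unassigned count", {
  rois <- roi_set(list(square_roi(0, 0, 10)), TRUE, 100, 100, 1)
  a <- assign_nuclei_to_rois(make_nuclei(c(5, 20), c(5, 20)), rois)
  expect_equal(a$counts$n_nuclei, 1L)
  expect_equal(a$unassigned, 1L)
  expect_equal(a$total, 2L)
})

test_that("with zero ROIs every nucleus is unassigned", {
  rois <- roi_set(list(), logical(0), 100, 100, 1)
  a <- assign_nuclei_to_rois(make_nuclei(c(5, 20), c(5, 20)), rois)
  expect_equal(nrow(a$counts), 0)
  expect_equal(a$unassigned, 2L)
})

test_that("assignment agrees with the winding-number oracle on random fields", {
  set.seed(101)
  polys <- lapply(1:5, function(i) {
    random_convex_polygon(runif(2, 15, 85), runif(1, 6, 14))
  })
  rois <- roi_set(polys, rep(TRUE, 5), 100, 100, 1)
  px <- runif(200, 0, 100); py <- runif(200, 0, 100)
  a <- assign_nuclei_to_rois(make_nuclei(px, py), rois)
  inside_any <- rep(FALSE, 200)
  for (k in 1:5) {
    oracle_in <- oracle_winding_inside(px, py, polys[[k]])
    # every point the oracle puts uniquely in polygon k is assigned to it
    only_k <- oracle_in
    for (j in setdiff(1:5, k)) {
      only_k <- only_k & !oracle_winding_inside(px, py, polys[[j]])
    }
    expect_true(all(a$roi_of_nucleus[only_k] == k))
    inside_any <- inside_any | oracle_in
  }
  expect_equal(a$unassigned, sum(!inside_any))
  # conservation: counts + unassigned = total
  expect_equal(sum(a$counts$n_nuclei) + a$unassigned, 200)
})

test_that("a nucleus in overlapping ROIs goes to the nearest ROI centroid, ties to lowest id", {
  overlapping <- list(square_roi(0, 0, 10), square_roi(4, 0, 10))
  rois <- roi_set(overlapping, c(TRUE, TRUE), 100, 100, 1)
  a <- assign_nuclei_to_rois(make_nuclei(c(6, 8), c(5, 5)), rois)
  # centroids at x = 5 and x = 9: point at 6 -> ROI 1, point at 8 -> ROI 2
  expect_equal(a$roi_of_nucleus, c(1L, 2L))
  # exact midpoint (x = 7) ties -> lowest id
  tie <- assign_nuclei_to_rois(make_nuclei(7, 5), rois)
  expect_equal(tie$roi_of_nucleus, 1L)
})

test_that("nuclei density converts pixel counts to per-mm^2", {
  # 1000 x 1000 px at 1 um/px = exactly 1 mm^2
  ns <- make_nuclei(runif(100, 0, 999), runif(100, 0, 999), 1000L, 1000L, 1)
  expect_equal(nuclei_density(ns), 100)
  # doubling the pixel size quadruples the area, quartering the density
  expect_equal(nuclei_density(ns, pixel_size_um = 2), 25)
})

test_that("field density equals the area-weighted mean over a 2x2 tiling", {
  set.seed(3)
  x <- runif(80, 0, 200); y <- runif(80, 0, 100)
  full <- nuclei_density(make_nuclei(x, y, 200L, 100L, 0.5))
  tiles <- c(
    nuclei_density(make_nuclei(x[x < 100 & y < 50], y[x < 100 & y < 50], 100L, 50L, 0.5)),
    nuclei_density(make_nuclei(x[x >= 100 & y < 50], y[x >= 100 & y < 50], 100L, 50L, 0.5)),
    nuclei_density(make_nuclei(x[x < 100 & y >= 50], y[x < 100 & y >= 50], 100L, 50L, 0.5)),
    nuclei_density(make_nuclei(x[x >= 100 & y >= 50], y[x >= 100 & y >= 50], 100L, 50L, 0.5))
  )
  expect_equal(full, mean(tiles)) # equal-area tiles
})

test_that("differentiation index is the eMHC-positive fraction of nuclei", {
  rois <- roi_set(list(square_roi(0, 0, 40), square_roi(50, 50, 40)),
                  c(TRUE, FALSE), 100, 100, 1)
  # 30 nuclei in the positive ROI, 90 elsewhere
  x <- c(runif(30, 5, 35), runif(40, 55, 85), runif(50, 5, 35))
  y <- c(runif(30, 5, 35), runif(40, 55, 85), runif(50, 92, 99))
  a <- assign_nuclei_to_rois(make_nuclei(x, y), rois)
  expect_equal(differentiation_index(a), 30 / 120)
  # all inside positive ROIs -> 1; none -> 0
  all_in <- assign_nuclei_to_rois(make_nuclei(runif(10, 5, 35), runif(10, 5, 35)), rois)
  expect_equal(differentiation_index(all_in), 1)
  neg_only <- roi_set(list(square_roi(0, 0, 40)), FALSE, 100, 100, 1)
  none <- assign_nuclei_to_rois(make_nuclei(runif(10, 5, 35), runif(10, 5, 35)), neg_only)
  expect_equal(differentiation_index(none), 0)
})

test_that("fusion distribution summarizes counts >= 2 with the stated bins", {
  counts <- tibble::tibble(roi_id = 1:5, emhc_positive = TRUE,
                           n_nuclei = c(1L, 2L, 3L, 50L, 60L))
  a <- structure(list(counts = counts, unassigned = 0L, total = 116L,
                      roi_of_nucleus = integer(0)), class = "roi_assignment")
  fd <- fusion_distribution(a)
  expect_setequal(fd$myotube_counts, c(2L, 3L, 50L, 60L))
  expect_equal(fd$median_nuclei_per_myotube, 26.5)
  expect_equal(fd$bin_fractions$fraction, c(0.5, 0, 0.5))
  # all twos: median 2, log2 median 1
  a2 <- a; a2$counts$n_nuclei <- rep(2L, 5)
  fd2 <- fusion_distribution(a2)
  expect_equal(fd2$log2_median, 1)
})

test_that("bin fractions always sum to 1 and match direct interval membership", {
  set.seed(6)
  for (k in 1:10) {
    n <- sample(1:30, 1)
    cts <- sample(2:80, n, replace = TRUE)
    a <- structure(list(
      counts = tibble::tibble(roi_id = seq_len(n), emhc_positive = TRUE,
                              n_nuclei = as.integer(cts)),
      unassigned = 0L, total = sum(cts), roi_of_nucleus = integer(0)),
      class = "roi_assignment")
    fd <- fusion_distribution(a)
    expect_equal(sum(fd$bin_fractions$fraction), 1)
    expect_equal(fd$bin_fractions$n,
                 c(sum(cts >= 2 & cts <= 14), sum(cts >= 15 & cts <= 49),
                   sum(cts >= 50)))
  }
})

test_that("median nuclei per myotube is monotone in the counts", {
  set.seed(4)
  cts <- sample(2:40, 12, replace = TRUE)
  mk <- function(v) {
    a <- structure(list(
      counts = tibble::tibble(roi_id = seq_along(v), emhc_positive = TRUE,
                              n_nuclei = as.integer(v)),
      unassigned = 0L, total = sum(v), roi_of_nucleus = integer(0)),
      class = "roi_assignment")
    fusion_distribution(a)$median_nuclei_per_myotube
  }
  expect_gte(mk(cts + 3L), mk(cts))
})

test_that("the t-test gives t = 0, p = 1 on identical groups and the rank-sum example is exact", {
  ident <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4), "student_t")
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  rs <- compare_groups(c(1, 2, 3), c(4, 5, 6), "wilcoxon_rank_sum")
  expect_equal(rs$p_value, 0.1) # 2 of the 20 rank splits are as extreme
})

test_that("exact rank-sum p equals full enumeration on random small samples", {
  set.seed(15)
  for (k in 1:10) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:8, na, replace = TRUE) # ties likely
    b <- sample(1:8, nb, replace = TRUE)
    got <- compare_groups(a, b, "wilcoxon_rank_sum")
    expect_equal(got$p_value, oracle_ranksum_p(a, b))
  }
})

test_that("rank-sum agrees with wilcox.test on tie-free data in both regimes", {
  set.seed(16)
  a <- rnorm(5); b <- rnorm(6) + 1          # exact regime, no ties
  expect_equal(compare_groups(a, b, "wilcoxon_rank_sum")$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value)
  a2 <- rnorm(20); b2 <- rnorm(25) + 0.5    # approximation regime
  expect_equal(compare_groups(a2, b2, "wilcoxon_rank_sum")$p_value,
               wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("insufficient samples raise errors naming the test", {
  expect_error(compare_groups(1, c(2, 3), "student_t"), "student_t")
  expect_error(compare_groups(numeric(0), 1, "wilcoxon_rank_sum"), "wilcoxon")
})

test_that("a ground-truth report reproduces the planted phenotype exactly", {
  sc <- generate_scene(small_scene_params(seed = 31L))
  img <- render_scene(sc, noiseless_rp())
  ns <- segment_nuclei(img, small_seg_config())
  rep <- build_fusion_report(ns, scene_rois(sc))
  truth_counts <- sort(vapply(sc$myotubes, function(m) nrow(m$nuclei), 1L))
  n_truth <- scene_nucleus_count(sc)
  di_truth <- (sum(truth_counts) + sum(sc$mono_cells$emhc_positive)) / n_truth
  expect_equal(rep$total_nuclei, n_truth)
  expect_equal(sort(rep$myotube_counts), as.integer(truth_counts))
  expect_equal(rep$differentiation_index, di_truth)
  expect_equal(rep$nuclei_in_emhc_positive,
               sum(truth_counts) + sum(sc$mono_cells$emhc_positive))
  g <- glance(rep)
  expect_equal(g$total_nuclei, n_truth)
  expect_equal(sum(tidy(rep)$is_myotube), length(truth_counts))
})

test_that("a field of eMHC-negative mono cells has zero differentiation and no myotubes", {
  sc <- generate_scene(scene_params(n_myotubes = 0L, n_mononucleated = 10L,
                                    fraction_mono_emhc_positive = 0,
                                    field_width_px = 200L, field_height_px = 200L,
                                    seed = 41L))
  img <- render_scene(sc, noiseless_rp())
  ns <- segment_nuclei(img, small_seg_config())
  expect_warning(rep <- build_fusion_report(ns, scene_rois(sc)), NA)
  expect_equal(rep$differentiation_index, 0)
  expect_length(rep$myotube_counts, 0)
  expect_true(is.na(rep$median_nuclei_per_myotube))
})

test_that("two conditions differing in fusion are detected by the rank-sum comparison", {
  # geometric mean ~5 vs ~15 nuclei per tube, 100 myotubes per condition
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    a <- sample_nuclei_per_myotube(sampler_geometric(5), 100)
    b <- sample_nuclei_per_myotube(sampler_geometric(15), 100)
    if (compare_groups(a, b, "wilcoxon_rank_sum")$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19) # >= 95% of 20 seeds
})
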