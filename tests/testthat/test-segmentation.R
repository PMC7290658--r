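test_that("rolling ball leaves a flat image exactly zero", {
  img <- matrix(17.3, 12, 15)
  out <- rolling_ball_background_subtract(img, 4)
  expect_equal(out, matrix(0, 12, 15))
})

test_that("an isolated impulse loses only the hand-derived ball-cap height", {
  # erosion of an impulse by the spherical-cap SE, then dilation, gives an
  # opening of r - sqrt(r^2 - 1) at the impulse pixel (worked by hand from
  # the min/max definitions), so the subtracted image keeps v minus that cap
  for (r in c(2, 5)) {
    img <- matrix(0, 21, 21); img[11, 11] <- 1000
    out <- rolling_ball_background_subtract(img, r)
    expect_equal(out[11, 11], 1000 - (r - sqrt(r^2 - 1)), tolerance = 1e-9)
    expect_lte(max(out), 1000)
  }
})

test_that("rolling ball equals brute-force grayscale opening on random rasters", {
  set.seed(31)
  for (k in 1:4) {
    img <- matrix(runif(256, 0, 100), 16, 16)
    r <- sample(c(2, 3.5, 5), 1)
    expect_equal(rolling_ball_background_subtract(img, r),
                 oracle_rolling_ball(img, r), tolerance = 1e-10)
  }
})

test_that("rolling-ball output is anti-extensive: within [0, input] everywhere", {
  set.seed(8)
  for (k in 1:5) {
    img <- matrix(runif(400, 0, 2^16), 20, 20)
    out <- rolling_ball_background_subtract(img, runif(1, 1, 8))
    expect_true(all(out >= 0))
    expect_true(all(out <= img + 1e-9))
  }
})

test_that("Otsu separates a two-level raster at the known fraction", {
  img <- matrix(10, 20, 20)
  img[sample(400, 160)] <- 200 # 40% bright
  th <- otsu_threshold(img)
  expect_gt(th$threshold, 10)
  expect_lt(th$threshold, 200)
  expect_equal(mean(th$mask), 0.4)
})

test_that("Otsu on a constant raster warns and returns an empty mask", {
  img <- matrix(42, 8, 8)
  expect_warning(th <- otsu_threshold(img), "constant")
  expect_true(is.na(th$threshold))
  expect_false(any(th$mask))
})

test_that("Otsu equals the exhaustive 256-cut scan and shifts with the data", {
  set.seed(12)
  for (k in 1:5) {
    img <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
    th <- otsu_threshold(img)
    expect_equal(th$threshold, oracle_otsu_threshold(img), tolerance = 1e-9)
    # adding a constant shifts the chosen threshold by exactly that constant
    shift <- 37.5
    th2 <- otsu_threshold(img + shift)
    expect_equal(th2$threshold, th$threshold + shift, tolerance = 1e-9)
    expect_identical(th2$mask, th$mask)
  }
})

test_that("cleanup fills interior holes and removes isolated specks", {
  cfg <- segmentation_config(opening_radius_px = 1L)
  blob <- matrix(FALSE, 12, 12)
  blob[3:9, 3:9] <- TRUE
  blob[6, 6] <- FALSE            # interior 1-px hole
  blob[1, 12] <- TRUE            # isolated speck
  out <- clean_mask(blob, cfg)
  expect_true(out[6, 6])
  expect_false(out[1, 12])
  # idempotence on this structured mask
  expect_identical(clean_mask(out, cfg), out)
})

test_that("cleanup respects its switches", {
  blob <- matrix(FALSE, 8, 8); blob[2:6, 2:6] <- TRUE; blob[4, 4] <- FALSE
  keep_holes <- clean_mask(blob, segmentation_config(fill_holes = FALSE,
                                                     opening_radius_px = 0L))
  expect_identical(keep_holes, blob)
})

test_that("particle analysis finds disjoint squares with exact centroids and areas", {
  mask <- matrix(FALSE, 30, 40)
  origins <- list(c(2, 2), c(2, 20), c(20, 8))
  for (o in origins) mask[o[1]:(o[1] + 4), o[2]:(o[2] + 4)] <- TRUE
  cfg <- segmentation_config(min_area_px = 1L)
  ns <- find_particles(mask, cfg)
  expect_equal(nrow(ns), 3)
  expect_true(all(ns$area_px == 25))
  got <- ns[order(ns$x), ]
  centers <- t(vapply(origins, function(o) c(o[2] + 1.5, o[1] + 1.5), numeric(2)))
  centers <- centers[order(centers[, 1]), ]
  expect_equal(cbind(got$x, got$y), centers, ignore_attr = TRUE)
  # area filter removes everything when the floor exceeds 25 px
  expect_equal(nrow(find_particles(mask, segmentation_config(min_area_px = 26L))), 0)
})

test_that("labeling matches the flood-fill oracle for both connectivities", {
  set.seed(77)
  for (k in 1:4) {
    mask <- matrix(runif(30 * 30) < 0.25, 30, 30)
    for (conn in c(4L, 8L)) {
      cfg <- segmentation_config(min_area_px = 0L, connectivity = conn)
      ns <- find_particles(mask, cfg)
      lab <- oracle_label_components(mask, conn)
      expect_equal(nrow(ns), max(lab))
      # per-component areas and centroids agree
      for (l in seq_len(max(lab))) {
        px <- which(lab == l, arr.ind = TRUE)
        row <- ns[ns$label == l, ]
        expect_equal(row$area_px, nrow(px))
        expect_equal(row$x, mean(px[, "col"] - 0.5))
        expect_equal(row$y, mean(px[, "row"] - 0.5))
      }
    }
  }
})

test_that("particle count is invariant under translation away from borders", {
  set.seed(5)
  mask <- matrix(FALSE, 40, 40)
  mask[10:14, 10:13] <- TRUE; mask[25:26, 30:33] <- TRUE; mask[33, 7:9] <- TRUE
  idx <- which(mask, arr.ind = TRUE)
  shifted <- matrix(FALSE, 40, 40)
  shifted[cbind(idx[, 1] + 3, idx[, 2] + 2)] <- TRUE
  cfg <- segmentation_config(min_area_px = 0L)
  expect_equal(nrow(find_particles(shifted, cfg)), nrow(find_particles(mask, cfg)))
})

test_that("noiseless renders segment to the exact ground truth", {
  sc <- generate_scene(small_scene_params(seed = 21L))
  img <- render_scene(sc, noiseless_rp())
  ns <- segment_nuclei(img, small_seg_config())
  truth <- scene_nuclei(sc)
  expect_equal(nrow(ns), nrow(truth))
  expect_equal(match_count(ns, truth, 1.0), nrow(truth))
})

test_that("an all-zero DAPI channel yields an empty particle set with a warning", {
  z <- matrix(0, 50, 50)
  stack <- image_stack(z, z, pixel_size_um = 0.25)
  expect_warning(ns <- segment_nuclei(stack, small_seg_config()), "constant")
  expect_equal(nrow(ns), 0)
})

test_that("default-noise renders keep recall and precision at >= 0.95", {
  sc <- generate_scene(scene_params(
    field_width_px = 300L, field_height_px = 300L, n_myotubes = 3L,
    n_mononucleated = 20L, nuclei_per_myotube_sampler = sampler_fixed(c(8L, 12L, 10L)),
    seed = 13L))
  img <- render_scene(sc, render_params(seed = 14L))
  ns <- segment_nuclei(img, segmentation_config(rolling_ball_radius_px = 25))
  truth <- scene_nuclei(sc)
  matched <- match_count(ns, truth, 1.5)
  expect_gte(matched / nrow(truth), 0.95)
  expect_gte(matched / nrow(ns), 0.95)
})

test_that("segmentation is deterministic", {
  sc <- generate_scene(small_scene_params(seed = 2L))
  img <- render_scene(sc, render_params(seed = 5L))
  cfg <- small_seg_config()
  expect_identical(serialize(segment_nuclei(img, cfg), NULL),
                   serialize(segment_nuclei(img, cfg), NULL))
})
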