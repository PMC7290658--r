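#' Segmentation configuration
#'
#' Parameters for the nuclei-detection chain: rolling-ball background
#' subtraction, automatic global thresholding, binary cleanup and particle
#' analysis. Defaults follow common ImageJ practice: ball radius 50 px,
#' 8-connectivity, minimum particle area 20 px^2, no upper area bound.
#'
#' @param rolling_ball_radius_px Radius of the rolling-ball structuring
#'   element (> 0).
#' @param threshold_method Automatic threshold; only `"otsu"` is implemented.
#' @param opening_radius_px Disk radius for the binary opening in cleanup
#'   (0 disables).
#' @param fill_holes Fill enclosed background holes before opening?
#' @param min_area_px,max_area_px Inclusive particle area bounds in pixels.
#' @param connectivity 4 or 8 (pixel adjacency for particle labeling).
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(rolling_ball_radius_px = 50,
                                threshold_method = "otsu",
                                opening_radius_px = 1L,
                                fill_holes = TRUE,
                                min_area_px = 20L,
                                max_area_px = Inf,
                                connectivity = 8L) {
  threshold_method <- match.arg(threshold_method, "otsu")
  if (rolling_ball_radius_px <= 0) abort("`rolling_ball_radius_px` must be > 0")
  if (opening_radius_px < 0) abort("`opening_radius_px` must be >= 0")
  if (min_area_px < 0) abort("`min_area_px` must be >= 0")
  if (min_area_px > max_area_px) abort("`min_area_px` must be <= `max_area_px`")
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8")
  structure(list(
    rolling_ball_radius_px = rolling_ball_radius_px,
    threshold_method = threshold_method,
    opening_radius_px = as.integer(opening_radius_px),
    fill_holes = isTRUE(fill_holes),
    min_area_px = min_area_px,
    max_area_px = max_area_px,
    connectivity = as.integer(connectivity)
  ), class = "segmentation_config")
}

# structuring-element offsets for a disk of given radius (flat)
disk_se <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  keep <- g$dx^2 + g$dy^2 <= radius^2
  list(dx = as.integer(g$dx[keep]), dy = as.integer(g$dy[keep]),
       h = rep(0, sum(keep)))
}

# spherical-cap structuring element: heights sqrt(r^2 - d^2) over a disk
ball_se <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- g$dx^2 + g$dy^2
  keep <- d2 <= radius^2
  list(dx = as.integer(g$dx[keep]), dy = as.integer(g$dy[keep]),
       h = sqrt(radius^2 - d2[keep]))
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth image background as the grayscale morphological
#' opening of the raster by a ball-shaped (spherical-cap) structuring element
#' of the given radius — the surface traced by a ball rolling under the
#' intensity landscape — and subtracts it. Features narrower than the ball
#' survive essentially intact; broad background variation is removed. The
#' output is non-negative and nowhere exceeds the input.
#'
#' @param raster Numeric matrix.
#' @param radius_px Ball radius in pixels (> 0).
#' @return Numeric matrix, same dimension: `raster - opening(raster)`.
#' @export
rolling_ball_background_subtract <- function(raster, radius_px) {
  if (!is.matrix(raster) || length(raster) == 0) abort("`raster` must be a non-empty matrix")
  if (!is.numeric(radius_px) || length(radius_px) != 1 || radius_px <= 0) {
    abort("`radius_px` must be a single positive number")
  }
  se <- ball_se(radius_px)
  bg <- cpp_gray_dilate(cpp_gray_erode(raster, se$dx, se$dy, se$h),
                        se$dx, se$dy, se$h)
  out <- raster - pmin(bg, raster) # guard fp jitter; opening <= raster in exact arithmetic
  out
}

#' Otsu automatic threshold
#'
#' Histograms the raster into 256 equal-width bins spanning its value range
#' and picks the inter-bin cut maximizing between-class variance (lowest such
#' cut on ties). Works unchanged for 8- and 16-bit data, because binning is
#' over the observed range.
#'
#' @param raster Numeric matrix.
#' @return List with `threshold` (numeric; `NA` for a constant raster, with a
#'   warning) and `mask` (`raster > threshold`; all-`FALSE` when constant).
#' @export
otsu_threshold <- function(raster) {
  if (!is.matrix(raster) || length(raster) == 0) abort("`raster` must be a non-empty matrix")
  lo <- min(raster); hi <- max(raster)
  if (hi <= lo) {
    warn("constant raster: no foreground separable; returning an empty mask")
    return(list(threshold = NA_real_,
                mask = matrix(FALSE, nrow(raster), ncol(raster))))
  }
  nbins <- 256L
  bin <- pmin(nbins - 1L, floor((raster - lo) / (hi - lo) * nbins))
  h <- as.numeric(tabulate(as.integer(bin) + 1L, nbins))
  n <- sum(h)
  mids <- seq_len(nbins) - 1
  w0 <- cumsum(h)[-nbins]                     # class sizes for cuts k = 0..254
  s0 <- cumsum(h * mids)[-nbins]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(h * mids) - s0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(bcv) - 1L                    # lowest maximizer
  threshold <- lo + (k + 1) * (hi - lo) / nbins
  list(threshold = threshold, mask = raster > threshold)
}

#' Binary mask cleanup
#'
#' Fills enclosed background holes (background components not touching the
#' image border) and applies a morphological opening with a disk of
#' `opening_radius_px`, removing specks smaller than the disk.
#'
#' @param mask Logical matrix.
#' @param config A [segmentation_config()].
#' @return Logical matrix.
#' @export
clean_mask <- function(mask, config = segmentation_config()) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix")
  out <- mask
  if (config$fill_holes) out <- cpp_fill_holes(out)
  if (config$opening_radius_px > 0) {
    se <- disk_se(config$opening_radius_px)
    num <- cpp_gray_dilate(
      cpp_gray_erode(out + 0, se$dx, se$dy, se$h), se$dx, se$dy, se$h)
    out <- num > 0.5
  }
  out
}

#' Particle analysis of a binary mask
#'
#' Labels connected components under the configured connectivity, discards
#' components with area outside `[min_area_px, max_area_px]`, and reports
#' each surviving particle's pixel area and centroid (arithmetic mean of
#' member-pixel centres, image coordinate frame: origin top-left, pixel
#' centre at `(col + 0.5, row + 0.5)` with 0-based col/row).
#'
#' @param mask Logical matrix.
#' @param config A [segmentation_config()].
#' @param pixel_size_um Micrometers per pixel, carried into the result.
#' @return A `nucleus_set`: tibble `label, x, y, area_px` with field
#'   dimensions and pixel size in attributes.
#' @export
find_particles <- function(mask, config = segmentation_config(),
                           pixel_size_um = NA_real_) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix")
  lab <- cpp_label_components(mask, config$connectivity)
  keep_lab <- integer(0); xs <- ys <- areas <- numeric(0)
  if (max(lab) > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    areas_all <- tabulate(l)
    xs_all <- vapply(split((idx[, "col"] - 0.5), l), mean, 0)
    ys_all <- vapply(split((idx[, "row"] - 0.5), l), mean, 0)
    ok <- areas_all >= config$min_area_px & areas_all <= config$max_area_px
    keep_lab <- which(ok); xs <- xs_all[ok]; ys <- ys_all[ok]; areas <- areas_all[ok]
  }
  new_nucleus_set(
    tibble::tibble(label = as.integer(keep_lab), x = unname(xs), y = unname(ys),
                   area_px = as.integer(areas)),
    width = ncol(mask), height = nrow(mask), pixel_size_um = pixel_size_um
  )
}

new_nucleus_set <- function(tbl, width, height, pixel_size_um) {
  structure(tbl,
            class = c("nucleus_set", class(tibble::tibble()))
            , field_width_px = as.integer(width)
            , field_height_px = as.integer(height)
            , pixel_size_um = as.numeric(pixel_size_um))
}

#' Segment nuclei from the DAPI channel
#'
#' The full detection chain of the quantification pipeline: rolling-ball
#' background subtraction, Otsu thresholding, binary cleanup, particle
#' analysis. Deterministic for fixed input and configuration.
#'
#' @param stack An [image_stack()] with a `dapi` channel.
#' @param config A [segmentation_config()].
#' @return A `nucleus_set` tibble (`label, x, y, area_px`) with field
#'   metadata attributes.
#' @examples
#' sc <- generate_scene(scene_params(n_myotubes = 1, n_mononucleated = 3,
#'   field_width_px = 160, field_height_px = 160,
#'   nuclei_per_myotube_sampler = sampler_fixed(c(3))))
#' img <- render_scene(sc, render_params(psf_sigma_px = 0, noise = "none"))
#' segment_nuclei(img, segmentation_config(rolling_ball_radius_px = 20))
#' @export
segment_nuclei <- function(stack, config = segmentation_config()) {
  stopifnot(inherits(stack, "image_stack"))
  sub <- rolling_ball_background_subtract(stack$dapi, config$rolling_ball_radius_px)
  th <- otsu_threshold(sub)
  cleaned <- clean_mask(th$mask, config)
  find_particles(cleaned, config, pixel_size_um = stack$pixel_size_um)
}
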