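#' Rendering parameters for simulated two-channel images
#'
#' Controls how a ground-truth [scene][generate_scene()] is rasterized into a
#' DAPI (nuclear) and an eMHC (cytoplasmic) channel. Intensities are in raw
#' camera counts at the chosen bit depth. The default noise level (Gaussian,
#' sd = 5% of the DAPI peak) is visible but well below what would defeat a
#' global threshold between background and nuclei.
#'
#' @param dapi_peak_intensity Intensity of nucleus disks in the DAPI channel.
#' @param emhc_intensity Intensity of myotube/cell bodies in the eMHC channel.
#' @param background_level Constant additive offset on both channels.
#' @param psf_sigma_px Gaussian blur sigma (point-spread proxy); 0 disables.
#' @param noise One of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sd Gaussian noise standard deviation (ignored otherwise).
#' @param bit_depth 8 or 16.
#' @param clip If `TRUE`, values outside the representable range are clipped;
#'   if `FALSE` (default) overflow above the bit-depth maximum is an error.
#' @param seed Integer seed for the noise draw.
#' @return A `render_params` object.
#' @export
render_params <- function(dapi_peak_intensity = 30000,
                          emhc_intensity = 20000,
                          background_level = 1000,
                          psf_sigma_px = 1,
                          noise = c("gaussian", "none", "poisson"),
                          noise_sd = 0.05 * dapi_peak_intensity,
                          bit_depth = 16L,
                          clip = FALSE,
                          seed = 1L) {
  noise <- match.arg(noise)
  if (dapi_peak_intensity <= 0 || emhc_intensity <= 0) abort("intensities must be > 0")
  if (background_level < 0) abort("`background_level` must be >= 0")
  if (psf_sigma_px < 0) abort("`psf_sigma_px` must be >= 0")
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16")
  maxv <- 2^bit_depth - 1
  if (!clip && (background_level + max(dapi_peak_intensity, emhc_intensity)) > maxv) {
    abort("peak + background exceeds the bit-depth range; lower intensities or set clip = TRUE")
  }
  structure(list(
    dapi_peak_intensity = dapi_peak_intensity,
    emhc_intensity = emhc_intensity,
    background_level = background_level,
    psf_sigma_px = psf_sigma_px,
    noise = noise,
    noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth),
    clip = isTRUE(clip),
    seed = as.integer(seed)
  ), class = "render_params")
}

#' Two-channel image container
#'
#' @param dapi,emhc Numeric matrices of equal dimension (rows = y, cols = x).
#' @param pixel_size_um Micrometers per pixel.
#' @param bit_depth 8 or 16.
#' @return An `image_stack` object.
#' @export
image_stack <- function(dapi, emhc, pixel_size_um, bit_depth = 16L) {
  if (!identical(dim(dapi), dim(emhc))) abort("channels must have identical dimensions")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) abort("`pixel_size_um` must be > 0")
  maxv <- 2^bit_depth - 1
  if (min(dapi, emhc) < 0 || max(dapi, emhc) > maxv) {
    abort("channel values outside the bit-depth range")
  }
  structure(list(dapi = dapi, emhc = emhc,
                 pixel_size_um = as.numeric(pixel_size_um),
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d x %d px, %d-bit, %.3g um/px (channels: dapi, emhc)\n",
              ncol(x$dapi), nrow(x$dapi), x$bit_depth, x$pixel_size_um))
  invisible(x)
}

# logical matrix of pixels whose centres lie within `radius` of any centre
disk_mask <- function(h, w, centers, radius) {
  m <- matrix(FALSE, h, w)
  if (is.null(centers) || nrow(centers) == 0) return(m)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    jr <- max(1L, floor(cx - radius)):min(w, ceiling(cx + radius + 1))
    ir <- max(1L, floor(cy - radius)):min(h, ceiling(cy + radius + 1))
    px <- jr - 0.5; py <- ir - 0.5
    d2 <- outer((py - cy)^2, (px - cx)^2, `+`)
    m[ir, jr] <- m[ir, jr] | (d2 <= radius^2)
  }
  m
}

# logical matrix of pixels whose centres fall inside the polygon
polygon_mask <- function(h, w, polygon) {
  m <- matrix(FALSE, h, w)
  lo <- pmax(c(1, 1), floor(apply(polygon, 2, min)))
  hi <- pmin(c(w, h), ceiling(apply(polygon, 2, max)) + 1)
  if (any(lo > hi)) return(m)
  jr <- lo[1]:hi[1]; ir <- lo[2]:hi[2]
  g <- expand.grid(y = ir - 0.5, x = jr - 0.5)
  inside <- point_in_polygon(g$x, g$y, polygon)
  m[ir, jr] <- matrix(inside, length(ir), length(jr))
  m
}

#' Render a scene to a two-channel image
#'
#' The DAPI channel receives a filled disk of the scene's nucleus radius at
#' every nucleus centre; the eMHC channel receives the filled myotube
#' polygons plus the cell bodies of eMHC-positive mononucleated cells.
#' Foreground pixels are set to `background + intensity` (overlaps do not
#' add). Blur and noise are applied per [render_params()]; the scene's ground
#' truth is not modified.
#'
#' @param scene A [generate_scene()] result.
#' @param rp A [render_params()] object.
#' @return An [image_stack()].
#' @export
render_scene <- function(scene, rp = render_params()) {
  stopifnot(inherits(scene, "scene"), inherits(rp, "render_params"))
  H <- scene$field_height_px; W <- scene$field_width_px
  nuclei <- as.matrix(scene_nuclei(scene)[, c("x", "y")])

  dapi_fg <- disk_mask(H, W, nuclei, scene$nucleus_radius_px)
  emhc_fg <- matrix(FALSE, H, W)
  for (m in scene$myotubes) emhc_fg <- emhc_fg | polygon_mask(H, W, m$polygon)
  pos <- scene$mono_cells[scene$mono_cells$emhc_positive, , drop = FALSE]
  emhc_fg <- emhc_fg | disk_mask(H, W, as.matrix(pos[, c("x", "y")]),
                                 scene$mono_cell_radius_px)

  b <- rp$background_level
  dapi <- matrix(b, H, W); dapi[dapi_fg] <- b + rp$dapi_peak_intensity
  emhc <- matrix(b, H, W); emhc[emhc_fg] <- b + rp$emhc_intensity

  if (rp$psf_sigma_px > 0) {
    dapi <- cpp_gaussian_blur(dapi, rp$psf_sigma_px)
    emhc <- cpp_gaussian_blur(emhc, rp$psf_sigma_px)
  }
  if (rp$noise != "none") {
    set.seed(rp$seed)
    if (rp$noise == "gaussian") {
      dapi <- dapi + rnorm(length(dapi), 0, rp$noise_sd)
      emhc <- emhc + rnorm(length(emhc), 0, rp$noise_sd)
    } else {
      dapi[] <- rpois(length(dapi), lambda = dapi)
      emhc[] <- rpois(length(emhc), lambda = emhc)
    }
  }
  maxv <- 2^rp$bit_depth - 1
  dapi <- round(dapi); emhc <- round(emhc)
  over <- max(dapi, emhc) > maxv
  if (over && !rp$clip) {
    abort(sprintf("rendered intensity exceeds %d-bit range; enable clip or lower intensities",
                  rp$bit_depth))
  }
  dapi <- pmin(pmax(dapi, 0), maxv)
  emhc <- pmin(pmax(emhc, 0), maxv)
  dim(dapi) <- dim(emhc) <- c(H, W)
  image_stack(dapi, emhc, scene$pixel_size_um, rp$bit_depth)
}
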