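# Small, fast study fixtures shared across test files.

# a compact field that segments in well under a second
small_scene_params <- function(seed = 1L, ...) {
  scene_params(field_width_px = 200L, field_height_px = 200L,
               n_myotubes = 2L, n_mononucleated = 8L,
               nuclei_per_myotube_sampler = sampler_fixed(c(3L, 5L)),
               seed = seed, ...)
}

small_seg_config <- function(...) {
  segmentation_config(rolling_ball_radius_px = 15, ...)
}

noiseless_rp <- function(...) {
  render_params(psf_sigma_px = 0, noise = "none", background_level = 0, ...)
}

random_convex_polygon <- function(center, radius, n = 8) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.4 * radius, radius)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}
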