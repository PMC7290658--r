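#' Nuclei-per-myotube samplers
#'
#' A myotube is a fused, multinucleated cell, so any sampler used to draw its
#' nucleus count must yield integers >= 2. Three families are provided:
#'
#' * `sampler_fixed(counts)` — cycles through an explicit list of counts
#'   (myotube i gets `counts[i]`, recycled); handy for pinning exact truth.
#' * `sampler_geometric(mean)` — `2 + Geometric(p)` with `p` chosen so the
#'   expectation equals `mean`; a long right tail resembling cultures where
#'   most tubes are small and a few are very large.
#' * `sampler_nbinom(mu, size)` — `2 + NegBinomial(mu - 2, size)`, for
#'   independent control of mean and overdispersion.
#'
#' @param counts Integer vector, all >= 2.
#' @param mean,mu Target mean nucleus count (> 2).
#' @param size Negative-binomial dispersion (smaller = more overdispersed).
#' @return A sampler object understood by [scene_params()] and
#'   [sample_nuclei_per_myotube()].
#' @export
sampler_fixed <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) < 1 || anyNA(counts) || any(counts < 2)) {
    abort("`counts` must be integers >= 2 (a myotube has at least 2 nuclei).")
  }
  structure(list(kind = "fixed", counts = counts), class = "nuclei_sampler")
}

#' @rdname sampler_fixed
#' @export
sampler_geometric <- function(mean) {
  if (!is.numeric(mean) || length(mean) != 1 || mean <= 2) {
    abort("`mean` must be a single number > 2.")
  }
  structure(list(kind = "geometric", prob = 1 / (mean - 1)), class = "nuclei_sampler")
}

#' @rdname sampler_fixed
#' @export
sampler_nbinom <- function(mu, size = 2) {
  if (!is.numeric(mu) || length(mu) != 1 || mu <= 2) abort("`mu` must be a single number > 2.")
  if (!is.numeric(size) || size <= 0) abort("`size` must be > 0.")
  structure(list(kind = "nbinom", mu = mu - 2, size = size), class = "nuclei_sampler")
}

#' Draw nucleus counts from a sampler
#'
#' @param sampler A sampler from [sampler_fixed()], [sampler_geometric()] or
#'   [sampler_nbinom()].
#' @param n Number of myotubes to draw counts for.
#' @return Integer vector of length `n`, all values >= 2.
#' @export
sample_nuclei_per_myotube <- function(sampler, n) {
  stopifnot(inherits(sampler, "nuclei_sampler"), n >= 0)
  if (n == 0) return(integer(0))
  switch(sampler$kind,
    fixed = rep_len(sampler$counts, n),
    geometric = 2L + rgeom(n, sampler$prob),
    nbinom = 2L + rnbinom(n, mu = sampler$mu, size = sampler$size)
  )
}

#' Parameters for simulated myotube fields
#'
#' Bundles everything needed to lay out a ground-truth field: multinucleated
#' myotubes (elongated capsule-shaped cells, all positive for embryonic
#' myosin heavy chain, eMHC) and mononucleated cells, some fraction of which
#' are eMHC-positive (differentiated but unfused). Defaults describe a
#' moderately confluent differentiation-day-4 culture imaged at high
#' magnification.
#'
#' @param field_width_px,field_height_px Field size in pixels.
#' @param pixel_size_um Micrometers per pixel.
#' @param n_myotubes Number of myotubes to place.
#' @param nuclei_per_myotube_sampler Sampler for per-myotube nucleus counts
#'   (see [sampler_fixed()]); must yield values >= 2.
#' @param n_mononucleated Number of mononucleated cells.
#' @param fraction_mono_emhc_positive Fraction of mononucleated cells that are
#'   eMHC-positive (differentiated but not fused), in `[0, 1]`.
#' @param nucleus_radius_px Nucleus radius used for rendering and spacing.
#' @param min_nucleus_separation_px Minimum centre-to-centre distance between
#'   any two nuclei. The default `2 * nucleus_radius_px + 3` keeps rasterized
#'   nuclei disjoint even under 8-connectivity, so noiseless counts are
#'   exactly recoverable.
#' @param seed Integer seed; identical parameters give a bit-identical scene.
#' @return A `scene_params` object.
#' @export
scene_params <- function(field_width_px = 400L,
                         field_height_px = 400L,
                         pixel_size_um = 0.25,
                         n_myotubes = 6L,
                         nuclei_per_myotube_sampler = sampler_geometric(8),
                         n_mononucleated = 30L,
                         fraction_mono_emhc_positive = 0.2,
                         nucleus_radius_px = 5,
                         min_nucleus_separation_px = 2 * nucleus_radius_px + 3,
                         seed = 1L) {
  p <- list(
    field_width_px = as.integer(field_width_px),
    field_height_px = as.integer(field_height_px),
    pixel_size_um = as.numeric(pixel_size_um),
    n_myotubes = as.integer(n_myotubes),
    nuclei_per_myotube_sampler = nuclei_per_myotube_sampler,
    n_mononucleated = as.integer(n_mononucleated),
    fraction_mono_emhc_positive = as.numeric(fraction_mono_emhc_positive),
    nucleus_radius_px = as.numeric(nucleus_radius_px),
    min_nucleus_separation_px = as.numeric(min_nucleus_separation_px),
    seed = as.integer(seed)
  )
  with(p, {
    if (field_width_px <= 0 || field_height_px <= 0) abort("field dimensions must be > 0")
    if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0")
    if (n_myotubes < 0 || n_mononucleated < 0) abort("object counts must be >= 0")
    if (fraction_mono_emhc_positive < 0 || fraction_mono_emhc_positive > 1) {
      abort("`fraction_mono_emhc_positive` must be in [0, 1]")
    }
    if (nucleus_radius_px <= 0) abort("`nucleus_radius_px` must be > 0")
    if (min_nucleus_separation_px < 0) abort("`min_nucleus_separation_px` must be >= 0")
  })
  if (!inherits(p$nuclei_per_myotube_sampler, "nuclei_sampler")) {
    abort("`nuclei_per_myotube_sampler` must be a nuclei sampler object.")
  }
  structure(p, class = "scene_params")
}

# capsule (stadium) polygon: segment a-b dilated by half-width w,
# approximated with `k` segments per semicircular cap
capsule_polygon <- function(a, b, w, k = 12) {
  th <- atan2(b[2] - a[2], b[1] - a[1])
  ang_b <- th - pi / 2 + seq(0, pi, length.out = k + 1)       # cap at b
  ang_a <- th + pi / 2 + seq(0, pi, length.out = k + 1)       # cap at a
  cbind(
    c(b[1] + w * cos(ang_b), a[1] + w * cos(ang_a)),
    c(b[2] + w * sin(ang_b), a[2] + w * sin(ang_a))
  )
}

#' Generate a ground-truth field of myotubes and mononucleated cells
#'
#' Places non-overlapping capsule-shaped myotubes (random position and
#' orientation, length scaled with the drawn nucleus count), fills each with
#' its nuclei by rejection sampling under a global minimum separation, and
#' scatters mononucleated cells outside all myotubes. The returned scene is
#' the exact ground truth that rendering and segmentation are later judged
#' against.
#'
#' @param params A [scene_params()] object.
#' @param max_attempts Rejection-sampling budget per placed object.
#' @return A `scene` object: `$myotubes` (list with `polygon`, `nuclei`
#'   matrices), `$mono_cells` (tibble `x, y, emhc_positive`), field metadata,
#'   and `$params`.
#' @seealso [render_scene()], [scene_rois()]
#' @export
generate_scene <- function(params, max_attempts = 5000L) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  W <- params$field_width_px; H <- params$field_height_px
  r <- params$nucleus_radius_px
  sep <- params$min_nucleus_separation_px
  half_w <- max(2.2 * r, 11)          # myotube half-width: a bit over 2 nuclei
  mono_rc <- 2.5 * r                  # mononucleated cell body radius

  counts <- sample_nuclei_per_myotube(params$nuclei_per_myotube_sampler,
                                      params$n_myotubes)
  ord <- order(counts, decreasing = TRUE) # place large tubes first
  placed_nuclei <- matrix(numeric(0), ncol = 2)
  axes <- list()

  too_crowded <- function(what) {
    abort(paste0(
      "field too crowded: failed to place ", what, " after ", max_attempts,
      " attempts; relax `n_myotubes`, `n_mononucleated`, ",
      "`min_nucleus_separation_px` or enlarge the field."
    ))
  }

  myotubes <- vector("list", params$n_myotubes)
  max_len <- 0.8 * min(W, H)
  for (m in seq_along(ord)) {
    n_nuc <- counts[ord[m]]
    # capsule sized for n_nuc nuclei at the required separation (factor 2
    # over the close-packing area keeps rejection sampling cheap); very
    # large tubes widen instead of growing past the field
    need_area <- n_nuc * sep^2 * 2
    half_w_m <- half_w
    len <- max(4 * r, need_area / (2 * half_w_m))
    if (len > max_len) {
      len <- max_len
      half_w_m <- need_area / (2 * len)
    }
    ok <- FALSE
    for (att in seq_len(ceiling(max_attempts / 10))) {
      th <- runif(1, 0, pi)
      cx <- runif(1, half_w_m + 2, W - half_w_m - 2)
      cy <- runif(1, half_w_m + 2, H - half_w_m - 2)
      a <- c(cx - len / 2 * cos(th), cy - len / 2 * sin(th))
      b <- c(cx + len / 2 * cos(th), cy + len / 2 * sin(th))
      lo <- pmin(a, b) - half_w_m; hi <- pmax(a, b) + half_w_m
      if (lo[1] < 1 || lo[2] < 1 || hi[1] > W - 1 || hi[2] > H - 1) next
      clear <- TRUE
      for (ax in axes) {
        if (segment_segment_dist(a, b, ax$a, ax$b) < half_w_m + ax$w + 4) {
          clear <- FALSE; break
        }
      }
      if (!clear) next
      # fill with nuclei
      nuc <- matrix(numeric(0), ncol = 2)
      fail <- FALSE
      nrm <- c(-(b[2] - a[2]), b[1] - a[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      for (k in seq_len(n_nuc)) {
        got <- FALSE
        for (att2 in seq_len(200L)) {
          t <- runif(1); u <- runif(1, -1, 1)
          p <- a + t * (b - a) + u * (half_w_m - r - 1) * nrm
          if (p[1] < r || p[2] < r || p[1] > W - r || p[2] > H - r) next
          all_n <- rbind(placed_nuclei, nuc)
          if (nrow(all_n) > 0 &&
              min((all_n[, 1] - p[1])^2 + (all_n[, 2] - p[2])^2) < sep^2) next
          nuc <- rbind(nuc, p)
          got <- TRUE
          break
        }
        if (!got) { fail <- TRUE; break }
      }
      if (fail) next
      poly <- capsule_polygon(a, b, half_w_m)
      myotubes[[ord[m]]] <- list(polygon = poly, nuclei = unname(nuc),
                                 emhc_positive = TRUE)
      axes[[length(axes) + 1]] <- list(a = a, b = b, w = half_w_m)
      placed_nuclei <- rbind(placed_nuclei, nuc)
      ok <- TRUE
      break
    }
    if (!ok) too_crowded(sprintf("a myotube with %d nuclei", n_nuc))
  }

  mono <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(params$n_mononucleated)) {
    got <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- c(runif(1, mono_rc + 1, W - mono_rc - 1),
             runif(1, mono_rc + 1, H - mono_rc - 1))
      near_tube <- FALSE
      for (ax in axes) {
        if (sqrt(point_segment_dist2(p[1], p[2], ax$a[1], ax$a[2],
                                     ax$b[1], ax$b[2])) < ax$w + mono_rc + 2) {
          near_tube <- TRUE; break
        }
      }
      if (near_tube) next
      all_n <- rbind(placed_nuclei, mono)
      if (nrow(all_n) > 0 &&
          min((all_n[, 1] - p[1])^2 + (all_n[, 2] - p[2])^2) < sep^2) next
      mono <- rbind(mono, p)
      got <- TRUE
      break
    }
    if (!got) too_crowded("a mononucleated cell")
  }

  n_pos <- round(params$fraction_mono_emhc_positive * params$n_mononucleated)
  emhc_pos <- rep(FALSE, params$n_mononucleated)
  if (n_pos > 0) emhc_pos[sample(params$n_mononucleated, n_pos)] <- TRUE

  mono_tbl <- tibble::tibble(
    x = if (nrow(mono)) unname(mono[, 1]) else numeric(0),
    y = if (nrow(mono)) unname(mono[, 2]) else numeric(0),
    emhc_positive = emhc_pos
  )
  structure(list(
    myotubes = myotubes,
    mono_cells = mono_tbl,
    field_width_px = W, field_height_px = H,
    pixel_size_um = params$pixel_size_um,
    nucleus_radius_px = r,
    mono_cell_radius_px = mono_rc,
    params = params
  ), class = "scene")
}

#' Ground-truth nucleus centres of a scene
#'
#' @param scene A [generate_scene()] result.
#' @return Tibble `x, y, compartment` where `compartment` is `"myotube"` or
#'   `"mono"`.
#' @export
scene_nuclei <- function(scene) {
  stopifnot(inherits(scene, "scene"))
  proto <- tibble::tibble(x = numeric(0), y = numeric(0), compartment = character(0))
  tube <- purrr::map_dfr(scene$myotubes, function(m) {
    tibble::tibble(x = m$nuclei[, 1], y = m$nuclei[, 2], compartment = "myotube")
  })
  mono <- dplyr::mutate(scene$mono_cells[, c("x", "y")], compartment = "mono")
  dplyr::bind_rows(proto, tube, mono)
}

#' Total ground-truth nucleus count
#' @param scene A [generate_scene()] result.
#' @return Integer.
#' @export
scene_nucleus_count <- function(scene) {
  nrow(scene_nuclei(scene))
}

#' @export
print.scene <- function(x, ...) {
  n_tube_nuc <- sum(vapply(x$myotubes, function(m) nrow(m$nuclei), 1L))
  cat(sprintf(
    "<scene> %d x %d px (%.3g um/px): %d myotubes (%d nuclei), %d mono cells (%d eMHC+)\n",
    x$field_width_px, x$field_height_px, x$pixel_size_um,
    length(x$myotubes), n_tube_nuc, nrow(x$mono_cells),
    sum(x$mono_cells$emhc_positive)
  ))
  invisible(x)
}
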