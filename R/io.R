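#' Write a two-channel image stack to TIFF with a metadata sidecar
#'
#' Writes one TIFF page per channel (DAPI first, then eMHC) at the stack's
#' bit depth, plus a sidecar JSON (`<path>.json`) holding the pixel size and
#' channel order. The sidecar is the authoritative pixel-size record.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  maxv <- 2^stack$bit_depth - 1
  tiff::writeTIFF(list(stack$dapi / maxv, stack$emhc / maxv), path,
                  bits.per.sample = stack$bit_depth, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         bit_depth = stack$bit_depth,
         channels = c("dapi", "emhc")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a two-channel image stack from TIFF
#'
#' Channels are resolved through `channel_map` (page indices, 1-based).
#' Pixel size is taken from the sidecar JSON when present, else from TIFF
#' resolution tags, else from the `pixel_size_um` argument; if none is
#' available the read fails.
#'
#' @param path TIFF path.
#' @param channel_map Named integer vector mapping `dapi` and `emhc` to page
#'   numbers.
#' @param pixel_size_um Fallback pixel size when no metadata is found.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, channel_map = c(dapi = 1L, emhc = 2L),
                             pixel_size_um = NULL) {
  if (!file.exists(path)) abort(paste0("unreadable image: ", path), class = "myofuse_missing_input")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (ch in c("dapi", "emhc")) {
    if (!ch %in% names(channel_map) || channel_map[[ch]] > length(pages)) {
      abort(paste0("missing channel: ", ch), class = "myofuse_missing_channel")
    }
  }
  dapi <- pages[[channel_map[["dapi"]]]]
  emhc <- pages[[channel_map[["emhc"]]]]
  bits <- attr(dapi, "bits.per.sample") %||% 16L

  sidecar <- paste0(path, ".json")
  px <- NULL
  if (file.exists(sidecar)) {
    px <- jsonlite::read_json(sidecar)$pixel_size_um
  } else {
    xres <- attr(dapi, "x.resolution")
    unit <- attr(dapi, "resolution.unit") %||% "inch"
    if (!is.null(xres) && xres > 0) {
      um_per_unit <- switch(unit, inch = 25400, cm = 10000, 25400)
      px <- um_per_unit / xres
    }
  }
  px <- px %||% pixel_size_um
  if (is.null(px)) {
    abort("pixel size not found in sidecar or TIFF tags; pass `pixel_size_um`",
          class = "myofuse_missing_pixel_size")
  }
  image_stack(unclass_matrix(dapi), unclass_matrix(emhc),
              pixel_size_um = as.numeric(px), bit_depth = as.integer(bits))
}

unclass_matrix <- function(m) {
  out <- matrix(as.numeric(m), nrow(m), ncol(m))
  out
}

#' Write / read scene ground truth (and ROIs) as JSON
#'
#' The interchange schema is
#' `{"field": {...}, "myotubes": [{"polygon": [[x,y],...], "nuclei": [[x,y],...],
#' "emhc_positive": true}], "mono_cells": [{"center": [x,y],
#' "emhc_positive": ...}]}`.
#'
#' @param scene A [generate_scene()] result.
#' @param path JSON path.
#' @return `path` invisibly (writer); a `scene` object (reader).
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "scene"))
  obj <- list(
    field = list(width_px = scene$field_width_px,
                 height_px = scene$field_height_px,
                 pixel_size_um = scene$pixel_size_um,
                 nucleus_radius_px = scene$nucleus_radius_px,
                 mono_cell_radius_px = scene$mono_cell_radius_px),
    myotubes = lapply(scene$myotubes, function(m) list(
      polygon = unname(apply(m$polygon, 1, as.numeric, simplify = FALSE)),
      nuclei = unname(apply(m$nuclei, 1, as.numeric, simplify = FALSE)),
      emhc_positive = TRUE
    )),
    mono_cells = lapply(seq_len(nrow(scene$mono_cells)), function(i) list(
      center = c(scene$mono_cells$x[i], scene$mono_cells$y[i]),
      emhc_positive = scene$mono_cells$emhc_positive[i]
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input: ", path), class = "myofuse_missing_input")
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_mat <- function(rows) {
    if (length(rows) == 0) return(matrix(numeric(0), ncol = 2))
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  }
  mono <- obj$mono_cells
  mono_tbl <- tibble::tibble(
    x = vapply(mono, function(m) as.numeric(m$center[[1]]), 0),
    y = vapply(mono, function(m) as.numeric(m$center[[2]]), 0),
    emhc_positive = vapply(mono, function(m) isTRUE(m$emhc_positive), TRUE)
  )
  structure(list(
    myotubes = lapply(obj$myotubes, function(m) list(
      polygon = to_mat(m$polygon), nuclei = to_mat(m$nuclei), emhc_positive = TRUE
    )),
    mono_cells = mono_tbl,
    field_width_px = as.integer(obj$field$width_px),
    field_height_px = as.integer(obj$field$height_px),
    pixel_size_um = as.numeric(obj$field$pixel_size_um),
    nucleus_radius_px = as.numeric(obj$field$nucleus_radius_px),
    mono_cell_radius_px = as.numeric(obj$field$mono_cell_radius_px),
    params = NULL
  ), class = "scene")
}

#' Read ROI polygons from JSON
#'
#' Accepts the scene schema (myotube polygons become eMHC-positive ROIs) or
#' an explicit `{"rois": [{"polygon": ..., "emhc_positive": ...}]}` list.
#'
#' @param path JSON path.
#' @param width,height,pixel_size_um Field metadata overrides (taken from the
#'   file's `field` entry when present).
#' @return A [roi_set()].
#' @export
read_roi_json <- function(path, width = NULL, height = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) abort(paste0("missing input: ", path), class = "myofuse_missing_input")
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_mat <- function(rows) do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  if (!is.null(obj$rois)) {
    polys <- lapply(obj$rois, function(r) to_mat(r$polygon))
    pos <- vapply(obj$rois, function(r) isTRUE(r$emhc_positive), TRUE)
  } else {
    polys <- lapply(obj$myotubes, function(m) to_mat(m$polygon))
    pos <- rep(TRUE, length(polys))
  }
  roi_set(polys, pos,
          width = width %||% obj$field$width_px,
          height = height %||% obj$field$height_px,
          pixel_size_um = pixel_size_um %||% obj$field$pixel_size_um %||% NA_real_)
}

#' Nucleus-table CSV round trip
#'
#' CSV schema: `label,x,y,area_px`; field metadata travels in a sidecar JSON
#' (`<path>.json`) so a read-back table can still compute densities.
#'
#' @param nuclei A `nucleus_set`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `nucleus_set` (reader).
#' @export
write_nuclei_csv <- function(nuclei, path) {
  stopifnot(inherits(nuclei, "nucleus_set"))
  readr::write_csv(tibble::as_tibble(nuclei), path)
  jsonlite::write_json(
    list(field_width_px = attr(nuclei, "field_width_px"),
         field_height_px = attr(nuclei, "field_height_px"),
         pixel_size_um = attr(nuclei, "pixel_size_um")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nuclei_csv
#' @export
read_nuclei_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input: ", path), class = "myofuse_missing_input")
  tbl <- strip_readr_attrs(readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           label = readr::col_integer(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           area_px = readr::col_integer())))
  meta <- list(field_width_px = NA, field_height_px = NA, pixel_size_um = NA)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  new_nucleus_set(tbl, meta$field_width_px, meta$field_height_px, meta$pixel_size_um)
}

#' Differential-expression table CSV round trip
#'
#' CSV schema: `gene_id,log2fc,pvalue` with an optional `padj` column.
#'
#' @param table A DE tibble.
#' @param path CSV path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_deg_csv <- function(table, path) {
  check_deg_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_deg_csv
#' @export
read_deg_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("missing input: ", path), class = "myofuse_missing_input")
  tbl <- strip_readr_attrs(readr::read_csv(path, show_col_types = FALSE))
  check_deg_table(tbl)
  tbl
}

strip_readr_attrs <- function(tbl) {
  attr(tbl, "spec") <- NULL
  attr(tbl, "problems") <- NULL
  class(tbl) <- c("tbl_df", "tbl", "data.frame")
  tbl
}
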