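#' Configuration for an end-to-end fusion-quantification run
#'
#' Describes a two-condition experiment on simulated fields: for each
#' condition, a scene-parameter template and a number of fields; plus the
#' segmentation configuration, DE-simulation parameters and significance
#' thresholds. Existing images and ROI files can be supplied instead of
#' simulation through the `fields` manifest.
#'
#' @param condition_a,condition_b Condition labels.
#' @param scene_a,scene_b [scene_params()] templates (per-field seeds are
#'   derived from `seed`).
#' @param n_fields Fields simulated per condition.
#' @param render [render_params()] shared by all fields.
#' @param segmentation A [segmentation_config()].
#' @param deg_sim A [deg_sim_params()], or `NULL` to skip the DE stage.
#' @param thresholds A [deg_thresholds()].
#' @param fields Optional manifest tibble `field_id, image, rois, condition`
#'   pointing at existing TIFF/JSON inputs; when given, simulation is
#'   skipped.
#' @param seed Master seed; all per-field and DE seeds derive from it.
#' @return A `fusion_run_config` object.
#' @export
fusion_run_config <- function(condition_a = "control",
                              condition_b = "treated",
                              scene_a = scene_params(),
                              scene_b = scene_params(
                                nuclei_per_myotube_sampler = sampler_geometric(15),
                                n_myotubes = 4L),
                              n_fields = 3L,
                              render = render_params(),
                              segmentation = segmentation_config(),
                              deg_sim = deg_sim_params(),
                              thresholds = deg_thresholds(),
                              fields = NULL,
                              seed = 1L) {
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 scene_a = scene_a, scene_b = scene_b,
                 n_fields = as.integer(n_fields), render = render,
                 segmentation = segmentation, deg_sim = deg_sim,
                 thresholds = thresholds, fields = fields,
                 seed = as.integer(seed)),
            class = "fusion_run_config")
}

#' Run the full quantification pipeline
#'
#' Chains simulate (unless a field manifest is given) -> segment -> quantify
#' -> opposing-gene classification, writing per-field reports (JSON), a tidy
#' per-myotube table, group-comparison statistics, the DE classification and
#' a provenance record into `out_dir`. Rerunning with the same configuration
#' and seed reproduces every output byte for byte.
#'
#' @param config A [fusion_run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the per-field glances, comparison table and
#'   DE classification.
#' @export
run_fusion_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "fusion_run_config"))
  if (!is.null(config$fields)) {
    missing <- config$fields$image[!file.exists(config$fields$image)]
    if (length(missing) > 0) {
      abort(paste0("missing input image(s): ", paste(missing, collapse = ", ")),
            class = "myofuse_missing_input")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  field_jobs <- list()
  if (is.null(config$fields)) {
    k <- 0L
    for (cond in c("a", "b")) {
      label <- config[[paste0("condition_", cond)]]
      template <- config[[paste0("scene_", cond)]]
      for (f in seq_len(config$n_fields)) {
        k <- k + 1L
        sp <- template
        sp$seed <- config$seed * 1000L + k
        rp <- config$render
        rp$seed <- sp$seed + 1L
        scene <- generate_scene(sp)
        stack <- render_scene(scene, rp)
        fid <- sprintf("%s_f%02d", label, f)
        img_path <- file.path(out_dir, paste0(fid, ".tif"))
        write_image_stack(stack, img_path)
        write_scene_json(scene, file.path(out_dir, paste0(fid, "_truth.json")))
        field_jobs[[k]] <- list(field_id = fid, condition = label,
                                stack = stack, rois = scene_rois(scene))
      }
    }
  } else {
    for (k in seq_len(nrow(config$fields))) {
      row <- config$fields[k, ]
      field_jobs[[k]] <- list(
        field_id = row$field_id, condition = row$condition,
        stack = read_image_stack(row$image),
        rois = read_roi_json(row$rois))
    }
  }

  glances <- list(); per_myotube <- list()
  for (job in field_jobs) {
    nuclei <- segment_nuclei(job$stack, config$segmentation)
    report <- build_fusion_report(nuclei, job$rois)
    write_nuclei_csv(nuclei, file.path(out_dir, paste0(job$field_id, "_nuclei.csv")))
    jsonlite::write_json(glance(report),
                         file.path(out_dir, paste0(job$field_id, "_report.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    g <- dplyr::mutate(glance(report), field_id = job$field_id,
                       condition = job$condition, .before = 1)
    glances[[length(glances) + 1]] <- g
    tube <- tidy(report)
    tube <- dplyr::filter(tube, .data$is_myotube)
    if (nrow(tube) > 0) {
      per_myotube[[length(per_myotube) + 1]] <- tibble::tibble(
        field_id = job$field_id, condition = job$condition,
        roi_id = tube$roi_id, n_nuclei = tube$n_nuclei)
    }
  }
  glances <- dplyr::bind_rows(glances)
  per_myotube <- dplyr::bind_rows(per_myotube)
  readr::write_csv(glances, file.path(out_dir, "field_reports.csv"))
  readr::write_csv(per_myotube, file.path(out_dir, "per_myotube.csv"))

  conds <- unique(glances$condition)
  comparisons <- NULL
  if (length(conds) == 2) {
    ga <- glances[glances$condition == conds[1], ]
    gb <- glances[glances$condition == conds[2], ]
    ca <- per_myotube$n_nuclei[per_myotube$condition == conds[1]]
    cb <- per_myotube$n_nuclei[per_myotube$condition == conds[2]]
    rows <- list()
    if (nrow(ga) >= 2 && nrow(gb) >= 2) {
      rows$total <- dplyr::mutate(
        tidy(compare_groups(ga$total_nuclei, gb$total_nuclei, "student_t")),
        metric = "total_nuclei", .before = 1)
      rows$di <- dplyr::mutate(
        tidy(compare_groups(ga$differentiation_index, gb$differentiation_index,
                            "student_t")),
        metric = "differentiation_index", .before = 1)
    }
    if (length(ca) >= 1 && length(cb) >= 1) {
      rows$fusion <- dplyr::mutate(
        tidy(compare_groups(ca, cb, "wilcoxon_rank_sum")),
        metric = "nuclei_per_myotube", .before = 1)
    }
    comparisons <- dplyr::bind_rows(rows)
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
  }

  classification <- NULL
  if (!is.null(config$deg_sim)) {
    dp <- config$deg_sim
    dp$seed <- config$seed * 1000L + 999L
    deg <- generate_deg_tables(dp)
    write_deg_csv(deg$contrast_a, file.path(out_dir, "deg_contrast_a.csv"))
    write_deg_csv(deg$contrast_b, file.path(out_dir, "deg_contrast_b.csv"))
    classification <- classify_opposing(
      filter_deg(deg$contrast_a, config$thresholds),
      filter_deg(deg$contrast_b, config$thresholds))
    readr::write_csv(tidy(classification),
                     file.path(out_dir, "opposing_classification.csv"))
    jsonlite::write_json(as.list(glance(classification)),
                         file.path(out_dir, "opposing_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  provenance <- list(
    package = "myofuse",
    version = as.character(utils::packageVersion("myofuse")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "fields")]),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(field_reports = glances, per_myotube = per_myotube,
                 comparisons = comparisons, classification = classification))
}
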