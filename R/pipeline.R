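# Pipeline orchestration: wire the modules together from a config, with
# seeded determinism and per-stage logging.

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by [run_pipeline()].
#' Unspecified fields take the documented defaults of the underlying stages.
#' The configuration is fully serialisable; every artifact written by the
#' pipeline embeds its fingerprint.
#'
#' @param cube Path to an ENVI header, or a [hypercube].
#' @param white Path to a white-reference CSV, or a `white_reference`.
#' @param register Optional ROI register CSV path (or `roi_register`).
#' @param roi Optional roi_id to crop before processing.
#' @param library Path to a material library CSV, or a [material_library];
#'   `NULL` builds one with [cluster_materials()] on the input cube.
#' @param templates Template directory path, a `shape_template_set`, or
#'   `NULL` for [render_templates()] defaults.
#' @param truth Optional `ground_truth_set` for evaluation.
#' @param out_dir Output directory (created if missing).
#' @param detection A [detection_params()].
#' @param da A [da_params()].
#' @param jitter_sd,n_per_class Classifier training settings.
#' @param reflectance_ceiling Clip ceiling for [to_reflectance()].
#' @param soil_name,grass_name Names of the two mound-diagnostic materials.
#' @param seed Integer seed.
#' @param verbose Log stage progress to the console.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cube, white, register = NULL, roi = NULL,
                            library = NULL, templates = NULL, truth = NULL,
                            out_dir = tempfile("moundscan_"),
                            detection = detection_params(), da = da_params(),
                            jitter_sd = 0.02, n_per_class = 200L,
                            reflectance_ceiling = 2.0,
                            soil_name = "Eroded Soil",
                            grass_name = "Light Grass",
                            seed = 1L, verbose = TRUE) {
  structure(list(cube = cube, white = white, register = register, roi = roi,
                 library = library, templates = templates, truth = truth,
                 out_dir = out_dir, detection = detection, da = da,
                 jitter_sd = jitter_sd, n_per_class = as.integer(n_per_class),
                 reflectance_ceiling = reflectance_ceiling,
                 soil_name = soil_name, grass_name = grass_name,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()];
#' `detection:` and `da:` sub-maps override individual threshold defaults.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. `seed =`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  det <- do.call(detection_params, y$detection %||% list())
  da <- do.call(da_params, y$da %||% list())
  args <- y[setdiff(names(y), c("detection", "da"))]
  args$detection <- det; args$da <- da
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_input <- function(x, reader, class_name) {
  if (is.null(x) || inherits(x, class_name)) return(x)
  if (is.character(x)) return(reader(x))
  abort_ms(sprintf("cannot interpret input as %s", class_name), "data_error")
}

write_mask_png <- function(mask, path) {
  png::writePNG(pmin(pmax(mask, 0), 1), path)
  invisible(path)
}

#' Run the full detection pipeline
#'
#' Stages: read/crop -> band pre-clean -> reflectance recovery -> material
#' library (loaded or clustered) -> SVM training and per-pixel
#' classification -> soil/grass layer extraction -> two-layer mound
#' detection -> evaluation (when ground truth is supplied). Writes the label
#' map, the two layer masks, the detection JSON, the contour overlay and
#' (with truth) a report CSV into `config$out_dir`; every file is stamped
#' with the configuration fingerprint. Fully deterministic under
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `detections`, `label_map`, `layers`,
#'   `report` (or `NULL`), `library`, `fingerprint` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  # fingerprint the analytic configuration only: where the outputs go (and
  # whether we log) does not change what is computed
  fp <- config_fingerprint(config[setdiff(names(config),
                                          c("truth", "verbose", "out_dir"))])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cube <- resolve_input(config$cube, read_cube, "hypercube")
  if (is.null(cube)) abort_ms("stage input: no cube supplied", "data_error")
  white <- resolve_input(config$white, read_white_reference, "white_reference")
  if (is.null(white)) abort_ms("stage input: no white reference supplied", "data_error")
  if (!is.null(config$roi)) {
    register <- resolve_input(config$register, read_roi_register, "roi_register")
    if (is.null(register)) abort_ms("stage input: roi requested but no register", "data_error")
    cube <- crop_roi(cube, register, config$roi)
  }
  log_msg("stage input: cube %d x %d x %d (%s)", dim(cube)[1], dim(cube)[2],
          dim(cube)[3], cube$quantity)

  cube <- preclean_cube(cube)
  log_msg("stage preclean: 3x3 grayscale closing applied to %d bands", dim(cube)[3])

  refl <- to_reflectance(cube, white, ceiling = config$reflectance_ceiling)
  log_msg("stage reflectance: ceiling %.2f", config$reflectance_ceiling)

  library <- resolve_input(config$library, read_material_library, "material_library")
  if (is.null(library)) {
    library <- cluster_materials(refl, config$da)
    log_msg("stage library: clustered %d materials", length(library$names))
  } else {
    log_msg("stage library: loaded %d materials", length(library$names))
  }
  for (nm in c(config$soil_name, config$grass_name)) {
    if (!nm %in% library$names) {
      abort_ms(sprintf("stage library: material '%s' missing", nm), "lookup_error")
    }
  }

  classifier <- train_classifier(library, jitter_sd = config$jitter_sd,
                                 n_per_class = config$n_per_class,
                                 seed = config$seed)
  labels <- classify_cube(refl, classifier)
  log_msg("stage classify: %d x %d label map, %d distinct labels",
          nrow(labels), ncol(labels), length(unique(as.vector(labels))))

  layers <- extract_layers(labels, library, c(config$soil_name, config$grass_name))
  log_msg("stage layers: soil %d px, grass %d px",
          sum(layers[[1]]), sum(layers[[2]]))

  templates <- resolve_input(config$templates, read_templates, "shape_template_set")
  if (is.null(templates)) templates <- render_templates()
  det <- detect_mounds(layers[[1]], layers[[2]], templates, config$detection)
  log_msg("stage detect: gate mean %.4f, %d detection(s)",
          det$gate$mean, length(det$detections))

  paths <- list(
    label_map = file.path(config$out_dir, "label_map.png"),
    soil = file.path(config$out_dir, "layer_soil.png"),
    grass = file.path(config$out_dir, "layer_grass.png"),
    detections = file.path(config$out_dir, "detections.json"),
    overlay = file.path(config$out_dir, "overlay.png"),
    library = file.path(config$out_dir, "material_library.csv")
  )
  write_mask_png(unclass(labels) / max(1, length(library$names)), paths$label_map)
  write_mask_png(unclass(layers[[1]]), paths$soil)
  write_mask_png(unclass(layers[[2]]), paths$grass)
  write_detections(det$detections, paths$detections, fingerprint = fp)
  png::writePNG(det$overlay, paths$overlay)
  write_material_library(library, paths$library)

  report <- NULL
  if (!is.null(config$truth)) {
    counts <- match_detections(det$detections, config$truth)
    report <- aggregate_report(list(roi = counts))
    paths$report <- file.path(config$out_dir, "report.csv")
    write_report(report, paths$report)
    log_msg("stage evaluate: tp %d, fn %d, fp %d, accuracy %.1f%%",
            counts$tp, counts$fn, counts$fp, 100 * counts$accuracy)
  } else {
    log_msg("stage evaluate: skipped (no ground truth supplied)")
  }

  invisible(list(detections = det$detections, label_map = labels,
                 layers = layers, report = report, library = library,
                 fingerprint = fp, paths = paths))
}
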