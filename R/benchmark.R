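# Synthetic validation bench: the controlled experiments the package uses to
# check itself end to end. Scenes are small enough to run routinely; the
# methods vignette records the problem sizes.

#' Pipeline-closure benchmark on noiseless synthetic scenes
#'
#' Generates `n_scenes` seeded scenes with 3-6 planted mounds each, with
#' noise, blur and distortion disabled, then runs reflectance recovery, SVM
#' classification against the generating library, layer extraction and mound
#' detection, scoring detections against the exact ground truth. On such
#' scenes the pipeline should close: the label map should reproduce the
#' generator's material raster exactly and detection should find every
#' planted mound with no false positives at default thresholds.
#'
#' @param n_scenes Number of scenes.
#' @param rows,cols,n_bands Scene dimensions.
#' @param seed Master seed; scene `i` uses `seed * 1000 + i`.
#' @param params A [detection_params()].
#' @return List: `label_accuracy` (pooled fraction of pixels labelled
#'   identically to the truth raster), `recall` (pooled TP / (TP + FN)),
#'   `false_positives` (total FP), `n_mounds` (total planted), `per_scene`
#'   data frame.
#' @export
closure_benchmark <- function(n_scenes = 20L, rows = 224L, cols = 224L,
                              n_bands = 30L, seed = 1L,
                              params = detection_params()) {
  lib <- default_spectra(n_bands)
  classifier <- train_classifier(lib, seed = seed)
  templates <- render_templates()
  per <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    s <- seed * 1000L + i
    n_mounds <- 3L + (i - 1L) %% 4L
    mounds <- sample_mounds(n_mounds, rows, cols, seed = s)
    spec <- scene_spec(rows = rows, cols = cols, n_bands = n_bands,
                       mounds = mounds, noise_sd = 0, blur_sigma_px = 0,
                       distortion_amp_px = 0, seed = s)
    scn <- generate_scene(spec, lib)
    refl <- to_reflectance(scn$cube, scn$white)
    labels <- classify_cube(refl, classifier)
    match_px <- sum(unclass(labels) == scn$truth$material_raster)
    layers <- extract_layers(labels, lib, c("Eroded Soil", "Light Grass"))
    det <- detect_mounds(layers[[1]], layers[[2]], templates, params)
    ec <- match_detections(det$detections, scn$truth)
    per[[i]] <- data.frame(scene = i, n_mounds = n_mounds,
                           label_match = match_px / (rows * cols),
                           tp = ec$tp, fn = ec$fn, fp = ec$fp)
  }
  per <- do.call(rbind, per)
  list(label_accuracy = sum(per$label_match) / n_scenes,
       recall = sum(per$tp) / sum(per$tp + per$fn),
       false_positives = sum(per$fp),
       n_mounds = sum(per$n_mounds),
       per_scene = per)
}

#' Detection degradation under geometric distortion
#'
#' Measures mean detection recall as the amplitude of the smooth sinusoidal
#' distortion field rises, holding everything else fixed (common random
#' numbers: each seed reuses one mound layout and one displacement-field
#' shape across all amplitudes). Detection runs on the generator's exact
#' material layers so that the measured degradation isolates the shape
#' analysis: distortion deforms the soil cores away from the oval/diamond
#' templates and breaks up the grass rings.
#'
#' @param amps Distortion amplitudes (px) to sweep.
#' @param n_seeds Seeds (scenes) per amplitude.
#' @param rows,cols Scene extent.
#' @param n_mounds Mounds per scene.
#' @param seed Master seed.
#' @param params A [detection_params()].
#' @return List: `amps`, `mean_recall` (one value per amplitude), `per_run`
#'   data frame.
#' @export
distortion_benchmark <- function(amps = c(0, 1, 2, 4), n_seeds = 20L,
                                 rows = 224L, cols = 224L, n_mounds = 4L,
                                 seed = 1L, params = detection_params()) {
  lib <- default_spectra(12L)
  soil_idx <- match("Eroded Soil", lib$names)
  grass_idx <- match("Light Grass", lib$names)
  templates <- render_templates()
  runs <- list()
  for (k in seq_len(n_seeds)) {
    s <- seed * 1000L + k
    mounds <- sample_mounds(n_mounds, rows, cols, seed = s)
    for (a in amps) {
      spec <- scene_spec(rows = rows, cols = cols, n_bands = 12L,
                         mounds = mounds, noise_sd = 0, blur_sigma_px = 0,
                         distortion_amp_px = a, seed = s)
      scn <- generate_scene(spec, lib)
      raster <- scn$truth$material_raster
      soil <- (raster == soil_idx) + 0
      grass <- (raster == grass_idx) + 0
      det <- detect_mounds(soil, grass, templates, params)
      ec <- match_detections(det$detections, scn$truth)
      runs[[length(runs) + 1L]] <- data.frame(seed = s, amp = a, tp = ec$tp,
                                              fn = ec$fn, fp = ec$fp,
                                              recall = ec$tp / (ec$tp + ec$fn))
    }
  }
  per_run <- do.call(rbind, runs)
  mean_recall <- vapply(amps, function(a) mean(per_run$recall[per_run$amp == a]), 0)
  list(amps = amps, mean_recall = mean_recall, per_run = per_run)
}
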