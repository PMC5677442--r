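# Two-layer contour detector: condition the eroded-soil and light-grass
# masks, gate on their spatial overlap, shape-filter soil contours against
# the mound templates, and confirm each candidate by the proximity and size
# of a surrounding grass contour.

#' Detection thresholds
#'
#' Defaults are the operating point of the detector: a soil contour is kept
#' when its best template match ratio is at most `ratio_max` and its
#' perimeter at least `perimeter_min_px`; it becomes a detection when some
#' grass contour lies within `radius_factor` times the soil contour's
#' enclosing radius (centroid distance), has perimeter at least
#' `perimeter_prop_min` times the soil perimeter (or larger outright), and
#' approaches it to within `ild_max_px` (minimum point-to-point distance).
#'
#' @param ratio_max Hu match ratio ceiling (default 0.15).
#' @param perimeter_min_px Minimum soil contour perimeter in px (default 10).
#' @param dilation_iters Dilations applied to the conditioned soil layer when
#'   building the overlap halo (default 2).
#' @param radius_factor Centroid-distance gate as a multiple of the soil
#'   contour's enclosing radius (default 1.2).
#' @param perimeter_prop_min Minimum grass/soil perimeter proportion
#'   (default 0.8).
#' @param ild_max_px Maximum minimum-intersection-line distance in px
#'   (default 2.5).
#' @param median_kernel Median filter kernel (odd; 3 is the only supported
#'   size, kept explicit because it is a named stage parameter).
#' @return A `detection_params` list.
#' @export
detection_params <- function(ratio_max = 0.15, perimeter_min_px = 10,
                             dilation_iters = 2L, radius_factor = 1.2,
                             perimeter_prop_min = 0.8, ild_max_px = 2.5,
                             median_kernel = 3L) {
  stopifnot(ratio_max > 0, perimeter_min_px > 0, is_count(dilation_iters),
            dilation_iters >= 1, radius_factor > 0, perimeter_prop_min > 0,
            ild_max_px > 0, is_count(median_kernel), median_kernel %% 2 == 1)
  if (median_kernel != 3L) abort_ms("only a 3 px median kernel is supported", "data_error")
  structure(list(ratio_max = ratio_max, perimeter_min_px = perimeter_min_px,
                 dilation_iters = as.integer(dilation_iters),
                 radius_factor = radius_factor,
                 perimeter_prop_min = perimeter_prop_min,
                 ild_max_px = ild_max_px, median_kernel = as.integer(median_kernel)),
            class = "detection_params")
}

as_binary_matrix <- function(layer) {
  m <- unclass(layer)
  if (!is.matrix(m) || !all(m %in% c(0, 1))) {
    abort_ms("expected a binary (0/1) matrix layer", "data_error")
  }
  m
}

#' Condition the soil layer
#'
#' 3x3 median (majority) filter followed by one binary closing with a 3x3
#' rectangular structuring element: despeckles the mask and seals small gaps
#' before contour extraction.
#'
#' @param layer Binary soil mask.
#' @param params A [detection_params()].
#' @return Conditioned binary mask of the same shape.
#' @export
condition_soil <- function(layer, params = detection_params()) {
  m <- as_binary_matrix(layer)
  close3(median3(m), "box")
}

#' Grass conditioning (median only)
#'
#' The grass branch is deliberately lighter than the soil branch: a single
#' 3x3 median pass, no closing.
#'
#' @inheritParams condition_soil
#' @export
condition_grass <- function(layer, params = detection_params()) {
  median3(as_binary_matrix(layer))
}

#' Build the soil overlap halo
#'
#' Dilates the conditioned soil layer `dilation_iters` times (default two)
#' with the 3x3 elliptical structuring element (the 4-connected cross at this
#' size). The halo reaches across the narrow bare gap between a mound's core
#' and its grass ring, so an AND with the grass layer is non-empty exactly
#' when the two layers nearly touch.
#'
#' @inheritParams condition_soil
#' @return Binary halo mask; a superset of the input pointwise.
#' @export
make_soil_halo <- function(layer, params = detection_params()) {
  m <- as_binary_matrix(layer)
  for (i in seq_len(params$dilation_iters)) m <- dilate3(m, "cross")
  m
}

#' Overlap gate between grass layer and soil halo
#'
#' `T2 = grass AND halo`; the scene passes when the mean intensity of `T2`
#' (foreground fraction) is strictly positive, i.e. the layers touch
#' somewhere. A mound-free scene fails here and skips all contour analysis.
#'
#' @param grass Median-filtered grass mask.
#' @param halo Soil halo from [make_soil_halo()].
#' @return `list(passes = logical, mean = foreground fraction, T2 = mask)`.
#' @export
overlap_gate <- function(grass, halo) {
  g <- as_binary_matrix(grass); h <- as_binary_matrix(halo)
  if (!all(dim(g) == dim(h))) abort_ms("grass and halo shapes differ", "alignment_error")
  T2 <- g * h
  mn <- sum(T2) / length(T2)
  list(passes = mn > 0, mean = mn, T2 = T2)
}

#' Shape-filter soil contours against the template set
#'
#' Keeps a soil contour when its perimeter is at least
#' `params$perimeter_min_px` and the minimum Hu match ratio over all
#' templates is at most `params$ratio_max`. Degenerate contours (fewer than
#' 3 boundary points or zero area) are discarded. The winning template name
#' and ratio are attached to each kept contour.
#'
#' @param contours List of `contour`s from [find_contours()].
#' @param templates A `shape_template_set`.
#' @param params A [detection_params()].
#' @return Filtered list of `contour`s with `best_ratio`/`best_template` set.
#' @export
filter_soil_contours <- function(contours, templates, params = detection_params()) {
  stopifnot(inherits(templates, "shape_template_set"))
  if (!length(templates$templates)) abort_ms("empty template set", "data_error")
  keep <- list()
  for (ct in contours) {
    if (ct$degenerate || ct$perimeter_px < params$perimeter_min_px) next
    hv <- log_hu(ct)
    ratios <- vapply(templates$templates, function(t) shape_ratio(hv, t$log_hu), 0)
    best <- which.min(ratios)
    if (ratios[best] <= params$ratio_max) {
      ct$best_ratio <- ratios[best]
      ct$best_template <- templates$templates[[best]]$name
      keep[[length(keep) + 1L]] <- ct
    }
  }
  keep
}

# Minimum point-to-point Euclidean distance between two contours (ILD).
min_contour_distance <- function(a, b) {
  pa <- a$points; pb <- b$points
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  sqrt(min(d2))
}

#' Pair filtered soil contours with grass contours
#'
#' A detection is emitted for a soil contour when at least one grass contour
#' satisfies all three gates: centroid distance `d <= radius_factor * rad`
#' (rad = soil enclosing radius), perimeter gate `P_gc >= P_sc` or
#' `P_gc / P_sc >= perimeter_prop_min`, and minimum intersection line
#' distance `ILD <= ild_max_px`. A soil contour with several qualifying
#' partners yields one detection listing all of them; the reported `d`,
#' `ild` and `prop` are those of the nearest qualifying partner.
#'
#' @param soil Filtered soil `contour`s (from [filter_soil_contours()]).
#' @param grass Grass `contour`s of the same ROI.
#' @param params A [detection_params()].
#' @return List of `detection` objects.
#' @export
pair_and_confirm <- function(soil, grass, params = detection_params()) {
  detections <- list()
  for (sc in soil) {
    partners <- list(); ds <- numeric(0); ilds <- numeric(0); props <- numeric(0)
    for (gc in grass) {
      if (gc$degenerate && gc$perimeter_px <= 0) next
      d <- sqrt((sc$centroid[["x"]] - gc$centroid[["x"]])^2 +
                (sc$centroid[["y"]] - gc$centroid[["y"]])^2)
      if (d > params$radius_factor * sc$enclosing_radius_px) next
      prop <- gc$perimeter_px / sc$perimeter_px
      if (!(gc$perimeter_px >= sc$perimeter_px || prop >= params$perimeter_prop_min)) next
      ild <- min_contour_distance(sc, gc)
      if (ild > params$ild_max_px) next
      partners[[length(partners) + 1L]] <- gc
      ds <- c(ds, d); ilds <- c(ilds, ild); props <- c(props, prop)
    }
    if (length(partners)) {
      i <- which.min(ds)
      detections[[length(detections) + 1L]] <- structure(list(
        soil_contour = sc,
        paired_grass_contours = partners,
        best_ratio = sc$best_ratio,
        best_template = sc$best_template,
        d_px = ds[i], ild_px = ilds[i], prop = props[i],
        centroid = sc$centroid
      ), class = "detection")
    }
  }
  detections
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf(
    "<detection> centroid (%.1f, %.1f), template %s (ratio %.3f), d %.1f px, ILD %.1f px, prop %.2f, %d grass partner(s)\n",
    x$centroid[["x"]], x$centroid[["y"]], x$best_template, x$best_ratio,
    x$d_px, x$ild_px, x$prop, length(x$paired_grass_contours)))
  invisible(x)
}

# RGB overlay: soil-detection contours red, paired grass contours green,
# over the union of the two conditioned layers in gray.
draw_overlay <- function(soil_mask, grass_mask, detections) {
  nr <- nrow(soil_mask); nc <- ncol(soil_mask)
  base <- 0.25 * soil_mask + 0.18 * grass_mask
  ov <- array(base, c(nr, nc, 3))
  paint <- function(ov, pts, channel) {
    idx <- cbind(pts[, 1] + 1, pts[, 2] + 1)
    for (ch in 1:3) {
      v <- if (ch == channel) 1 else 0
      ov[cbind(idx, ch)] <- v
    }
    ov
  }
  for (det in detections) {
    for (gc in det$paired_grass_contours) ov <- paint(ov, gc$points, 2L)
    ov <- paint(ov, det$soil_contour$points, 1L)
  }
  ov
}

#' Detect termite mounds from the two material layers
#'
#' End-to-end two-layer detector: condition the soil layer (median +
#' closing), median-filter the grass layer, build the dilated soil halo and
#' gate on its AND-overlap with the grass layer (an empty overlap
#' short-circuits to zero detections), trace soil contours, shape-filter
#' them against the templates, trace grass contours and confirm each soil
#' candidate by grass proximity.
#'
#' @param soil,grass Binary layers of one ROI ("Eroded Soil" and
#'   "Light Grass" masks from [extract_layers()]).
#' @param templates A `shape_template_set` ([render_templates()] or
#'   [read_templates()]).
#' @param params A [detection_params()].
#' @return List with `detections` (list of `detection`s), `overlay`
#'   (rows x cols x 3 RGB array with detected soil contours in red and paired
#'   grass contours in green), and `gate` (the [overlap_gate()] result).
#' @export
detect_mounds <- function(soil, grass, templates = render_templates(),
                          params = detection_params()) {
  s <- as_binary_matrix(soil); g <- as_binary_matrix(grass)
  if (!all(dim(s) == dim(g))) abort_ms("soil and grass shapes differ", "alignment_error")
  s_cond <- condition_soil(s, params)
  g_cond <- condition_grass(g, params)
  halo <- make_soil_halo(s_cond, params)
  gate <- overlap_gate(g_cond, halo)
  if (!gate$passes) {
    return(list(detections = list(), overlay = draw_overlay(s_cond, g_cond, list()),
                gate = gate))
  }
  # mound cores are filled regions: outer soil borders only; grass rings can
  # be annular, so their inner (hole) rims are traced as well
  soil_contours <- find_contours(s_cond, holes = FALSE)
  kept <- filter_soil_contours(soil_contours, templates, params)
  grass_contours <- find_contours(g_cond, holes = TRUE)
  detections <- pair_and_confirm(kept, grass_contours, params)
  list(detections = detections,
       overlay = draw_overlay(s_cond, g_cond, detections),
       gate = gate)
}

#' Export detections as JSON
#'
#' One record per detection: contour polygon (0-based row/col pixel
#' centres), centroid, match scores, pairing distances and template name.
#'
#' @param detections List of `detection`s from [detect_mounds()].
#' @param path Output path; when `NULL` the JSON string is returned.
#' @param fingerprint Optional configuration fingerprint to embed.
#' @export
write_detections <- function(detections, path = NULL, fingerprint = NULL) {
  recs <- lapply(detections, function(d) list(
    centroid = list(x = unname(d$centroid[["x"]]), y = unname(d$centroid[["y"]])),
    polygon = apply(d$soil_contour$points, 1, function(p) list(row = p[1], col = p[2])),
    area_px2 = d$soil_contour$area_px2,
    perimeter_px = d$soil_contour$perimeter_px,
    best_template = d$best_template,
    best_ratio = d$best_ratio,
    d_px = d$d_px, ild_px = d$ild_px, prop = d$prop,
    n_grass_partners = length(d$paired_grass_contours)
  ))
  obj <- list(n_detections = length(recs), detections = recs)
  if (!is.null(fingerprint)) obj$config_fingerprint <- fingerprint
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
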