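# Synthetic hyperspectral scene generator with exact ground truth.
#
# Emulates the survey scenery: eroded-soil mound cores (oval or diamond,
# rotated) ringed by light grass, over a patchy background of other soil and
# vegetation materials, imaged in VNIR radiance at a configurable ground
# sample distance with optional blur, smooth spatial distortion and noise.

#' Synthetic scene specification
#'
#' @param rows,cols Raster extent in pixels.
#' @param n_bands Number of spectral bands over 385-1000 nm.
#' @param gsd_cm_per_px Ground sample distance (default 4.7 cm/px, the
#'   hyperspectral resolution of the survey flights this generator emulates).
#' @param mounds List of mound descriptions:
#'   `list(center = c(row, col), core_axes_px = c(a, b), ring_width_px =,
#'   shape = "oval"|"diamond", rotation_deg =)`. `core_axes_px` are
#'   semi-axes; defaults for missing fields come from
#'   [default_mound_axes_px()] and a 3 px ring.
#' @param background_materials Names of the library materials to mix into the
#'   background patches (defaults to every material except the two mound
#'   layers).
#' @param noise_sd Per-pixel Gaussian noise s.d. in reflectance units.
#' @param blur_sigma_px Gaussian blur s.d. (0 disables).
#' @param distortion_amp_px Amplitude of a smooth sinusoidal displacement
#'   field (0 disables), emulating uncorrected geometric distortion.
#' @param seed Integer seed; scenes are bit-reproducible under it.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(rows = 256L, cols = 256L, n_bands = 30L,
                       gsd_cm_per_px = 4.7, mounds = list(),
                       background_materials = NULL,
                       noise_sd = 0.01, blur_sigma_px = 0.5,
                       distortion_amp_px = 0, seed = 1L) {
  stopifnot(rows >= 8, cols >= 8, n_bands >= 10, gsd_cm_per_px > 0,
            noise_sd >= 0, blur_sigma_px >= 0, distortion_amp_px >= 0)
  mounds <- lapply(mounds, function(m) {
    if (is.null(m$core_axes_px)) m$core_axes_px <- default_mound_axes_px(gsd_cm_per_px)
    if (is.null(m$ring_width_px)) m$ring_width_px <- 3
    if (is.null(m$shape)) m$shape <- "oval"
    if (is.null(m$rotation_deg)) m$rotation_deg <- 0
    stopifnot(length(m$center) == 2L, all(m$core_axes_px > 0),
              m$ring_width_px > 0, m$shape %in% c("oval", "diamond"))
    m
  })
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 n_bands = as.integer(n_bands), gsd_cm_per_px = gsd_cm_per_px,
                 mounds = mounds, background_materials = background_materials,
                 noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
                 distortion_amp_px = distortion_amp_px, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default mound core semi-axes at a given resolution
#'
#' Surveyed mounds have a mean bounding rectangle of about 1.951 m^2 with a
#' mildly elongated core; this converts that footprint to pixel semi-axes at
#' the scene's ground sample distance (aspect ratio 1.25).
#'
#' @param gsd_cm_per_px Ground sample distance in cm/pixel.
#' @return `c(a, b)` semi-axes in pixels.
#' @export
default_mound_axes_px <- function(gsd_cm_per_px = 4.7) {
  area_px2 <- 1.951 * 1e4 / gsd_cm_per_px^2   # bounding rectangle, px^2
  aspect <- 1.25
  # bounding rectangle of the core is (2a) x (2b)
  b <- sqrt(area_px2 / aspect) / 2
  c(a = b * aspect, b = b)
}

#' Reference material spectra for synthetic scenes
#'
#' A ten-material VNIR library (385-1000 nm) of smooth synthetic reflectance
#' curves, including the two mound-diagnostic materials "Eroded Soil" and
#' "Light Grass". Inter-material contrast is concentrated in the 540-700 nm,
#' 720-800 nm and 924-1000 nm windows, where field spectra of soils and
#' vegetation differ most; differences elsewhere are small. Pure function of
#' `n_bands`.
#'
#' @param n_bands Number of bands (>= 10).
#' @return A [material_library].
#' @export
default_spectra <- function(n_bands = 30L) {
  stopifnot(n_bands >= 10L)
  wl <- seq(385, 1000, length.out = n_bands)
  bump <- function(lo, hi) {
    # raised-cosine bump supported on [lo, hi]
    t <- (wl - lo) / (hi - lo)
    ifelse(t > 0 & t < 1, 0.5 * (1 - cos(2 * pi * t)), 0)
  }
  w1 <- bump(540, 700); w2 <- bump(720, 800); w3 <- bump(924, 1000)
  base <- 0.18 + 0.05 * (wl - 385) / 615
  # name, window amplitudes (a1, a2, a3), flat offset
  tab <- list(
    list("Eroded Soil",   0.42,  0.30,  0.28,  0.012),
    list("Light Grass",   0.30,  0.55,  0.10,  0.010),
    list("Dry Grass",     0.22,  0.18,  0.40,  0.008),
    list("Green Bush",    0.08,  0.45,  0.05,  0.006),
    list("Olive Bush",    0.14,  0.32,  0.18,  0.004),
    list("Red Soil",      0.34,  0.12,  0.34,  0.002),
    list("Pale Soil",     0.26,  0.22,  0.50,  0.000),
    list("Shrub",         0.05,  0.26,  0.24, -0.004),
    list("Woody Debris",  0.18,  0.05,  0.14, -0.008),
    list("Shadow",       -0.10, -0.08, -0.06, -0.012)
  )
  spectra <- t(vapply(tab, function(m) {
    pmin(pmax(base + m[[2]] * w1 + m[[3]] * w2 + m[[4]] * w3 + m[[5]], 0), 1)
  }, numeric(n_bands)))
  material_library(vapply(tab, `[[`, "", 1), spectra, wl)
}

# Mask of one mound component (core or core + ring) on the scene grid.
mound_mask <- function(rows, cols, m, grow = 0) {
  a <- m$core_axes_px[1] + grow; b <- m$core_axes_px[2] + grow
  th <- m$rotation_deg * pi / 180
  rs <- seq_len(rows); cs <- seq_len(cols)
  dy <- matrix(rs - m$center[1], rows, cols)
  dx <- matrix(rep(cs - m$center[2], each = rows), rows, cols)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- if (m$shape == "oval") (u / a)^2 + (v / b)^2 <= 1
            else abs(u) / a + abs(v) / b <= 1
  inside + 0
}

# Separable Gaussian blur with replicate padding.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2)); k <- k / sum(k)
  acc <- 0
  for (i in seq_along(k)) acc <- acc + k[i] * shift_replicate(m, i - rad - 1L, 0L)
  m <- acc; acc <- 0
  for (i in seq_along(k)) acc <- acc + k[i] * shift_replicate(m, 0L, i - rad - 1L)
  acc
}

#' Generate a synthetic hyperspectral scene
#'
#' Paints each mound as an eroded-soil core surrounded by a light-grass ring
#' over seeded Voronoi background patches of the remaining materials, then
#' renders the material raster to radiance through a smooth synthetic
#' illuminant (so that [to_reflectance()] inverts it exactly), optionally
#' warps the raster by a smooth sinusoidal displacement field, blurs, and
#' adds per-pixel Gaussian noise.
#'
#' @param spec A [scene_spec()].
#' @param library A [material_library] containing `"Eroded Soil"` and
#'   `"Light Grass"` (default: [default_spectra()]).
#' @return List with elements `cube` (radiance [hypercube]), `white`
#'   (`white_reference`), and `truth` (a `ground_truth_set`: one entry per
#'   mound with centroid, shape label, core/ring polygons, plus the full
#'   post-distortion `material_raster` of 1-based library indices).
#' @export
generate_scene <- function(spec, library = default_spectra(spec$n_bands)) {
  stopifnot(inherits(spec, "scene_spec"), inherits(library, "material_library"))
  need <- c("Eroded Soil", "Light Grass")
  if (!all(need %in% library$names)) {
    abort_ms("library must contain 'Eroded Soil' and 'Light Grass'", "lookup_error")
  }
  if (length(library$wavelengths_nm) != spec$n_bands) {
    abort_ms("library band count does not match scene spec", "alignment_error")
  }
  rows <- spec$rows; cols <- spec$cols
  soil_idx <- match("Eroded Soil", library$names)
  grass_idx <- match("Light Grass", library$names)
  bg_names <- spec$background_materials
  if (is.null(bg_names)) bg_names <- setdiff(library$names, need)
  bg_idx <- match(bg_names, library$names)
  if (anyNA(bg_idx)) abort_ms("unknown background material name", "lookup_error")

  with_seed(spec$seed, {
    # background: contiguous Voronoi patches of the background materials
    n_sites <- max(3L, as.integer(rows * cols / 2500))
    sr <- stats::runif(n_sites, 1, rows); sc <- stats::runif(n_sites, 1, cols)
    site_mat <- sample(bg_idx, n_sites, replace = TRUE)
    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(rep(seq_len(cols), each = rows), rows, cols)
    best_d <- matrix(Inf, rows, cols); lab <- matrix(site_mat[1], rows, cols)
    for (s in seq_len(n_sites)) {
      d <- (rr - sr[s])^2 + (cc - sc[s])^2
      upd <- d < best_d
      lab[upd] <- site_mat[s]; best_d[upd] <- d[upd]
    }

    # mounds: light-grass ring first, eroded-soil core on top
    footprints <- vector("list", length(spec$mounds))
    truth <- vector("list", length(spec$mounds))
    for (i in seq_along(spec$mounds)) {
      m <- spec$mounds[[i]]
      core <- mound_mask(rows, cols, m)
      outer_m <- mound_mask(rows, cols, m, grow = m$ring_width_px)
      if (sum(core) < 3) abort_ms("mound core lies outside the raster or is too small",
                                  "bounds_error")
      footprints[[i]] <- outer_m
      for (j in seq_len(i - 1)) {
        if (any(footprints[[j]] * outer_m > 0)) {
          abort_ms(sprintf("mounds %d and %d overlap", j, i), "data_error")
        }
      }
      lab[outer_m > 0] <- grass_idx
      lab[core > 0] <- soil_idx
      core_cs <- find_contours(core); ring_cs <- find_contours(outer_m)
      truth[[i]] <- list(
        centroid = c(row = m$center[1], col = m$center[2]),
        shape = m$shape,
        core_axes_px = m$core_axes_px,
        core_polygon = core_cs[[1]]$points,
        ring_polygon = ring_cs[[1]]$points
      )
    }

    # smooth sinusoidal distortion: inverse-warp the label raster
    if (spec$distortion_amp_px > 0) {
      # wavelength comparable to the mound footprint: the field shears and
      # squeezes shapes locally instead of translating them rigidly
      ph <- stats::runif(4, 0, 2 * pi)
      wav <- stats::runif(2, 30, 80)
      dy <- spec$distortion_amp_px * sin(2 * pi * cc / wav[2] + ph[1]) *
        cos(2 * pi * rr / wav[1] + ph[2])
      dx <- spec$distortion_amp_px * sin(2 * pi * rr / wav[1] + ph[3]) *
        cos(2 * pi * cc / wav[2] + ph[4])
      src_r <- pmin(pmax(round(rr - dy), 1), rows)
      src_c <- pmin(pmax(round(cc - dx), 1), cols)
      lab <- matrix(lab[cbind(as.vector(src_r), as.vector(src_c))], rows, cols)
    }

    # render: reflectance -> radiance under a smooth synthetic illuminant
    wl <- library$wavelengths_nm
    illum <- 0.6 + 0.4 * sin(pi * (wl - 385) / 615)   # positive, smooth
    refl <- library$spectra[as.vector(lab), , drop = FALSE]
    cube_arr <- array(refl, c(rows, cols, spec$n_bands))
    for (b in seq_len(spec$n_bands)) {
      band <- cube_arr[, , b] * illum[b]
      if (spec$blur_sigma_px > 0) band <- gauss_blur(band, spec$blur_sigma_px)
      if (spec$noise_sd > 0) {
        band <- band + stats::rnorm(rows * cols, sd = spec$noise_sd * illum[b])
      }
      cube_arr[, , b] <- pmax(band, 0)
    }
    list(
      cube = hypercube(cube_arr, wl, quantity = "radiance",
                       gsd_cm_per_px = spec$gsd_cm_per_px),
      white = white_reference(wl, illum),
      truth = structure(list(mounds = truth, material_raster = lab,
                             material_names = library$names),
                        class = "ground_truth_set")
    )
  })
}

#' @export
print.ground_truth_set <- function(x, ...) {
  cat(sprintf("<ground_truth_set> %d mounds on a %d x %d raster\n",
              length(x$mounds), nrow(x$material_raster), ncol(x$material_raster)))
  invisible(x)
}

#' Randomly placed non-overlapping mounds for a scene
#'
#' Convenience sampler used by the test-bench and the pipeline examples:
#' draws `n` mound descriptions with random centres (rejection-sampled so
#' footprints stay inside the raster and apart), shapes alternating between
#' oval and diamond, and random rotations.
#'
#' @param n Number of mounds.
#' @param rows,cols Scene extent.
#' @param gsd_cm_per_px Resolution, passed to [default_mound_axes_px()].
#' @param ring_width_px Grass ring width.
#' @param seed Integer seed.
#' @return A list suitable for `scene_spec(mounds = )`.
#' @export
sample_mounds <- function(n, rows, cols, gsd_cm_per_px = 4.7, ring_width_px = 3,
                          seed = 1L) {
  axes <- default_mound_axes_px(gsd_cm_per_px)
  rad <- max(axes) + ring_width_px + 2
  with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < n && tries < 4000L) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, rad + 1, rows - rad), stats::runif(1, rad + 1, cols - rad))
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) > 2 * rad + 2)) {
        centers <- rbind(centers, cand)
      }
    }
    if (nrow(centers) < n) {
      abort_ms(sprintf("could not place %d non-overlapping mounds on %d x %d", n, rows, cols),
               "data_error")
    }
    lapply(seq_len(n), function(i) list(
      center = centers[i, ],
      core_axes_px = axes,
      ring_width_px = ring_width_px,
      shape = if (i %% 2 == 1) "oval" else "diamond",
      rotation_deg = stats::runif(1, 0, 180)
    ))
  })
}
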