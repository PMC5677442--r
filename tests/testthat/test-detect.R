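# Layer conditioning, overlap gating, shape filtering and pairing.

concentric_pair <- function(n = 64, r_core = 10, gap = 1, ring = 3) {
  ctr <- n / 2
  soil <- shape_mask(n, n, c(ctr, ctr), r_core, r_core)
  grass <- shape_mask(n, n, c(ctr, ctr), r_core + gap + ring, r_core + gap + ring) -
    shape_mask(n, n, c(ctr, ctr), r_core + gap, r_core + gap)
  list(soil = soil, grass = grass, center = c(ctr, ctr))
}

test_that("soil conditioning despeckles and stabilises", {
  z <- matrix(0, 12, 12)
  expect_equal(condition_soil(z), z)
  # a single isolated pixel is removed by the majority filter
  one <- z; one[6, 6] <- 1
  expect_equal(condition_soil(one), z)
  # a solid square keeps its interior; conditioning is idempotent on it
  sq <- z; sq[3:10, 3:10] <- 1
  cond <- condition_soil(sq)
  expect_true(all(cond[4:9, 4:9] == 1))
  expect_equal(condition_soil(cond), cond)
  # idempotent on smooth (oval) mound cores; diamond tips can take an extra
  # pass to settle, a known property of the majority filter
  ax <- default_mound_axes_px(4.7)
  for (s in 1:5) {
    set.seed(s)
    m <- shape_mask(70, 70, c(35, 35), ax[1], ax[2], runif(1, 0, 180), "oval")
    cond <- condition_soil(m)
    expect_equal(condition_soil(cond), cond)
  }
  # sparse speckle is wiped out entirely
  set.seed(77)
  speck <- matrix(rbinom(400, 1, 0.04), 20, 20)
  expect_equal(condition_soil(speck), matrix(0, 20, 20))
})

test_that("the soil halo is a double cross dilation", {
  z <- matrix(0, 11, 11)
  one <- z; one[6, 6] <- 1
  halo <- make_soil_halo(one)
  # diamond of radius 2 under the 4-connected cross: 13 pixels
  expect_equal(sum(halo), 13)
  rr <- abs(row(z) - 6) + abs(col(z) - 6)
  expect_equal(halo, (rr <= 2) + 0, ignore_attr = TRUE)
  expect_equal(make_soil_halo(z), z)
  full <- matrix(1, 11, 11)
  expect_equal(make_soil_halo(full), full)
  # dilation is extensive
  blob <- (random_blob(4) > 0) + 0
  expect_true(all(make_soil_halo(blob) >= blob))
})

test_that("the overlap gate measures the AND-mask mean", {
  a <- matrix(0, 10, 10); a[2:4, 2:4] <- 1
  b <- matrix(0, 10, 10); b[7:9, 7:9] <- 1
  g <- overlap_gate(a, b)
  expect_false(g$passes)
  expect_equal(g$mean, 0)
  expect_equal(sum(g$T2), 0)

  g2 <- overlap_gate(a, a)
  expect_true(g2$passes)
  expect_equal(g2$mean, 9 / 100)

  c1 <- matrix(0, 10, 10); c1[2, 2] <- 1
  g3 <- overlap_gate(a, c1)
  expect_true(g3$passes)
  expect_equal(g3$mean, 0.01)

  expect_error(overlap_gate(a, matrix(0, 5, 5)), class = "moundscan_alignment_error")
})

test_that("soil contours are filtered by template likeness and perimeter", {
  tpl <- render_templates()
  # the template's own contour is a perfect match
  timg <- tpl$templates[[1]]$image
  ct <- main_contour(timg)
  kept <- filter_soil_contours(list(ct), tpl)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$best_ratio, 0, tolerance = 1e-12)
  expect_identical(kept[[1]]$best_template, tpl$templates[[1]]$name)

  # matching shape but tiny perimeter (< 10 px) is discarded
  small <- main_contour(disk_mask(1))
  expect_length(filter_soil_contours(list(small), tpl), 0)

  # a thin elongated bar does not resemble any oval/diamond template
  thin <- matrix(0, 40, 160); thin[19:22, 8:152] <- 1
  bar <- main_contour(thin)
  expect_length(filter_soil_contours(list(bar), tpl), 0)
})

test_that("pairing requires proximity, ring size and a small gap", {
  cp <- concentric_pair()
  tpl <- render_templates()
  soil_ct <- filter_soil_contours(find_contours(cp$soil, holes = FALSE), tpl)
  grass_ct <- find_contours(cp$grass, holes = TRUE)
  det <- pair_and_confirm(soil_ct, grass_ct)
  expect_length(det, 1)
  expect_lt(det[[1]]$d_px, 1)
  expect_lte(det[[1]]$ild_px, 2.5)
  expect_gte(det[[1]]$prop, 0.8)

  # grass ring translated far away: centroid gate fails
  far <- matrix(0, 64, 64)
  far[2:10, 2:10] <- cp$grass[27:35, 27:35]
  expect_length(pair_and_confirm(soil_ct, find_contours(far, holes = TRUE)), 0)

  # tiny grass fleck adjacent to the core: perimeter-proportion gate fails
  fleck <- matrix(0, 64, 64); fleck[32, 19:21] <- 1
  expect_length(pair_and_confirm(soil_ct, find_contours(fleck, holes = TRUE)), 0)
})

test_that("the detector runs end to end and short-circuits mound-free scenes", {
  tpl <- render_templates()
  cp <- concentric_pair()
  # disjoint layers short-circuit at the gate
  lone <- matrix(0, 64, 64); lone[5:9, 50:60] <- 1
  res0 <- detect_mounds(cp$soil, lone, tpl)
  expect_false(res0$gate$passes)
  expect_length(res0$detections, 0)

  # three clean planted mounds, found at the planted centroids
  n <- 200
  soil <- matrix(0, n, n); grass <- matrix(0, n, n)
  centers <- list(c(40, 40), c(60, 140), c(150, 80))
  for (cc in centers) {
    soil <- pmax(soil, shape_mask(n, n, cc, 14, 11, rotation_deg = 20))
    grass <- pmax(grass, shape_mask(n, n, cc, 18, 15, rotation_deg = 20) -
                    shape_mask(n, n, cc, 15, 12, rotation_deg = 20))
  }
  res <- detect_mounds(soil, grass, tpl)
  expect_length(res$detections, 3)
  found <- t(vapply(res$detections, function(d)
    c(d$centroid[["y"]] + 1, d$centroid[["x"]] + 1), numeric(2)))
  for (cc in centers) {
    expect_lte(min(sqrt((found[, 1] - cc[1])^2 + (found[, 2] - cc[2])^2)), 2)
  }
  # gate soundness: detections imply non-empty halo AND grass overlap
  expect_true(res$gate$passes)
  expect_gt(res$gate$mean, 0)

  # overlay marks the detected contours in red
  expect_equal(dim(res$overlay), c(n, n, 3))
  p1 <- res$detections[[1]]$soil_contour$points[1, ] + 1
  expect_equal(res$overlay[p1[1], p1[2], ], c(1, 0, 0))
})

test_that("detection is equivariant under rotation and translation", {
  n <- 120
  soil <- matrix(0, n, n); grass <- matrix(0, n, n)
  for (cc in list(c(35, 48), c(85, 70))) {
    soil <- pmax(soil, shape_mask(n, n, cc, 13, 10, rotation_deg = 35))
    grass <- pmax(grass, shape_mask(n, n, cc, 17, 14, rotation_deg = 35) -
                    shape_mask(n, n, cc, 14, 11, rotation_deg = 35))
  }
  tpl <- render_templates()
  base <- detect_mounds(soil, grass, tpl)
  expect_length(base$detections, 2)

  rot <- detect_mounds(t(soil)[n:1, ], t(grass)[n:1, ], tpl)   # 90 degrees
  expect_length(rot$detections, length(base$detections))
  # centroids transform with the rotation: (r, c) -> (n + 1 - c, r), 1-based
  base_rc <- t(vapply(base$detections, function(d)
    c(d$centroid[["y"]] + 1, d$centroid[["x"]] + 1), numeric(2)))
  rot_rc <- t(vapply(rot$detections, function(d)
    c(d$centroid[["y"]] + 1, d$centroid[["x"]] + 1), numeric(2)))
  mapped <- cbind(n + 1 - base_rc[, 2], base_rc[, 1])
  for (i in seq_len(nrow(mapped))) {
    expect_lte(min(sqrt((rot_rc[, 1] - mapped[i, 1])^2 +
                        (rot_rc[, 2] - mapped[i, 2])^2)), 1.5)
  }

  # integer translation
  sh <- function(m, dr, dc) {
    out <- matrix(0, n, n)
    out[(1 + dr):n, (1 + dc):n] <- m[1:(n - dr), 1:(n - dc)]
    out
  }
  tra <- detect_mounds(sh(soil, 7, 11), sh(grass, 7, 11), tpl)
  expect_length(tra$detections, length(base$detections))
  tra_rc <- t(vapply(tra$detections, function(d)
    c(d$centroid[["y"]] + 1, d$centroid[["x"]] + 1), numeric(2)))
  for (i in seq_len(nrow(base_rc))) {
    expect_lte(min(sqrt((tra_rc[, 1] - base_rc[i, 1] - 7)^2 +
                        (tra_rc[, 2] - base_rc[i, 2] - 11)^2)), 1e-6)
  }
})

test_that("relaxing thresholds never shrinks the detection set", {
  cp <- concentric_pair(gap = 2)   # slightly marginal geometry
  tpl <- render_templates()
  det_ids <- function(params) {
    res <- detect_mounds(cp$soil, cp$grass, tpl, params)
    vapply(res$detections, function(d)
      paste(round(d$centroid, 3), collapse = ","), "")
  }
  base <- det_ids(detection_params())
  for (params in list(detection_params(ratio_max = 0.3),
                      detection_params(ild_max_px = 5),
                      detection_params(radius_factor = 2))) {
    expect_true(all(base %in% det_ids(params)))
  }
})
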