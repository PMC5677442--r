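# Cube I/O, ROI cropping, band pre-cleaning and reflectance recovery.

make_cube <- function(nr = 4, nc = 4, nb = 3, seed = 1) {
  set.seed(seed)
  hypercube(array(runif(nr * nc * nb), c(nr, nc, nb)),
            seq(400, 900, length.out = nb))
}

test_that("write/read round trip is bit-exact for every interleave", {
  cube <- make_cube()
  for (il in c("bil", "bip", "bsq")) {
    hdr <- file.path(tempdir(), paste0("rt_", il, ".hdr"))
    write_cube(cube, hdr, interleave = il)
    back <- read_cube(hdr)
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm)
    expect_identical(back$quantity, "radiance")
  }
})

test_that("a generated scene survives the ENVI round trip", {
  lib <- default_spectra(12)
  spec <- scene_spec(rows = 24, cols = 20, n_bands = 12,
                     mounds = list(), seed = 5)
  scn <- generate_scene(spec, lib)
  hdr <- file.path(tempdir(), "scene_rt.hdr")
  write_cube(scn$cube, hdr)
  back <- read_cube(hdr)
  expect_identical(dim(back$data), c(24L, 20L, 12L))
  expect_identical(back$data, scn$cube$data)
})

test_that("inconsistent or broken headers are rejected with named fields", {
  cube <- make_cube(3, 3, 2)
  hdr <- file.path(tempdir(), "bad.hdr")
  write_cube(cube, hdr)
  # declare 2 bands but 3 wavelengths
  lines <- readLines(hdr)
  lines[grepl("^wavelength", lines)] <- "wavelength = {400, 650, 900}"
  writeLines(lines, hdr)
  expect_error(read_cube(hdr), "2 bands but 3 wavelengths",
               class = "moundscan_format_error")
  # drop a required key
  write_cube(cube, hdr)
  writeLines(grep("^samples", readLines(hdr), invert = TRUE, value = TRUE), hdr)
  expect_error(read_cube(hdr), "samples", class = "moundscan_format_error")
  # truncate the payload
  write_cube(cube, hdr)
  bin <- sub("\\.hdr$", "", hdr)
  writeBin(readBin(bin, "raw", 10), bin)
  expect_error(read_cube(hdr), "size mismatch", class = "moundscan_size_error")
})

test_that("ROI cropping follows 0-based half-open windows", {
  cube <- make_cube(4, 4, 3)
  reg_path <- file.path(tempdir(), "reg.csv")
  write.csv(data.frame(roi_id = c("full", "mid", "a", "b"),
                       row0 = c(0, 1, 0, 2), col0 = c(0, 1, 0, 2),
                       height = c(4, 2, 2, 2), width = c(4, 2, 2, 2)),
            reg_path, row.names = FALSE)
  reg <- read_roi_register(reg_path)

  expect_identical(crop_roi(cube, reg, "full")$data, cube$data)
  mid <- crop_roi(cube, reg, "mid")
  expect_identical(mid$data, cube$data[2:3, 2:3, , drop = FALSE])
  expect_equal(mid$wavelengths_nm, cube$wavelengths_nm)

  # two disjoint ROIs partition distinct pixels of the original
  a <- crop_roi(cube, reg, "a")$data
  b <- crop_roi(cube, reg, "b")$data
  expect_length(intersect(as.vector(a), as.vector(b)), 0)
  expect_true(all(c(as.vector(a), as.vector(b)) %in% as.vector(cube$data)))

  expect_error(crop_roi(cube, reg, "nope"), class = "moundscan_lookup_error")
  write.csv(data.frame(roi_id = "over", row0 = 3, col0 = 0, height = 3, width = 2),
            reg_path, row.names = FALSE)
  expect_error(crop_roi(cube, read_roi_register(reg_path), "over"),
               class = "moundscan_bounds_error")
})

test_that("band pre-cleaning is a proper grayscale closing", {
  # constant band unchanged
  flat <- hypercube(array(0.7, c(6, 6, 1)), 500)
  expect_equal(preclean_cube(flat)$data, flat$data)

  # single dark pixel in a bright field is raised to the neighbourhood level
  m <- matrix(0.9, 7, 7); m[4, 4] <- 0.1
  cube <- hypercube(array(m, c(7, 7, 1)), 500)
  cleaned <- preclean_cube(cube)
  # oracle: dilation then erosion on the 3x3 neighbourhood
  dil <- matrix(NA_real_, 7, 7); ero <- matrix(NA_real_, 7, 7)
  pad <- function(i, n) pmin(pmax(i, 1), n)
  for (r in 1:7) for (c in 1:7) {
    dil[r, c] <- max(m[pad((r - 1):(r + 1), 7), pad((c - 1):(c + 1), 7)])
  }
  for (r in 1:7) for (c in 1:7) {
    ero[r, c] <- min(dil[pad((r - 1):(r + 1), 7), pad((c - 1):(c + 1), 7)])
  }
  expect_equal(cleaned$data[, , 1], ero)
  expect_equal(cleaned$data[4, 4, 1], 0.9)

  # idempotence and extensivity on random bands
  cube <- make_cube(12, 10, 4, seed = 42)
  once <- preclean_cube(cube)
  twice <- preclean_cube(once)
  expect_equal(twice$data, once$data)
  expect_true(all(once$data >= cube$data - 1e-12))
})

test_that("reflectance recovery divides by the white spectrum and clips", {
  nb <- 5
  wl <- seq(400, 800, length.out = nb)
  w <- white_reference(wl, seq(0.5, 1.5, length.out = nb))
  arr <- array(rep(w$intensity, each = 6), c(2, 3, nb))
  cube <- hypercube(arr, wl)

  refl <- to_reflectance(cube, w)
  expect_equal(refl$data, array(1, c(2, 3, nb)))
  expect_identical(refl$quantity, "reflectance")

  zero <- hypercube(array(0, c(2, 2, nb)), wl)
  expect_equal(to_reflectance(zero, w)$data, array(0, c(2, 2, nb)))

  half <- hypercube(arr * 0.5, wl)
  expect_equal(to_reflectance(half, w)$data, array(0.5, c(2, 3, nb)))

  # homogeneity below the clip ceiling
  set.seed(7)
  rad <- hypercube(array(runif(2 * 3 * nb, 0, 0.4), c(2, 3, nb)), wl)
  r1 <- to_reflectance(rad, w)$data
  rad3 <- hypercube(rad$data * 3, wl)
  expect_equal(to_reflectance(rad3, w)$data, pmin(3 * r1, 2))

  # clipping at the ceiling
  big <- hypercube(arr * 10, wl)
  expect_equal(to_reflectance(big, w, ceiling = 2)$data, array(2, c(2, 3, nb)))
})

test_that("white spectra on a different grid are interpolated, never extrapolated", {
  wl <- c(450, 500, 550)
  cube <- hypercube(array(1, c(2, 2, 3)), wl)
  w <- white_reference(c(400, 600), c(1, 2))   # linear: 1.25, 1.5, 1.75
  refl <- to_reflectance(cube, w)
  expect_equal(refl$data[1, 1, ], 1 / c(1.25, 1.5, 1.75))

  w_short <- white_reference(c(470, 600), c(1, 2))
  expect_error(to_reflectance(cube, w_short), class = "moundscan_alignment_error")
  expect_error(to_reflectance(to_reflectance(cube, w), w),
               class = "moundscan_data_error")  # already reflectance
})

test_that("invalid constructions are rejected", {
  expect_error(hypercube(array(1, c(2, 2, 3)), c(500, 400, 600)),
               class = "moundscan_format_error")
  expect_error(hypercube(array(1, c(2, 2, 3)), c(400, 500)),
               class = "moundscan_format_error")
  expect_error(hypercube(array(-1, c(2, 2, 1)), 500),
               class = "moundscan_data_error")
  expect_error(white_reference(c(400, 500), c(1, 0)),
               class = "moundscan_data_error")
})
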