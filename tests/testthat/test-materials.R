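# Deterministic-annealing clustering, SVM classification, layer extraction.

three_material_cube <- function(n = 36, nb = 20, noise_sd = 0.01, seed = 99) {
  wl <- seq(400, 900, length.out = nb)
  sp <- rbind(seq(0.1, 0.3, length.out = nb),
              seq(0.6, 0.4, length.out = nb),
              rep(0.9, nb))
  set.seed(seed)
  lab <- sample(1:3, n * n, replace = TRUE)
  X <- pmax(sp[lab, ] + rnorm(n * n * nb, sd = noise_sd), 0)
  list(cube = hypercube(array(X, c(n, n, nb)), wl, "reflectance"),
       truth = matrix(lab, n, n), spectra = sp, wl = wl)
}

test_that("annealing parameters default to the documented operating point", {
  p <- da_params()
  expect_identical(p$max_clusters, 10L)
  expect_equal(p$t_max, 0.02)
  expect_equal(p$t_min, 0.00025)
  expect_equal(p$cooling, 0.8)
  expect_equal(p$split_threshold, 0.8)
  expect_identical(p$max_materials_per_pixel, 5L)
  expect_error(da_params(cooling = 1.2))
})

test_that("clustering recovers well-separated generating spectra", {
  tc <- three_material_cube(noise_sd = 0.01)
  lib <- cluster_materials(tc$cube, da_params(seed = 7))
  expect_length(lib$names, 3)
  for (i in 1:3) {
    errs <- apply(lib$spectra, 1, function(s) max(abs(s - tc$spectra[i, ])))
    expect_lt(min(errs), 3 * 0.01)
  }
  # same cube, same seed: identical library
  lib2 <- cluster_materials(tc$cube, da_params(seed = 7))
  expect_identical(lib$spectra, lib2$spectra)
})

test_that("a uniform cube collapses to a single material", {
  nb <- 15
  sp <- seq(0.2, 0.6, length.out = nb)
  cube <- hypercube(array(rep(sp, each = 36), c(6, 6, nb)),
                    seq(400, 900, length.out = nb), "reflectance")
  lib <- cluster_materials(cube)
  expect_length(lib$names, 1)
  expect_equal(as.vector(lib$spectra[1, ]), sp, tolerance = 1e-8)
})

test_that("the classifier reproduces library spectra and is deterministic", {
  tc <- three_material_cube()
  lib <- material_library(c("A", "B", "C"), tc$spectra, tc$wl)
  clf <- train_classifier(lib, seed = 3)
  # self-consistency: each library spectrum maps to its own label
  self <- classify_cube(hypercube(array(tc$spectra, c(3, 1, ncol(tc$spectra))),
                                  tc$wl, "reflectance"), clf)
  expect_identical(as.integer(self), 1:3)
  # ambiguous query answered identically on repeat
  mid <- (tc$spectra[1, ] + tc$spectra[3, ]) / 2
  midcube <- hypercube(array(rep(mid, each = 10), c(10, 1, ncol(tc$spectra))),
                       tc$wl, "reflectance")
  lab <- classify_cube(midcube, clf)
  expect_length(unique(as.vector(lab)), 1)
  # retraining with the same seed gives identical predictions
  clf2 <- train_classifier(lib, seed = 3)
  expect_identical(as.vector(classify_cube(tc$cube, clf)),
                   as.vector(classify_cube(tc$cube, clf2)))
})

test_that("noisy pixels classify to the generating material at >= 99%", {
  tc <- three_material_cube(noise_sd = 0.01)
  lib <- material_library(c("A", "B", "C"), tc$spectra, tc$wl)
  clf <- train_classifier(lib, seed = 5)
  lab <- classify_cube(tc$cube, clf)
  expect_gte(mean(unclass(lab) == tc$truth), 0.99)
})

test_that("a single-material library labels everything with that material", {
  wl <- seq(400, 900, length.out = 12)
  lib <- material_library("Only", matrix(0.5, 1, 12), wl)
  clf <- train_classifier(lib)
  cube <- hypercube(array(runif(3 * 3 * 12), c(3, 3, 12)), wl, "reflectance")
  expect_true(all(classify_cube(cube, clf) == 1L))
})

test_that("band-axis mismatches are refused", {
  tc <- three_material_cube(nb = 20)
  lib <- material_library(c("A", "B", "C"), tc$spectra, tc$wl)
  clf <- train_classifier(lib)
  other <- hypercube(array(0.5, c(2, 2, 10)), seq(400, 900, length.out = 10),
                     "reflectance")
  expect_error(classify_cube(other, clf), class = "moundscan_alignment_error")
})

test_that("layer extraction partitions the pixel grid", {
  tc <- three_material_cube()
  lib <- material_library(c("A", "B", "C"), tc$spectra, tc$wl)
  labels <- structure(tc$truth, materials = lib$names,
                      class = c("label_map", "matrix", "array"))
  layers <- extract_layers(labels, lib, c("A", "B", "C"))
  # pixel conservation over all materials
  expect_equal(Reduce(`+`, lapply(layers, sum)), length(tc$truth))
  expect_equal(Reduce(`+`, lapply(layers, unclass)),
               matrix(1, nrow(tc$truth), ncol(tc$truth)), ignore_attr = TRUE)
  # complementarity on a two-valued map
  two <- structure((tc$truth > 1) + 1, materials = c("lo", "hi"),
                   class = c("label_map", "matrix", "array"))
  l2 <- extract_layers(two, structure(list(names = c("lo", "hi")),
                                      class = "material_library"), c("lo", "hi"))
  expect_equal(unclass(l2$lo) + unclass(l2$hi),
               matrix(1, nrow(tc$truth), ncol(tc$truth)), ignore_attr = TRUE)
  # requesting an absent material yields zeros, an unknown one an error
  only_a <- structure(matrix(1L, 3, 3), materials = lib$names,
                      class = c("label_map", "matrix", "array"))
  l3 <- extract_layers(only_a, lib, c("A", "C"))
  expect_equal(sum(l3$A), 9)
  expect_equal(sum(l3$C), 0)
  expect_error(extract_layers(only_a, lib, "Z"), class = "moundscan_lookup_error")
})

test_that("library CSV round trip preserves names and spectra", {
  lib <- default_spectra(18)
  p <- file.path(tempdir(), "lib.csv")
  write_material_library(lib, p)
  back <- read_material_library(p)
  expect_identical(back$names, lib$names)
  expect_equal(back$spectra, lib$spectra, tolerance = 1e-12)
})
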