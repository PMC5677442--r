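# Material spectra library, deterministic-annealing clustering, SVM pixel
# classification and binary layer extraction.

#' Material spectra library
#'
#' Named reflectance spectra over a shared wavelength axis; the classifier's
#' targets. A survey typically carries around ten materials (soils, grasses,
#' bushes, shadow), of which "Eroded Soil" and "Light Grass" drive mound
#' detection.
#'
#' @param names Character vector of unique material names.
#' @param spectra Matrix, one row per material, one column per band,
#'   finite and >= 0.
#' @param wavelengths_nm Shared band axis, strictly increasing.
#' @return A `material_library`.
#' @export
material_library <- function(names, spectra, wavelengths_nm) {
  spectra <- as.matrix(spectra)
  if (anyDuplicated(names)) abort_ms("material names must be unique", "data_error")
  if (nrow(spectra) != length(names)) {
    abort_ms("one spectrum row per material name required", "data_error")
  }
  if (ncol(spectra) != length(wavelengths_nm)) {
    abort_ms("spectrum length does not match wavelength axis", "format_error")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    abort_ms("library wavelengths must be strictly increasing", "format_error")
  }
  if (!all(is.finite(spectra)) || any(spectra < 0)) {
    abort_ms("library spectra must be finite and non-negative", "data_error")
  }
  rownames(spectra) <- names
  structure(list(names = as.character(names), spectra = spectra,
                 wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "material_library")
}

#' @export
print.material_library <- function(x, ...) {
  cat(sprintf("<material_library> %d materials x %d bands (%.0f-%.0f nm): %s\n",
              length(x$names), ncol(x$spectra), min(x$wavelengths_nm),
              max(x$wavelengths_nm), paste(x$names, collapse = ", ")))
  invisible(x)
}

#' @rdname material_library
#' @param path CSV path; column `wavelength_nm` then one column per material.
#' @export
read_material_library <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    abort_ms("material library CSV must start with a wavelength_nm column", "format_error")
  }
  material_library(names(df)[-1], t(as.matrix(df[, -1, drop = FALSE])), df$wavelength_nm)
}

#' @rdname material_library
#' @param library A `material_library`.
#' @export
write_material_library <- function(library, path) {
  df <- data.frame(wavelength_nm = library$wavelengths_nm, check.names = FALSE)
  for (i in seq_along(library$names)) df[[library$names[i]]] <- library$spectra[i, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname material_library
#' @param new_names Replacement names, one per material, in order.
#' @export
rename_materials <- function(library, new_names) {
  material_library(new_names, library$spectra, library$wavelengths_nm)
}

#' Deterministic-annealing clustering parameters
#'
#' Defaults are the operating point used to build the field material library:
#' at most 10 clusters, temperature annealed from 0.02 down to 0.00025 by a
#' cooling factor of 0.8, a split threshold of 0.8, and at most 5 materials
#' associated per pixel during the soft-assignment phase.
#'
#' @param max_clusters Cap on the number of materials.
#' @param t_max,t_min Initial and final annealing temperature (squared
#'   reflectance units).
#' @param cooling Multiplicative temperature decay, in (0, 1).
#' @param split_threshold A cluster splits when the temperature falls below
#'   `split_threshold` times its critical temperature (twice the largest
#'   eigenvalue of its covariance).
#' @param max_materials_per_pixel Cap on non-zero per-pixel cluster
#'   associations while annealing.
#' @param seed Integer seed for subsampling and split perturbations.
#' @return A `da_params` list.
#' @export
da_params <- function(max_clusters = 10L, t_max = 0.02, t_min = 0.00025,
                      cooling = 0.8, split_threshold = 0.8,
                      max_materials_per_pixel = 5L, seed = 1L) {
  stopifnot(is_count(max_clusters), max_clusters >= 1,
            t_max > 0, t_min > 0, t_min < t_max,
            cooling > 0, cooling < 1, split_threshold > 0,
            is_count(max_materials_per_pixel), max_materials_per_pixel >= 1)
  structure(list(max_clusters = as.integer(max_clusters), t_max = t_max,
                 t_min = t_min, cooling = cooling,
                 split_threshold = split_threshold,
                 max_materials_per_pixel = as.integer(max_materials_per_pixel),
                 seed = as.integer(seed)),
            class = "da_params")
}

# Soft-assignment EM pass at fixed temperature.
da_em <- function(X, centers, priors, temp, max_assoc, iters = 25, tol = 1e-8) {
  n <- nrow(X)
  for (it in seq_len(iters)) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), `+`) - 2 * X %*% t(centers)
    d2 <- pmax(d2, 0)
    logp <- sweep(-d2 / temp, 2, log(priors), `+`)
    logp <- logp - apply(logp, 1, max)
    p <- exp(logp)
    if (ncol(p) > max_assoc) {
      # keep only each pixel's top associations (cap on materials per pixel)
      thr <- apply(p, 1, function(r) sort(r, decreasing = TRUE)[max_assoc])
      p[p < thr] <- 0
    }
    p <- p / rowSums(p)
    w <- colSums(p)
    new_centers <- crossprod(p, X) / pmax(w, 1e-12)
    empty <- w < 1e-9
    if (any(empty)) new_centers[empty, ] <- centers[empty, , drop = FALSE]
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    priors <- pmax(w / n, 1e-12); priors <- priors / sum(priors)
    if (shift < tol) break
  }
  list(centers = centers, priors = priors, posterior = p)
}

# Largest covariance eigenvalue and eigenvector of each cluster under the
# soft assignment; drives the phase-transition split test.
cluster_principal <- function(X, post, k) {
  w <- post[, k]
  sw <- sum(w)
  if (sw < 1e-9) return(list(lambda = 0, vec = rep(0, ncol(X))))
  mu <- colSums(X * w) / sw
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc * sqrt(w / sw), Xc * sqrt(w / sw))
  e <- eigen(cv, symmetric = TRUE)
  list(lambda = e$values[1], vec = e$vectors[, 1])
}

#' Cluster a reflectance cube into a material library
#'
#' Deterministic-annealing (DA) clustering of pixel spectra: a single
#' centroid at high temperature, annealed downwards by the cooling factor;
#' a cluster is duplicated (with a small seeded perturbation along its
#' principal axis) whenever the temperature falls below `split_threshold`
#' times its critical temperature `2 * lambda_max`, until `max_clusters` is
#' reached or the schedule ends. Deterministic under a fixed seed.
#'
#' @param cube A reflectance [hypercube], typically a demonstrative scene
#'   containing all the materials of interest.
#' @param params A [da_params()].
#' @param max_pixels Spectra are subsampled (seeded) to at most this many
#'   pixels before clustering.
#' @return A [material_library] with materials named `"Material 1"`, ... in
#'   decreasing order of pixel support; rename with [rename_materials()].
#' @export
cluster_materials <- function(cube, params = da_params(), max_pixels = 4000L) {
  stopifnot(inherits(cube, "hypercube"), inherits(params, "da_params"))
  if (cube$quantity != "reflectance") {
    abort_ms("cluster_materials expects a reflectance cube", "data_error")
  }
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1] * d[2], d[3])
  with_seed(params$seed, {
    if (nrow(X) > max_pixels) X <- X[sample.int(nrow(X), max_pixels), , drop = FALSE]
    centers <- matrix(colMeans(X), 1)
    priors <- 1
    temp <- params$t_max
    repeat {
      fit <- da_em(X, centers, priors, temp, params$max_materials_per_pixel)
      centers <- fit$centers; priors <- fit$priors
      # merge numerically coincident centroids (un-split duplicates)
      if (nrow(centers) > 1) {
        keep <- rep(TRUE, nrow(centers))
        for (i in seq_len(nrow(centers) - 1)) {
          if (!keep[i]) next
          for (j in (i + 1):nrow(centers)) {
            if (keep[j] && max(abs(centers[i, ] - centers[j, ])) < 1e-6) {
              priors[i] <- priors[i] + priors[j]; keep[j] <- FALSE
            }
          }
        }
        if (!all(keep)) {
          centers <- centers[keep, , drop = FALSE]; priors <- priors[keep]
          fit <- da_em(X, centers, priors, temp, params$max_materials_per_pixel)
          centers <- fit$centers; priors <- fit$priors
        }
      }
      if (temp <= params$t_min) break
      # split phase: duplicate clusters past their critical temperature
      if (nrow(centers) < params$max_clusters) {
        for (k in seq_len(nrow(centers))) {
          if (nrow(centers) >= params$max_clusters) break
          pc <- cluster_principal(X, fit$posterior, k)
          if (temp < params$split_threshold * 2 * pc$lambda) {
            eps <- sqrt(pmax(pc$lambda, 1e-12)) * 0.01
            centers <- rbind(centers, centers[k, ] + stats::rnorm(1) * eps * pc$vec)
            priors <- c(priors, priors[k] / 2)
            priors[k] <- priors[k] / 2
          }
        }
        priors <- priors / sum(priors)
      }
      temp <- temp * params$cooling
    }
    o <- order(priors, decreasing = TRUE)
    centers <- pmax(centers[o, , drop = FALSE], 0)
    material_library(sprintf("Material %d", seq_len(nrow(centers))),
                     centers, cube$wavelengths_nm)
  })
}

#' Train a per-pixel material classifier
#'
#' A library carries one signature per material; a support vector machine
#' needs a training set with spread. Each signature is therefore augmented
#' with `n_per_class` multiplicative Gaussian jitters
#' (`spectrum * (1 + N(0, jitter_sd))` per band), features are standardised
#' per band, and a linear-kernel multiclass SVM (libsvm one-vs-one voting,
#' cost `cost`) is fitted on the jittered set.
#'
#' @param library A [material_library].
#' @param jitter_sd Relative jitter standard deviation (default 0.02).
#' @param n_per_class Jittered copies per material (default 200).
#' @param seed Integer seed for the jitter draws.
#' @param cost SVM regularisation constant.
#' @return A `material_classifier` carrying the fitted SVM, the per-band
#'   standardisation, the material names and the band axis.
#' @export
train_classifier <- function(library, jitter_sd = 0.02, n_per_class = 200L,
                             seed = 1L, cost = 1) {
  stopifnot(inherits(library, "material_library"))
  k <- length(library$names)
  nb <- ncol(library$spectra)
  with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(k), function(i) {
      base <- matrix(library$spectra[i, ], n_per_class, nb, byrow = TRUE)
      base * (1 + matrix(stats::rnorm(n_per_class * nb, sd = jitter_sd),
                         n_per_class, nb))
    }))
    y <- factor(rep(library$names, each = n_per_class), levels = library$names)
    center <- colMeans(X)
    scale <- pmax(apply(X, 2, stats::sd), 1e-8)
    Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
    fit <- if (k > 1) {
      e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE)
    } else NULL  # single material: everything gets that label
    structure(list(fit = fit, center = center, scale = scale,
                   names = library$names,
                   wavelengths_nm = library$wavelengths_nm,
                   jitter_sd = jitter_sd, n_per_class = as.integer(n_per_class),
                   seed = as.integer(seed), cost = cost),
              class = "material_classifier")
  })
}

#' @export
print.material_classifier <- function(x, ...) {
  cat(sprintf("<material_classifier> linear SVM, %d classes x %d bands\n",
              length(x$names), length(x$center)))
  invisible(x)
}

# Predict material indices for a pixel-spectra matrix.
predict_materials <- function(classifier, X) {
  if (is.null(classifier$fit)) return(rep(1L, nrow(X)))
  Xs <- sweep(sweep(X, 2, classifier$center), 2, classifier$scale, `/`)
  as.integer(stats::predict(classifier$fit, Xs))
}

#' Classify every pixel of a reflectance cube
#'
#' @param cube A reflectance [hypercube] whose band axis matches the
#'   classifier's.
#' @param classifier A `material_classifier` from [train_classifier()].
#' @return A `label_map`: integer matrix of 1-based material indices with the
#'   material names attached as attribute `"materials"`.
#' @export
classify_cube <- function(cube, classifier) {
  stopifnot(inherits(cube, "hypercube"), inherits(classifier, "material_classifier"))
  d <- dim(cube$data)
  if (d[3] != length(classifier$wavelengths_nm) ||
      any(abs(cube$wavelengths_nm - classifier$wavelengths_nm) > 1e-6)) {
    abort_ms("cube band axis does not match the classifier's", "alignment_error")
  }
  X <- matrix(cube$data, d[1] * d[2], d[3])
  lab <- matrix(predict_materials(classifier, X), d[1], d[2])
  structure(lab, materials = classifier$names, class = c("label_map", class(lab)))
}

#' Extract binary material layers from a label map
#'
#' @param labels A `label_map` from [classify_cube()].
#' @param library A [material_library] (or anything carrying the same names).
#' @param names Material names to extract, e.g.
#'   `c("Eroded Soil", "Light Grass")`.
#' @return A named list of `binary_layer` objects (0/1 matrices with a
#'   `material_name` attribute). Masks of distinct names are disjoint; a
#'   material absent from the map yields an all-zero mask.
#' @export
extract_layers <- function(labels, library, names) {
  all_names <- if (inherits(library, "material_library")) library$names
               else attr(labels, "materials")
  idx <- match(names, all_names)
  if (anyNA(idx)) {
    abort_ms(sprintf("unknown material(s): %s",
                     paste(names[is.na(idx)], collapse = ", ")), "lookup_error")
  }
  out <- lapply(seq_along(names), function(i) {
    m <- (unclass(labels) == idx[i]) + 0
    structure(m, material_name = names[i], class = c("binary_layer", class(m)))
  })
  stats::setNames(out, names)
}
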