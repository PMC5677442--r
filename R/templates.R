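# Binary shape templates for the Hu-moment matching stage.

# Rasterise one shape as a binary matrix. Oval and diamond cores are the two
# silhouettes termite mounds present from above.
raster_shape <- function(shape, size_px, aspect, rotation_deg = 0) {
  ctr <- (size_px + 1) / 2
  a <- size_px * 0.42            # semi-axis along the major direction
  b <- a / aspect
  th <- rotation_deg * pi / 180
  g <- expand.grid(r = seq_len(size_px), c = seq_len(size_px))
  dx <- g$c - ctr; dy <- g$r - ctr
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- switch(shape,
    oval = (u / a)^2 + (v / b)^2 <= 1,
    diamond = abs(u) / a + abs(v) / b <= 1,
    abort_ms(sprintf("unknown template shape '%s'", shape), "data_error")
  )
  matrix(as.numeric(inside), size_px, size_px)
}

#' Render the mound shape template set
#'
#' Builds the library of binary key-shape templates the soil-contour filter
#' matches against: ovals and diamonds at a few aspect ratios, one foreground
#' component per image, each carrying its signed-log Hu vector.
#'
#' @param shapes List of `list(name =, shape = "oval"|"diamond", aspect =)`
#'   entries; the default set covers round-to-elongated ovals and diamonds.
#' @param size_px Side of the square template images (>= 32).
#' @return A `shape_template_set`: list of `list(name, image, log_hu)`.
#' @export
render_templates <- function(shapes = NULL, size_px = 64L) {
  stopifnot(size_px >= 32L)
  if (is.null(shapes)) {
    shapes <- list(
      list(name = "oval_round",    shape = "oval",    aspect = 1.0),
      list(name = "oval_mid",      shape = "oval",    aspect = 1.25),
      list(name = "oval_long",     shape = "oval",    aspect = 1.6),
      list(name = "diamond_round", shape = "diamond", aspect = 1.0),
      list(name = "diamond_mid",   shape = "diamond", aspect = 1.25),
      list(name = "diamond_long",  shape = "diamond", aspect = 1.6)
    )
  }
  templates <- lapply(shapes, function(s) {
    img <- raster_shape(s$shape, size_px, s$aspect)
    list(name = s$name, image = img, log_hu = log_hu(img))
  })
  structure(list(templates = templates), class = "shape_template_set")
}

#' @export
print.shape_template_set <- function(x, ...) {
  cat(sprintf("<shape_template_set> %d templates: %s\n", length(x$templates),
              paste(vapply(x$templates, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Read and write shape templates as binary PNGs
#'
#' @param dir Directory of single-channel PNGs, one shape each; file names
#'   (minus extension) become template names.
#' @return `read_templates`: a `shape_template_set`.
#' @export
read_templates <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) abort_ms(sprintf("no PNG templates found in %s", dir), "lookup_error")
  templates <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img <- (img > 0.5) + 0
    list(name = sub("\\.png$", "", basename(f)), image = img, log_hu = log_hu(img))
  })
  structure(list(templates = templates), class = "shape_template_set")
}

#' @rdname read_templates
#' @param set A `shape_template_set`.
#' @export
write_templates <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in set$templates) {
    png::writePNG(t$image, file.path(dir, paste0(t$name, ".png")))
  }
  invisible(dir)
}
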