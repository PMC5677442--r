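# Fixed 3x3 morphological and rank filters used throughout the pipeline.
#
# All filters use replicate (nearest-edge) padding. With that padding,
# grayscale closing is extensive (output >= input everywhere, including the
# image border) and idempotent, which the band pre-cleaning stage relies on.

# Shift a matrix by (dr, dc), replicating edge rows/columns.
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Offsets of a 3x3 structuring element. "box" is the full rectangle; at this
# size an "ellipse" element degenerates to the 4-connected cross.
se_offsets <- function(shape = c("box", "cross")) {
  shape <- match.arg(shape)
  if (shape == "box") {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(0L, -1L, 0L, 1L, 0L), dc = c(0L, 0L, -1L, 0L, 1L))
  }
}

reduce_over_se <- function(m, shape, f) {
  off <- se_offsets(shape)
  out <- shift_replicate(m, off$dr[1], off$dc[1])
  for (k in seq_len(nrow(off))[-1]) {
    out <- f(out, shift_replicate(m, off$dr[k], off$dc[k]))
  }
  out
}

#' @rdname morphology3
#' @export
dilate3 <- function(m, shape = c("box", "cross")) {
  reduce_over_se(m, match.arg(shape), pmax)
}

#' @rdname morphology3
#' @export
erode3 <- function(m, shape = c("box", "cross")) {
  reduce_over_se(m, match.arg(shape), pmin)
}

#' 3x3 morphological operators
#'
#' Grayscale dilation, erosion, closing and a binary median (majority) filter
#' with a fixed 3x3 structuring element and replicate border padding. These
#' are the elementary operations behind band pre-cleaning and binary-layer
#' conditioning. `shape = "box"` is the full 3x3 rectangle; `shape = "cross"`
#' is the 4-connected cross (the elliptical element at this kernel size).
#'
#' @param m Numeric matrix (grayscale) or 0/1 matrix (binary).
#' @param shape Structuring element, `"box"` or `"cross"`.
#' @return A matrix of the same dimensions.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 1
#' sum(dilate3(m, "cross"))  # 5: the centre plus its 4-neighbours
#' @name morphology3
#' @export
close3 <- function(m, shape = c("box", "cross")) {
  shape <- match.arg(shape)
  erode3(dilate3(m, shape), shape)
}

#' @rdname morphology3
#' @export
median3 <- function(m) {
  stopifnot(is.matrix(m))
  if (!all(m %in% c(0, 1))) {
    abort_ms("median3 expects a binary (0/1) matrix", "data_error")
  }
  s <- reduce_over_se(m, "box", `+`)
  (s >= 5) + 0
}
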