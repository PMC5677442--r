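# Contour extraction and shape descriptors.
#
# Outer borders of 8-connected foreground components are traced in the
# border-following style of Suzuki & Abe, giving an ordered polygon through
# pixel centres. All geometry (area, centroid, higher moments) is computed
# from that polygon by Green's-theorem line integrals; the seven Hu moment
# invariants derived from them are compared in signed-log space.

# 8-connected component labelling by vectorised frontier expansion.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask > 0)
  if (length(fg) == 0) return(lab)
  off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  cur <- 0L
  todo <- rep(FALSE, nr * nc); todo[fg] <- TRUE
  for (s in fg) {
    if (!todo[s]) next
    cur <- cur + 1L
    frontier <- s
    todo[s] <- FALSE
    lab[s] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb <- integer(0)
      for (k in seq_len(nrow(off))) {
        rr <- r + off[k, 1]; cc <- c + off[k, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nb <- c(nb, (cc[ok] - 1L) * nr + rr[ok])
      }
      nb <- unique(nb[todo[nb]])
      if (length(nb)) {
        lab[nb] <- cur
        todo[nb] <- FALSE
      }
      frontier <- nb
    }
  }
  lab
}

# Moore-neighbour border following with Jacob's stopping criterion.
# Returns the ordered (row, col) boundary of one component, 1-based.
trace_border <- function(lab, id) {
  nr <- nrow(lab); nc <- ncol(lab)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && lab[r, c] == id
  idx <- which(lab == id)
  # start at the topmost-leftmost pixel in raster order
  r0 <- (idx - 1L) %% nr + 1L; c0 <- (idx - 1L) %/% nr + 1L
  o <- order(r0, c0)
  sr <- r0[o[1]]; sc <- c0[o[1]]
  # clockwise Moore neighbourhood, starting west
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  pts_r <- sr; pts_c <- sc
  # backtrack starts west of the start pixel (the scan arrived from the west)
  b <- 1L
  cr <- sr; cc <- sc
  first_next <- NULL
  guard <- 0L; guard_max <- 8L * length(idx) + 64L
  repeat {
    guard <- guard + 1L
    if (guard > guard_max) break  # safety net; cannot trigger on valid masks
    found <- FALSE
    k <- b
    for (step in 1:8) {
      k <- k %% 8L + 1L
      rr <- cr + dr[k]; ccol <- cc + dc[k]
      if (inside(rr, ccol)) { found <- TRUE; break }
    }
    if (!found) break  # isolated single pixel
    prev_k <- if (k == 1L) 8L else k - 1L
    if (is.null(first_next)) first_next <- c(rr, ccol)
    else if (cr == sr && cc == sc && rr == first_next[1] && ccol == first_next[2]) break
    pts_r <- c(pts_r, rr); pts_c <- c(pts_c, ccol)
    # new backtrack: the neighbour checked just before the hit, seen from the
    # new current pixel
    br <- cr + dr[prev_k]; bc <- cc + dc[prev_k]
    cr <- rr; cc <- ccol
    b <- which(dr == (br - cr) & dc == (bc - cc))
    if (length(b) != 1L) b <- 1L
  }
  n <- length(pts_r)
  if (n > 1L && pts_r[n] == sr && pts_c[n] == sc) { pts_r <- pts_r[-n]; pts_c <- pts_c[-n] }
  cbind(row = pts_r, col = pts_c)
}

# Raw geometric moments m_pq (p + q <= 3) of the closed polygon through the
# 0-based pixel centres, via Green's-theorem line integrals. Orientation is
# normalised so that m00 >= 0.
polygon_moments <- function(pts0) {
  x <- pts0[, 2]; y <- pts0[, 1]   # x = col, y = row
  n <- length(x)
  xp <- c(x[n], x[-n]); yp <- c(y[n], y[-n])
  dxy <- xp * y - x * yp
  m <- c(
    m00 = sum(dxy) / 2,
    m10 = sum(dxy * (xp + x)) / 6,
    m01 = sum(dxy * (yp + y)) / 6,
    m20 = sum(dxy * (xp^2 + xp * x + x^2)) / 12,
    m11 = sum(dxy * (xp * (2 * yp + y) + x * (yp + 2 * y))) / 24,
    m02 = sum(dxy * (yp^2 + yp * y + y^2)) / 12,
    m30 = sum(dxy * (xp^3 + xp^2 * x + xp * x^2 + x^3)) / 20,
    m21 = sum(dxy * (xp^2 * (3 * yp + y) + 2 * xp * x * (yp + y) + x^2 * (yp + 3 * y))) / 60,
    m12 = sum(dxy * (yp^2 * (3 * xp + x) + 2 * yp * y * (xp + x) + y^2 * (xp + 3 * x))) / 60,
    m03 = sum(dxy * (yp^3 + yp^2 * y + yp * y^2 + y^3)) / 20
  )
  if (m[["m00"]] < 0) m <- -m
  m
}

central_moments <- function(m) {
  xb <- m[["m10"]] / m[["m00"]]; yb <- m[["m01"]] / m[["m00"]]
  c(
    mu20 = m[["m20"]] - xb * m[["m10"]],
    mu11 = m[["m11"]] - xb * m[["m01"]],
    mu02 = m[["m02"]] - yb * m[["m01"]],
    mu30 = m[["m30"]] - 3 * xb * m[["m20"]] + 2 * xb^2 * m[["m10"]],
    mu21 = m[["m21"]] - 2 * xb * m[["m11"]] - yb * m[["m20"]] + 2 * xb^2 * m[["m01"]],
    mu12 = m[["m12"]] - 2 * yb * m[["m11"]] - xb * m[["m02"]] + 2 * yb^2 * m[["m10"]],
    mu03 = m[["m03"]] - 3 * yb * m[["m02"]] + 2 * yb^2 * m[["m01"]]
  )
}

hu_from_moments <- function(m) {
  mu <- central_moments(m)
  s2 <- m[["m00"]]^2; s25 <- m[["m00"]]^2.5
  n20 <- mu[["mu20"]] / s2; n11 <- mu[["mu11"]] / s2; n02 <- mu[["mu02"]] / s2
  n30 <- mu[["mu30"]] / s25; n21 <- mu[["mu21"]] / s25
  n12 <- mu[["mu12"]] / s25; n03 <- mu[["mu03"]] / s25
  t0 <- n30 + n12; t1 <- n21 + n03
  q0 <- n30 - 3 * n12; q1 <- 3 * n21 - n03
  c(
    h1 = n20 + n02,
    h2 = (n20 - n02)^2 + 4 * n11^2,
    h3 = q0^2 + q1^2,
    h4 = t0^2 + t1^2,
    h5 = q0 * t0 * (t0^2 - 3 * t1^2) + q1 * t1 * (3 * t0^2 - t1^2),
    h6 = (n20 - n02) * (t0^2 - t1^2) + 4 * n11 * t0 * t1,
    h7 = q1 * t0 * (t0^2 - 3 * t1^2) - q0 * t1 * (3 * t0^2 - t1^2)
  )
}

# Minimum enclosing circle (exact, Welzl-style incremental on the convex hull).
min_enclosing_circle <- function(pts0) {
  x <- pts0[, 2]; y <- pts0[, 1]
  if (length(x) == 1L) return(list(center = c(x, y), radius = 0))
  hull <- unique(cbind(x, y))
  if (nrow(hull) > 3L) hull <- hull[rev(grDevices::chull(hull[, 1], hull[, 2])), , drop = FALSE]
  px <- hull[, 1]; py <- hull[, 2]
  n <- length(px)
  # deterministic pseudo-shuffle to get expected-linear behaviour
  o <- order((seq_len(n) * 7919L) %% n)
  px <- px[o]; py <- py[o]
  circ2 <- function(ax, ay, bx, by) {
    list(cx = (ax + bx) / 2, cy = (ay + by) / 2,
         r2 = ((ax - bx)^2 + (ay - by)^2) / 4)
  }
  circ3 <- function(ax, ay, bx, by, cx, cy) {
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear: diameter of the farthest pair
      cands <- list(circ2(ax, ay, bx, by), circ2(ax, ay, cx, cy), circ2(bx, by, cx, cy))
      return(cands[[which.max(vapply(cands, `[[`, 0, "r2"))]])
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) + (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) + (cx^2 + cy^2) * (bx - ax)) / d
    list(cx = ux, cy = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
  }
  inc <- function(cc, qx, qy) (qx - cc$cx)^2 + (qy - cc$cy)^2 <= cc$r2 * (1 + 1e-10) + 1e-12
  cc <- circ2(px[1], py[1], px[min(2L, n)], py[min(2L, n)])
  if (n >= 3L) for (i in 3:n) {
    if (inc(cc, px[i], py[i])) next
    cc <- circ2(px[1], py[1], px[i], py[i])
    for (j in 2:(i - 1)) {
      if (inc(cc, px[j], py[j])) next
      cc <- circ2(px[j], py[j], px[i], py[i])
      if (j >= 2L) for (k in 1:(j - 1)) {
        if (inc(cc, px[k], py[k])) next
        cc <- circ3(px[k], py[k], px[j], py[j], px[i], py[i])
      }
    }
  }
  list(center = c(cc$cx, cc$cy), radius = sqrt(cc$r2))
}

# Assemble the contour object from an ordered 1-based (row, col) point matrix.
build_contour <- function(pts) {
  pts0 <- pts - 1  # 0-based pixel-centre coordinates
  n <- nrow(pts0)
  per <- if (n < 2L) 0 else {
    d <- sqrt(diff(c(pts0[, 1], pts0[1, 1]))^2 + diff(c(pts0[, 2], pts0[1, 2]))^2)
    sum(d)
  }
  degenerate <- n < 3L
  m <- if (!degenerate) polygon_moments(pts0) else NULL
  if (!degenerate && m[["m00"]] <= 0) degenerate <- TRUE
  mec <- min_enclosing_circle(pts0)
  structure(list(
    points = pts0,
    perimeter_px = per,
    area_px2 = if (degenerate) 0 else m[["m00"]],
    centroid = if (degenerate) c(x = mean(pts0[, 2]), y = mean(pts0[, 1]))
               else c(x = m[["m10"]] / m[["m00"]], y = m[["m01"]] / m[["m00"]]),
    enclosing_radius_px = mec$radius,
    enclosing_center = c(x = mec$center[1], y = mec$center[2]),
    moments = m,
    degenerate = degenerate
  ), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d points, area %.1f px^2, perimeter %.1f px, centroid (%.1f, %.1f)%s\n",
              nrow(x$points), x$area_px2, x$perimeter_px,
              x$centroid[["x"]], x$centroid[["y"]],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Trace the contours of a binary layer
#'
#' Extracts the border polygons of every 8-connected foreground component by
#' Moore border following (the Suzuki-Abe border-following scheme): the
#' outer border of each component and, when `holes = TRUE` (the default),
#' one inner border per enclosed hole, traced along the component pixels
#' that face the hole. Hole borders matter for ring-shaped vegetation: the
#' inner rim of a grass annulus is the part that approaches the mound core.
#' Each contour carries its polygon geometry: area by Green's theorem under
#' the polygon-through-pixel-centres convention, polygonal perimeter,
#' centroid, minimum enclosing circle radius, and the raw moments that feed
#' [log_hu()].
#'
#' @param mask Binary (0/1) matrix.
#' @param holes Also trace inner (hole) borders.
#' @return List of `contour` objects (empty for an empty mask); hole borders
#'   are flagged by the `hole` field. Components of fewer than 3 boundary
#'   points, or zero polygon area, are flagged `degenerate`; they carry no
#'   moments.
#' @export
find_contours <- function(mask, holes = TRUE) {
  stopifnot(is.matrix(mask))
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  out <- lapply(seq_len(k), function(id) {
    ct <- build_contour(trace_border(lab, id))
    ct$hole <- FALSE
    ct
  })
  if (holes) {
    # holes: background components (4-connected) not touching the image edge
    bg <- 1 - (mask > 0)
    bg_lab <- label_components_4(bg)
    if (max(bg_lab) > 0) {
      edge_ids <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                           bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
      hole_ids <- setdiff(seq_len(max(bg_lab)), c(0L, edge_ids))
      for (h in hole_ids) {
        hole_mask <- (bg_lab == h) + 0
        # component pixels 8-adjacent to the hole form its inner rim
        rim <- (mask > 0) * dilate3(hole_mask, "box")
        rim_lab <- label_components(rim)
        for (rid in seq_len(max(rim_lab))) {
          ct <- build_contour(trace_border(rim_lab, rid))
          ct$hole <- TRUE
          out[[length(out) + 1L]] <- ct
        }
      }
    }
  }
  out
}

# 4-connected labelling (background/hole analysis).
label_components_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask > 0)
  if (length(fg) == 0) return(lab)
  off <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  cur <- 0L
  todo <- rep(FALSE, nr * nc); todo[fg] <- TRUE
  for (s in fg) {
    if (!todo[s]) next
    cur <- cur + 1L
    frontier <- s; todo[s] <- FALSE; lab[s] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb <- integer(0)
      for (k in 1:4) {
        rr <- r + off[k, 1]; cc <- c + off[k, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nb <- c(nb, (cc[ok] - 1L) * nr + rr[ok])
      }
      nb <- unique(nb[todo[nb]])
      if (length(nb)) { lab[nb] <- cur; todo[nb] <- FALSE }
      frontier <- nb
    }
  }
  lab
}

#' Signed-log Hu moment vector of a shape
#'
#' Computes the seven Hu invariants `h1..h7` of a contour (or of a binary
#' template image, via its traced outer contour) and maps them to
#' `m_i = sign(h_i) * log10(|h_i|)`. Invariants with `|h_i|` at or below
#' `floor` are numerically indistinguishable from zero (they arise for
#' symmetric shapes) and are returned as `NA`; [shape_ratio()] skips them.
#'
#' @param x A `contour` from [find_contours()], or a binary matrix.
#' @param floor Magnitude below which an invariant is treated as zero.
#' @return Numeric 7-vector (possibly with `NA` entries), with the raw
#'   invariants attached as attribute `"hu"`.
#' @export
log_hu <- function(x, floor = 1e-5) {
  if (is.matrix(x) && !inherits(x, "contour")) {
    cs <- find_contours(x)
    cs <- Filter(function(ct) !ct$degenerate, cs)
    if (length(cs) != 1L) {
      abort_ms("template image must contain exactly one non-degenerate component",
               "degenerate_error")
    }
    x <- cs[[1]]
  }
  stopifnot(inherits(x, "contour"))
  if (x$degenerate) abort_ms("cannot compute Hu invariants of a degenerate contour",
                             "degenerate_error")
  h <- hu_from_moments(x$moments)
  m <- ifelse(abs(h) > floor, sign(h) * log10(abs(h)), NA_real_)
  # |h| exactly 1 would give log 0 and an infinite reciprocal downstream
  m[!is.na(m) & abs(m) < 1e-12] <- NA_real_
  names(m) <- paste0("m", 1:7)
  attr(m, "hu") <- h
  m
}

#' Hu-moment shape match ratio
#'
#' The shape-matching score between a soil contour and a template:
#' `sum_i |1/m_i^S - 1/m_i^T|` over the seven signed-log Hu terms, skipping
#' any term flagged zero for either shape. Lower is closer; the ratio is 0
#' for identical vectors and invariant (up to rasterisation error) under
#' rotation, translation and uniform scaling of the underlying shape.
#'
#' @param a,b Signed-log Hu 7-vectors from [log_hu()].
#' @return Non-negative scalar.
#' @export
shape_ratio <- function(a, b) {
  stopifnot(length(a) == 7L, length(b) == 7L)
  use <- !is.na(a) & !is.na(b)
  if (!any(use)) abort_ms("no comparable Hu terms between the two shapes", "degenerate_error")
  sum(abs(1 / a[use] - 1 / b[use]))
}
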