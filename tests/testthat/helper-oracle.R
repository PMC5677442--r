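# Independent brute-force geometry oracle.
#
# Polygon moments are computed by fan triangulation from the origin: each
# edge (p_i, p_{i+1}) contributes the exact integral of x^p y^q over the
# signed triangle (0, p_i, p_{i+1}), evaluated in closed form through the
# affine map from the reference triangle {(0,0),(1,0),(0,1)} and
# int u^a v^b du dv = a! b! / (a + b + 2)!. This is a different derivation
# from the Green's-theorem line integrals used by the package.

oracle_triangle_moment <- function(x1, y1, x2, y2, p, q) {
  J <- x1 * y2 - x2 * y1   # signed Jacobian; triangle (0, p1, p2)
  total <- 0
  for (i in 0:p) for (j in 0:q) {
    a <- i + j                       # power of u
    b <- (p - i) + (q - j)           # power of v
    coef <- choose(p, i) * choose(q, j) *
      x1^i * x2^(p - i) * y1^j * y2^(q - j)
    total <- total + coef * factorial(a) * factorial(b) / factorial(a + b + 2)
  }
  J * total
}

oracle_polygon_moments <- function(pts0) {
  x <- pts0[, 2]; y <- pts0[, 1]
  n <- length(x)
  out <- c(m00 = 0, m10 = 0, m01 = 0, m20 = 0, m11 = 0, m02 = 0,
           m30 = 0, m21 = 0, m12 = 0, m03 = 0)
  pq <- list(m00 = c(0, 0), m10 = c(1, 0), m01 = c(0, 1), m20 = c(2, 0),
             m11 = c(1, 1), m02 = c(0, 2), m30 = c(3, 0), m21 = c(2, 1),
             m12 = c(1, 2), m03 = c(0, 3))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    for (nm in names(pq)) {
      out[nm] <- out[nm] + oracle_triangle_moment(x[k], y[k], x[k2], y[k2],
                                                  pq[[nm]][1], pq[[nm]][2])
    }
  }
  if (out[["m00"]] < 0) out <- -out
  out
}

# Raw -> central -> normalised -> Hu, written out independently.
oracle_hu <- function(m) {
  xb <- m[["m10"]] / m[["m00"]]; yb <- m[["m01"]] / m[["m00"]]
  mu <- c(
    mu20 = m[["m20"]] - xb^2 * m[["m00"]],
    mu11 = m[["m11"]] - xb * yb * m[["m00"]],
    mu02 = m[["m02"]] - yb^2 * m[["m00"]],
    mu30 = m[["m30"]] - 3 * xb * m[["m20"]] + 2 * xb^3 * m[["m00"]],
    mu21 = m[["m21"]] - 2 * xb * m[["m11"]] - yb * m[["m20"]] + 2 * xb^2 * yb * m[["m00"]],
    mu12 = m[["m12"]] - 2 * yb * m[["m11"]] - xb * m[["m02"]] + 2 * yb^2 * xb * m[["m00"]],
    mu03 = m[["m03"]] - 3 * yb * m[["m02"]] + 2 * yb^3 * m[["m00"]]
  )
  n2 <- function(v) v / m[["m00"]]^2
  n3 <- function(v) v / m[["m00"]]^2.5
  n20 <- n2(mu[["mu20"]]); n11 <- n2(mu[["mu11"]]); n02 <- n2(mu[["mu02"]])
  n30 <- n3(mu[["mu30"]]); n21 <- n3(mu[["mu21"]])
  n12 <- n3(mu[["mu12"]]); n03 <- n3(mu[["mu03"]])
  c(
    h1 = n20 + n02,
    h2 = (n20 - n02)^2 + 4 * n11^2,
    h3 = (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    h4 = (n30 + n12)^2 + (n21 + n03)^2,
    h5 = (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    h6 = (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    h7 = (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  )
}

oracle_polygon_area <- function(pts0) abs(oracle_polygon_moments(pts0)[["m00"]])

oracle_polygon_centroid <- function(pts0) {
  m <- oracle_polygon_moments(pts0)
  c(x = m[["m10"]] / m[["m00"]], y = m[["m01"]] / m[["m00"]])
}

oracle_polygon_perimeter <- function(pts0) {
  idx <- c(seq_len(nrow(pts0)), 1L)
  sum(sqrt(rowSums((pts0[idx[-1], , drop = FALSE] -
                    pts0[idx[-length(idx)], , drop = FALSE])^2)))
}

# ---- raster shape helpers ---------------------------------------------------

# Binary ellipse/diamond mask, arbitrary centre/axes/rotation.
shape_mask <- function(nr, nc, center, a, b, rotation_deg = 0, kind = "oval") {
  th <- rotation_deg * pi / 180
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  dx <- cc - center[2]; dy <- rr - center[1]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- if (kind == "oval") (u / a)^2 + (v / b)^2 <= 1
            else abs(u) / a + abs(v) / b <= 1
  inside + 0
}

disk_mask <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  shape_mask(n, n, c(r + pad + 1, r + pad + 1), r, r)
}

# Random blobby mask (union of a few overlapping disks), >= 20 px across.
random_blob <- function(seed) {
  set.seed(seed)
  n <- 96
  m <- matrix(0, n, n)
  k <- sample(3:5, 1)
  cx <- runif(k, 30, 66); cy <- runif(k, 30, 66); r <- runif(k, 9, 16)
  for (i in seq_len(k)) {
    m <- pmax(m, shape_mask(n, n, c(cy[i], cx[i]), r[i], r[i] * runif(1, 0.6, 1),
                            rotation_deg = runif(1, 0, 180)))
  }
  m
}

# Largest non-degenerate contour of a mask.
main_contour <- function(mask) {
  cs <- Filter(function(ct) !ct$degenerate, find_contours(mask, holes = FALSE))
  cs[[which.max(vapply(cs, function(ct) ct$area_px2, 0))]]
}
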