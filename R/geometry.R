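# Planar polygon primitives shared by the imaging, mechanics and rendering code.
# Polygons are n x 2 numeric matrices of (x, y) vertices in micrometres,
# implicitly closed (last vertex joins the first).

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
    stop("polygon must be a numeric matrix with >= 3 rows and 2 columns")
  if (anyNA(poly) || any(!is.finite(poly)))
    stop("polygon vertices must be finite")
  # drop a duplicated closing vertex
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1L, ], poly[n, ], tolerance = 1e-12)) && n > 3L)
    poly <- poly[-n, , drop = FALSE]
  poly
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of vertices, implicitly closed.
#' @param signed return the signed area (positive for counter-clockwise)?
#' @return Area in squared input units.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  a <- sum(x * ys - xs * y) / 2
  if (signed) a else abs(a)
}

#' Polygon perimeter (edge-length sum)
#' @inheritParams polygon_area
#' @return Perimeter in input units.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_polygon(poly)
  d <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Second-order area moments about the centroid, as the 2x2 covariance-like
# matrix [[mxx, mxy], [mxy, myy]] (Green's theorem, standard closed forms).
polygon_second_moments <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  cxy <- polygon_centroid(poly)
  ixx <- sum(cr * (x^2 + x * xs + xs^2)) / 12
  iyy <- sum(cr * (y^2 + y * ys + ys^2)) / 12
  ixy <- sum(cr * (x * ys + 2 * x * y + 2 * xs * ys + xs * y)) / 24
  s <- sign(a)
  m <- matrix(c(ixx * s - abs(a) * cxy[1L]^2,
                ixy * s - abs(a) * cxy[1L] * cxy[2L],
                ixy * s - abs(a) * cxy[1L] * cxy[2L],
                iyy * s - abs(a) * cxy[2L]^2), 2L, 2L)
  m / abs(a)  # normalized (per unit area), i.e. the vertex-density covariance
}

# O(n^2) simplicity check: no two non-adjacent edges intersect.
polygon_is_simple <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  p1 <- poly
  p2 <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE)  # parallel: treat as non-crossing
    t <- ((b1[1L] - a1[1L]) * d2[2L] - (b1[2L] - a1[2L]) * d2[1L]) / den
    u <- ((b1[1L] - a1[1L]) * d1[2L] - (b1[2L] - a1[2L]) * d1[1L]) / den
    eps <- 1e-12
    t > eps && t < 1 - eps && u > eps && u < 1 - eps
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      if (seg_int(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

polygon_convex_hull <- function(poly) {
  poly <- as_polygon(poly)
  idx <- grDevices::chull(poly[, 1L], poly[, 2L])
  poly[idx, , drop = FALSE]
}
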