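#' Decoupled planar deformation gradient
#'
#' Represents the in-plane deformation of a loaded cell as the product of an
#' isotropic compression/expansion `s * I` (which alone changes area, by
#' `s^2`) and a unit-determinant shear `S = [[1, gx], [gy, 1]] /
#' sqrt(1 - gx*gy)` (which distorts shape but preserves area exactly). This
#' multiplicative split encodes the decoupling principle that shear stress
#' drives local shape distortion while compressive stress drives the
#' cross-sectional area change.
#'
#' @param s isotropic stretch (dimensionless), > 0.
#' @param gx,gy shear factors along the two axes; requires `gx * gy < 1`.
#' @return Object of class `"deformation_gradient"` with the 2x2 matrix `F`.
#' @export
deformation_gradient <- function(s, gx = 0, gy = 0) {
  stopifnot(is.finite(s), s > 0)
  if (gx * gy >= 1)
    stop("degenerate shear: gx * gy must be < 1")
  S <- matrix(c(1, gy, gx, 1), 2L, 2L) / sqrt(1 - gx * gy)
  structure(list(s = s, gx = gx, gy = gy, F = s * S),
            class = "deformation_gradient")
}

#' @export
print.deformation_gradient <- function(x, ...) {
  cat(sprintf("Deformation gradient: s = %.6g, gx = %.6g, gy = %.6g (det F = %.6g)\n",
              x$s, x$gx, x$gy, det(x$F)))
  invisible(x)
}

#' Apply a deformation gradient to a polygon
#'
#' Maps every vertex by `F = s * S`; the polygon area scales by exactly
#' `s^2` since `det(S) = 1` by construction.
#'
#' @param poly simple polygon, n x 2 vertex matrix (um).
#' @param D a [deformation_gradient()], or the stretch `s` (with optional
#'   `gx`, `gy`).
#' @param gx,gy shear factors, used when `D` is numeric.
#' @return Transformed n x 2 vertex matrix.
#' @export
apply_deformation <- function(poly, D, gx = 0, gy = 0) {
  if (is.numeric(D)) D <- deformation_gradient(D, gx, gy)
  stopifnot(inherits(D, "deformation_gradient"))
  poly <- as_polygon(poly)
  if (!polygon_is_simple(poly)) stop("polygon must be simple (non-self-intersecting)")
  t(D$F %*% t(poly))
}

#' Recover the compression factor from an area change
#'
#' Under the compression/shear decoupling the whole area change is carried
#' by the isotropic part, so `s = sqrt(A_final / A_initial) = sqrt(zeta)`.
#' The shear content of the deformation is reported as unresolved: local
#' shape descriptors are too variable for a reliable shear estimate, so only
#' the compression factor is quantified.
#'
#' @param A_initial,A_final projected areas (um^2), > 0.
#' @return List with `s`, `zeta` and `shear = "unresolved"`.
#' @export
decompose_area_change <- function(A_initial, A_final) {
  if (any(A_initial <= 0) || any(A_final <= 0))
    stop("areas must be positive")
  zeta <- A_final / A_initial
  list(s = sqrt(zeta), zeta = zeta, shear = "unresolved")
}
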