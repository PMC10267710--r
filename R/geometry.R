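# Frame-agnostic 3D vector primitives underlying the bone-centered coordinate
# system: plane projections, signed in-plane angles, orthonormal frame
# construction and rotations about arbitrary axes. All angles are in degrees,
# all positions in millimetres. Vectors are plain numeric length-3 (x, y, z).

# Relative tolerance for degeneracy detection (near-parallel axes, vanishing
# projections); absolute post-condition tolerances are 1e-9 .. 1e-12, suited
# to double precision at mm scale.
.TOL_DEGENERATE <- 1e-6

.condition <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(class, "tibia3d_error", "error", "condition"),
    list(message = message, call = call)
  )
}

.stop_geom <- function(message) {
  stop(.condition("tibia3d_invalid_geometry", message))
}

.check_vec3 <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 3L) {
    .stop_geom(sprintf("%s must be a numeric vector of length 3", what))
  }
  if (!all(is.finite(v))) {
    .stop_geom(sprintf("%s has non-finite components", what))
  }
  as.numeric(v)
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v, what = "axis") {
  n <- .norm3(v)
  if (n <= 1e-9) {
    .stop_geom(sprintf("%s has near-zero norm (%.3g); cannot normalize", what, n))
  }
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct a plane from a point and a normal direction
#'
#' @param origin Numeric length-3 point on the plane (mm).
#' @param normal Numeric length-3 normal direction; normalized internally.
#' @return A `plane3d` object: list with unit `normal` and `origin`.
#' @examples
#' transverse <- plane3d(c(0, 0, 0), c(0, 0, 1))
#' @export
plane3d <- function(origin, normal) {
  origin <- .check_vec3(origin, "plane origin")
  normal <- .unit3(.check_vec3(normal, "plane normal"), "plane normal")
  structure(list(origin = origin, normal = normal), class = "plane3d")
}

#' Perpendicular (orthogonal) projection of a point into a plane
#'
#' Drops a perpendicular from `p` onto `plane`, the operation used to bring
#' skew anatomical axes into a shared projection plane before measuring an
#' angle between them.
#'
#' @param p Numeric length-3 point (mm).
#' @param plane A [plane3d()] object.
#' @return The foot of the perpendicular, numeric length 3.
#' @examples
#' project_point_to_plane(c(1, 2, 3), plane3d(c(0, 0, 0), c(0, 0, 1)))
#' @export
project_point_to_plane <- function(p, plane) {
  p <- .check_vec3(p, "point")
  stopifnot(inherits(plane, "plane3d"))
  d <- sum((p - plane$origin) * plane$normal)
  p - d * plane$normal
}

# Project a direction vector into the plane with the given unit normal.
.project_dir <- function(v, n) v - sum(v * n) * n

#' Signed angle between two directions measured in a plane
#'
#' Both directions are projected into the plane perpendicular to `normal`;
#' the returned angle runs from the projection of `a` to the projection of
#' `b`, positive counter-clockwise about `normal` (right-hand rule).
#'
#' @param a,b Numeric length-3 direction vectors.
#' @param normal Plane normal (need not be unit length).
#' @param names Optional character of length 2 naming `a` and `b` in error
#'   messages when a projection degenerates.
#' @return Angle in degrees, in the half-open interval (-180, 180].
#' @examples
#' signed_angle_in_plane(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))  # +90
#' @export
signed_angle_in_plane <- function(a, b, normal, names = c("a", "b")) {
  a <- .check_vec3(a, names[1L])
  b <- .check_vec3(b, names[2L])
  n <- .unit3(.check_vec3(normal, "normal"), "normal")
  ap <- .project_dir(a, n)
  bp <- .project_dir(b, n)
  for (i in 1:2) {
    v <- list(a, b)[[i]]
    vp <- list(ap, bp)[[i]]
    if (.norm3(vp) <= .TOL_DEGENERATE * .norm3(v)) {
      stop(.condition(
        "tibia3d_degenerate_projection",
        sprintf("axis '%s' is (near-)parallel to the plane normal; its in-plane projection is degenerate",
                names[i])
      ))
    }
  }
  ang <- atan2(sum(.cross3(ap, bp) * n), sum(ap * bp)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Build an orthonormal frame from a primary and a secondary direction
#'
#' `e3` is the unit primary direction; `e2` is the Gram-Schmidt
#' orthogonalized component of the secondary direction (its orientation in
#' the plane normal to `e3` is preserved); `e1` completes the frame with the
#' requested handedness.
#'
#' @param primary_dir,secondary_dir Numeric length-3 directions, not parallel.
#' @param handedness `"right"` (default) or `"left"`.
#' @return List with unit vectors `e1`, `e2`, `e3`.
#' @export
orthonormal_frame <- function(primary_dir, secondary_dir,
                              handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  e3 <- .unit3(.check_vec3(primary_dir, "primary direction"), "primary direction")
  s <- .check_vec3(secondary_dir, "secondary direction")
  s_perp <- .project_dir(s, e3)
  if (.norm3(s_perp) <= .TOL_DEGENERATE * .norm3(s)) {
    stop(.condition(
      "tibia3d_degenerate_frame",
      "primary and secondary directions are (near-)parallel; frame is degenerate"
    ))
  }
  e2 <- s_perp / .norm3(s_perp)
  e1 <- .cross3(e2, e3)
  if (handedness == "left") e1 <- -e1
  list(e1 = e1, e2 = e2, e3 = e3)
}

# 3x3 rotation matrix for a rotation of theta degrees about unit axis k
# (Rodrigues form).
.rotation_matrix <- function(k, theta_deg) {
  th <- theta_deg * pi / 180
  ct <- cos(th)
  st <- sin(th)
  K <- matrix(c(0, k[3L], -k[2L],
                -k[3L], 0, k[1L],
                k[2L], -k[1L], 0), nrow = 3L)
  diag(3L) * ct + st * K + (1 - ct) * (k %o% k)
}

#' Rotate a point about an arbitrary axis line
#'
#' Rodrigues rotation of `p` about the line through `axis_point` with
#' direction `axis_dir`, by `theta_deg` degrees (right-hand rule about
#' `axis_dir`). Distances to the axis are preserved.
#'
#' @param p Numeric length-3 point (mm).
#' @param axis_point Point on the rotation axis.
#' @param axis_dir Axis direction (non-zero).
#' @param theta_deg Rotation angle, degrees.
#' @return Rotated point, numeric length 3.
#' @export
rotate_about_axis <- function(p, axis_point, axis_dir, theta_deg) {
  p <- .check_vec3(p, "point")
  o <- .check_vec3(axis_point, "axis point")
  k <- .unit3(.check_vec3(axis_dir, "axis direction"), "axis direction")
  R <- .rotation_matrix(k, theta_deg)
  as.numeric(o + R %*% (p - o))
}
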