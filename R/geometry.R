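# Geometric primitives for cephalometric measurements.
#
# Coordinate convention used everywhere: image/clinical y-down frame, i.e.
# +x anterior (toward nasion after registration) and +y inferior.

.norm2 <- function(v) sqrt(sum(v * v))

#' Interior angle at a vertex
#'
#' Angle ABC at vertex B between rays B->A and B->C, in degrees, in \[0, 180\].
#'
#' @param a,b,c numeric length-2 points.
#' @param name measurement name used in error messages.
#' @return angle in degrees.
#' @examples
#' angle3(c(1, 0), c(0, 0), c(0, 1)) # 90
#' @export
angle3 <- function(a, b, c, name = "angle3") {
  u <- a - b
  v <- c - b
  nu <- .norm2(u)
  nv <- .norm2(v)
  if (nu < 1e-6 || nv < 1e-6) {
    stop_ceph("degenerate vertex in ", name, ": ray shorter than 1e-6 mm",
              class = "degenerate_geometry")
  }
  ca <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ca))) * 180 / pi
}

#' Angle between two directed rays
#'
#' Angle between direction P1->P2 and direction Q1->Q2, in \[0, 180\] degrees.
#' Used for axis inclinations (e.g. incisor axis against the SN line) where
#' the clinical convention distinguishes proclination (> 90 deg) from
#' retroclination (< 90 deg).
#'
#' @param p1,p2 points defining the first ray (from `p1` toward `p2`).
#' @param q1,q2 points defining the second ray.
#' @param name measurement name used in error messages.
#' @return angle in degrees.
#' @export
ray_angle <- function(p1, p2, q1, q2, name = "ray_angle") {
  u <- p2 - p1
  v <- q2 - q1
  nu <- .norm2(u)
  nv <- .norm2(v)
  if (nu < 1e-6 || nv < 1e-6) {
    stop_ceph("degenerate ray in ", name, class = "degenerate_geometry")
  }
  ca <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ca))) * 180 / pi
}

#' Acute angle between two undirected lines
#'
#' @param p1,p2 points on the first line.
#' @param q1,q2 points on the second line.
#' @param name measurement name used in error messages.
#' @return angle in degrees, in \[0, 90\].
#' @examples
#' line_line_angle(c(0, 0), c(1, 0), c(0, 0), c(1, 1)) # 45
#' @export
line_line_angle <- function(p1, p2, q1, q2, name = "line_line_angle") {
  th <- ray_angle(p1, p2, q1, q2, name = name)
  min(th, 180 - th)
}

#' Euclidean distance between two landmarks
#'
#' @param p,q numeric length-2 points.
#' @return distance in the input units (mm after calibration).
#' @export
point_point_distance <- function(p, q) {
  .norm2(p - q)
}

#' Signed perpendicular distance of a point from a line
#'
#' Distance of `p` from the line through `l1` and `l2`. The sign follows the
#' line's orientation from `l1` to `l2`: for a reference line running
#' superior-to-inferior in the y-down frame (e.g. the esthetic line from
#' pronasale down to soft pogonion), points anterior (+x side) of the line get
#' positive distances.
#'
#' @param p the query point.
#' @param l1,l2 points defining the oriented line.
#' @param name measurement name used in error messages.
#' @return signed distance in mm.
#' @export
point_line_signed_distance <- function(p, l1, l2, name = "point_line_signed_distance") {
  d <- l2 - l1
  len <- .norm2(d)
  if (len < 1e-6) {
    stop_ceph("degenerate line in ", name, class = "degenerate_geometry")
  }
  w <- p - l1
  (d[2] * w[1] - d[1] * w[2]) / len
}

#' Signed projection of a point difference onto an axis
#'
#' Signed length of (P - Q) projected onto the unit vector from `l1` to `l2`.
#' With the Frankfort horizontal as axis this yields sagittal (overjet-type)
#' offsets.
#'
#' @param p,q the two points whose difference is projected.
#' @param l1,l2 points defining the oriented axis.
#' @param name measurement name used in error messages.
#' @return signed distance in mm.
#' @export
projected_distance <- function(p, q, l1, l2, name = "projected_distance") {
  d <- l2 - l1
  len <- .norm2(d)
  if (len < 1e-6) {
    stop_ceph("degenerate axis in ", name, class = "degenerate_geometry")
  }
  sum((p - q) * d) / len
}

#' Signed projection onto the normal of an axis
#'
#' Signed length of (P - Q) projected onto the +90-degree rotation of the unit
#' axis `l1`->`l2`; in the y-down frame the normal of a left-to-right axis
#' points inferiorly, so with the Frankfort horizontal as axis a positive
#' value means P lies inferior to Q (overbite-type overlaps).
#'
#' @inheritParams projected_distance
#' @return signed distance in mm.
#' @export
normal_projected_distance <- function(p, q, l1, l2, name = "normal_projected_distance") {
  d <- l2 - l1
  len <- .norm2(d)
  if (len < 1e-6) {
    stop_ceph("degenerate axis in ", name, class = "degenerate_geometry")
  }
  n <- c(-d[2], d[1]) / len
  sum((p - q) * n)
}

# Rigid motion helpers (used by the generator and property tests).
rigid_transform <- function(coords, angle_deg = 0, dx = 0, dy = 0) {
  th <- angle_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  sweep(coords %*% t(R), 2, c(dx, dy), `+`)
}
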