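# Small 3-D geometry helpers shared across modules.
# Global frame convention: x anterior, y mediolateral (left positive),
# z vertical (up).  Angles are degrees at all interfaces, radians inside.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Rotation matrix about the x axis
#' @param a angle in radians
#' @keywords internal
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0,
           0, ca, sa,
           0, -sa, ca), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa,
           0, 1, 0,
           sa, 0, ca), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0,
           -sa, ca, 0,
           0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#' @param axis unit 3-vector
#' @param a angle in radians
#' @keywords internal
rot_axis <- function(axis, a) {
  u <- unit3(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Normalize a 3-vector to unit length
#' @param v numeric length-3
#' @keywords internal
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps * 100)
    stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Polyline length of an n x 3 matrix of points
#' @keywords internal
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}
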