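# Small 3D vector helpers used throughout. Coordinates are plain numeric
# 3-vectors or n x 3 matrices, units are Angstrom.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Bond angle at vertex `b` (degrees)
#' @noRd
bond_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  rad2deg(acos(max(-1, min(1, ct))))
}

#' Dihedral angle a-b-c-d in degrees, IUPAC sign convention, in (-180, 180]
#' @noRd
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place atom D from internal coordinates (NeRF construction).
#'
#' Given positions of three reference atoms a, b, c, places D such that
#' |c-D| = bond, angle(b,c,D) = angle and dihedral(a,b,c,D) = torsion.
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unit(c - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10) stop("degenerate reference frame: collinear atoms")
  n <- unit(n)
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix for a rotation of `theta` degrees about unit `axis`
#' @noRd
rotation_about_axis <- function(axis, theta) {
  u <- unit(axis)
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Deterministic near-uniform points on the unit sphere (golden spiral)
#' @noRd
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
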