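# Small 3D geometry kernel shared by the energy model and the move set.
# All coordinates are in Angstrom, angles in degrees unless noted.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed dihedral angle of four points
#'
#' Returns the torsion a-b-c-d in degrees in (-180, 180].
#' @param a,b,c,d numeric xyz vectors.
#' @return numeric scalar, degrees.
#' @keywords internal
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference atoms a-b-c, places d such that |c-d| = `bond`,
#' angle b-c-d = `angle` and dihedral a-b-c-d = `dihedral`.
#' @param a,b,c xyz of the three reference atoms.
#' @param bond bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return xyz of the placed atom.
#' @keywords internal
placeAtom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- deg2rad(dihedral)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

#' Rotate points about an arbitrary axis
#'
#' Rodrigues rotation of the rows of `xyz` about the axis through `origin`
#' with direction `axis` by `theta` degrees.
#' @param xyz n x 3 matrix of coordinates.
#' @param origin point on the axis.
#' @param axis direction vector (need not be unit length).
#' @param theta rotation angle in degrees.
#' @return n x 3 matrix of rotated coordinates.
#' @keywords internal
rotateAboutAxis <- function(xyz, origin, axis, theta) {
  u <- vunit(axis)
  th <- deg2rad(theta)
  ct <- cos(th)
  st <- sin(th)
  # rotation matrix from Rodrigues' formula
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  rot <- ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
  p <- sweep(xyz, 2, origin)
  sweep(p %*% t(rot), 2, origin, `+`)
}

# Virtual C-beta from backbone N, CA, C using ideal tetrahedral geometry.
virtualCB <- function(n, ca, c) {
  placeAtom(n, c, ca, bond = 1.521, angle = 110.1, dihedral = 122.6)
}

#' Truncated-shifted 6-12 repulsion (WCA form)
#'
#' Purely repulsive clash term: 4 eps ((s/d)^12 - (s/d)^6) + eps for
#' d < s * 2^(1/6), zero otherwise, capped at `clamp`.
#' @keywords internal
wcaEnergy <- function(d, sigma, eps, clamp) {
  d <- pmax(d, 1e-6)
  sr6 <- (sigma / d)^6
  e <- 4 * eps * (sr6 * sr6 - sr6) + eps
  ifelse(d >= sigma * 2^(1 / 6), 0, pmin(e, clamp))
}

#' Clamped 6-12 Lennard-Jones pair energy
#'
#' Full attractive/repulsive 6-12 term; exactly zero beyond `cutoff`,
#' repulsion capped at `clamp`. Minimum of -eps at d = sigma * 2^(1/6).
#' @keywords internal
ljEnergy <- function(d, sigma, eps, clamp, cutoff = Inf) {
  d <- pmax(d, 1e-6)
  sr6 <- (sigma / d)^6
  e <- 4 * eps * (sr6 * sr6 - sr6)
  ifelse(d > cutoff, 0, pmin(e, clamp))
}

# Both pair terms above are vectorized over d (and sigma/eps if matched).
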