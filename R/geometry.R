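# Vector geometry primitives used throughout: angles, torsions, internal-
# coordinate atom placement (NeRF), rigid-body superposition.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("GeometryError: zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex `b` (degrees)
#'
#' @param a,b,c numeric 3-vectors; the angle a-b-c is measured at `b`.
#' @return Angle in degrees in [0, 180].
#' @keywords internal
angle3 <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  d <- max(-1, min(1, sum(u * v)))
  acos(d) * 180 / pi
}

#' Signed dihedral angle (degrees)
#'
#' Praxeolitic formulation: project the outer bonds onto the plane normal to
#' the central bond and take atan2. Returns values in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return Torsion in degrees.
#' @keywords internal
dihedral4 <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  n1 <- vnorm(b1)
  if (n1 < 1e-12) stop("GeometryError: degenerate central bond")
  b1 <- b1 / n1
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  if (vnorm(v) < 1e-12 || vnorm(w) < 1e-12) {
    stop("GeometryError: collinear atoms in dihedral")
  }
  x <- sum(v * w)
  y <- sum(vcross(b1, v) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three placed atoms A-B-C, returns the position of D bonded to C with
#' bond length |CD|, angle B-C-D and torsion A-B-C-D.
#'
#' @param a,b,c positions of the three reference atoms.
#' @param bond,angle,torsion internal coordinates (Angstrom, degrees).
#' @keywords internal
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * cos(tor) * sin(pi - ang),
          bond * sin(tor) * sin(pi - ang))
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d2 + c)
}

rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis
#' @keywords internal
rot_axis <- function(axis, deg) {
  u <- unitv(axis)
  t <- deg * pi / 180
  ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) + uz * st, ux * uz * (1 - ct) - uy * st,
    ux * uy * (1 - ct) - uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) + ux * st,
    ux * uz * (1 - ct) + uy * st, uy * uz * (1 - ct) - ux * st, ct + uz^2 * (1 - ct)),
    3, 3)
}

#' Optimal proper rotation between two point sets (Kabsch)
#'
#' Returns the rotation matrix that minimizes the RMSD of `p` onto `q` after
#' both are centered. Reflections are excluded by the determinant guard, so
#' the result is always a proper rotation.
#'
#' @param p,q n x 3 coordinate matrices (row-matched).
#' @return 3 x 3 rotation matrix applied as p %*% R.
#' @keywords internal
kabsch_rotation <- function(p, q) {
  h <- t(p) %*% q
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  diag_mat <- diag(c(1, 1, d))
  s$u %*% diag_mat %*% t(s$v)
}

#' Least-squares superposition RMSD of two conformations
#'
#' Centers both point sets, solves the optimal proper rotation, and returns
#' the residual RMSD. Used for fragment comparison; reflections are never
#' allowed to absorb chirality differences.
#'
#' @param p,q n x 3 coordinate matrices with matched rows.
#' @return RMSD in the units of the input coordinates.
#' @export
superpose_rmsd <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q))) {
    stop("ContractViolation: point counts differ")
  }
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  r <- kabsch_rotation(pc, qc)
  dif <- pc %*% r - qc
  sqrt(sum(dif^2) / nrow(p))
}

#' Superpose one conformation onto another
#'
#' @param p,q n x 3 matrices; p is moved onto q.
#' @return p after optimal rotation/translation onto q.
#' @keywords internal
superpose_onto <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  pm <- colMeans(p); qm <- colMeans(q)
  pc <- sweep(p, 2, pm)
  qc <- sweep(q, 2, qm)
  r <- kabsch_rotation(pc, qc)
  sweep(pc %*% r, 2, qm, "+")
}

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' Deterministic spherical point set used by the surface-area sampler.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
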