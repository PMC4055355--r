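# ---- elementary vector helpers (3-vectors as numeric length 3) --------------

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Minimal signed circular difference between angles
#'
#' Computes `a - b` on the circle, mapped to the interval (-180, 180].
#' All chi-angle arithmetic in the package goes through this function so
#' that wraparound (e.g. 179 vs -179 being 2 degrees apart) is handled
#' consistently.
#'
#' @param a,b angles in degrees; recycled to a common length.
#' @return signed difference(s) in degrees, each in (-180, 180].
#' @examples
#' circular_diff(179, -179)  # 358 wraps to -2
#' @export
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# map any angle (deg) into (-180, 180]
wrap_angle <- function(x) {
  d <- x %% 360
  ifelse(d > 180, d - 360, d)
}

#' Signed dihedral angle of four points
#'
#' Standard torsion angle about the p2-p3 axis with the IUPAC sign
#' convention (positive clockwise when viewed from p2 towards p3); the cis
#' arrangement is 0 degrees and trans is 180 degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 Cartesian coordinates (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("dihedral undefined: coincident consecutive points")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("dihedral undefined: collinear point triple")
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2) / vnorm(b2)
  wrap_angle(rad2deg(atan2(y, x)))
}

# Place atom D given three reference atoms A-B-C, a bond length C-D, a bond
# angle B-C-D (degrees) and a torsion A-B-C-D (degrees).  This is the usual
# internal-to-Cartesian (NERF) step; its sign convention matches
# dihedral_angle() exactly, which the build/measure round-trip tests rely on.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  # local frame at c
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  nn <- vnorm(n)
  if (nn < 1e-9) stop("degenerate reference frame: collinear A, B, C")
  n <- n / nn
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# bond angle at b (degrees)
bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  rad2deg(acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired point sets and returns both the minimised RMSD and the transform.
#'
#' @param ref n x 3 matrix of reference coordinates.
#' @param mov n x 3 matrix of moving coordinates (same row order as `ref`,
#'   unless `pairing` is given).
#' @param pairing optional integer vector: row i of `ref` pairs with row
#'   `pairing[i]` of `mov`.
#' @return a list with elements `rmsd` (Angstrom), `rotation` (3 x 3 proper
#'   rotation matrix) and `translation` (length 3), such that
#'   `mov %*% t(rotation) + translation` superposes onto `ref`.
#' @export
superpose_rmsd <- function(ref, mov, pairing = NULL) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!is.null(pairing)) mov <- mov[pairing, , drop = FALSE]
  if (nrow(ref) != nrow(mov)) stop("point sets must pair one-to-one")
  if (nrow(ref) < 3L) stop("need at least 3 paired points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  x <- sweep(ref, 2L, cr); y <- sweep(mov, 2L, cm)
  if (min(svd(x)$d[2L], svd(y)$d[2L]) < 1e-8)
    stop("points are collinear: superposition is underdetermined")
  h <- t(y) %*% x
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- y %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fit - x)^2)))
  list(rmsd = rmsd,
       rotation = rot,
       translation = as.numeric(cr - rot %*% cm))
}

#' Apply a rigid transform returned by [superpose_rmsd()]
#' @param xyz n x 3 coordinate matrix.
#' @param transform list with `rotation` and `translation`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2L,
        transform$translation, `+`)
}
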