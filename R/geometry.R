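# Low-level 3D geometry helpers shared by the featurizer, the fixture
# generator and the evaluation code. All coordinates are in Angstrom.

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  a / n
}

#' Torsion angle defined by four points
#'
#' Returns the signed dihedral angle (radians, IUPAC sign convention) of the
#' four points, or `NA` when the construction is degenerate (three collinear
#' points make the angle undefined).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return angle in radians in (-pi, pi], or `NA_real_`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) return(NA_real_)
  m1 <- vcross(n1, b2 / vnorm(b2))
  -atan2(sum(m1 * n2), sum(n1 * n2))
}

# Natural-extension-reference-frame atom placement: position a new atom D
# given the three previous atoms A-B-C, the C-D bond length, the B-C-D bond
# angle (radians) and the A-B-C-D torsion (radians).
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Rotation matrix -> unit quaternion (w, x, y, z), Shepperd's method.
# Sign convention: scalar part non-negative; if the scalar part is ~0 the
# first non-zero vector component is made positive (double-cover tie-break).
rotmat_to_quat <- function(R) {
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3L, 2L] - R[2L, 3L]) / s,
           (R[1L, 3L] - R[3L, 1L]) / s,
           (R[2L, 1L] - R[1L, 2L]) / s)
  } else if (R[1L, 1L] >= R[2L, 2L] && R[1L, 1L] >= R[3L, 3L]) {
    s <- sqrt(1 + R[1L, 1L] - R[2L, 2L] - R[3L, 3L]) * 2
    q <- c((R[3L, 2L] - R[2L, 3L]) / s,
           0.25 * s,
           (R[1L, 2L] + R[2L, 1L]) / s,
           (R[1L, 3L] + R[3L, 1L]) / s)
  } else if (R[2L, 2L] >= R[3L, 3L]) {
    s <- sqrt(1 + R[2L, 2L] - R[1L, 1L] - R[3L, 3L]) * 2
    q <- c((R[1L, 3L] - R[3L, 1L]) / s,
           (R[1L, 2L] + R[2L, 1L]) / s,
           0.25 * s,
           (R[2L, 3L] + R[3L, 2L]) / s)
  } else {
    s <- sqrt(1 + R[3L, 3L] - R[1L, 1L] - R[2L, 2L]) * 2
    q <- c((R[2L, 1L] - R[1L, 2L]) / s,
           (R[1L, 3L] + R[3L, 1L]) / s,
           (R[2L, 3L] + R[3L, 2L]) / s,
           0.25 * s)
  }
  q <- q / sqrt(sum(q * q))
  if (q[1L] < -1e-12) {
    q <- -q
  } else if (abs(q[1L]) <= 1e-12) {
    nz <- which(abs(q) > 1e-12)
    if (length(nz) && q[nz[1L]] < 0) q <- -q
  }
  q
}

# Unit quaternion (w,x,y,z) -> rotation matrix.
quat_to_rotmat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

# Uniform random rotation matrix (via QR of a Gaussian matrix, det fixed +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d + (d == 0)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Apply a rigid motion (rotation R then translation t) to an n x 3 matrix.
apply_rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2L, t, "+")
}
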