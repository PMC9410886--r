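# Small rotation / rigid-body helpers used throughout the geometry engine.
# All rotations are 3x3 proper orthonormal matrices acting on column vectors.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation by `theta` radians about an arbitrary unit axis (Rodrigues).
#' @noRd
rot_axis <- function(axis, theta) {
  u <- unitize(axis)
  ct <- cos(theta); st <- sin(theta); vt <- 1 - ct
  matrix(c(
    ct + u[1]^2 * vt,          u[1] * u[2] * vt - u[3] * st, u[1] * u[3] * vt + u[2] * st,
    u[1] * u[2] * vt + u[3] * st, ct + u[2]^2 * vt,          u[2] * u[3] * vt - u[1] * st,
    u[1] * u[3] * vt - u[2] * st, u[2] * u[3] * vt + u[1] * st, ct + u[3]^2 * vt
  ), nrow = 3, byrow = TRUE)
}

#' @noRd
rot_x <- function(theta) rot_axis(c(1, 0, 0), theta)
#' @noRd
rot_y <- function(theta) rot_axis(c(0, 1, 0), theta)
#' @noRd
rot_z <- function(theta) rot_axis(c(0, 0, 1), theta)

# Axis-angle decomposition of a proper rotation; returns list(axis, angle)
# with angle in [0, pi]. Axis is arbitrary for angle ~ 0.
#' @noRd
rot_log <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  angle <- acos(ca)
  if (angle < 1e-7) return(list(axis = c(0, 0, 1), angle = angle))
  if (pi - angle < 1e-6) {
    # near 180 deg: extract axis from R + I
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    axis <- unitize(B[, i])
    return(list(axis = axis, angle = angle))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(angle))
  list(axis = axis, angle = angle)
}

# Geodesic interpolation between two rotations: R1 advanced by `frac` of the
# rotation taking R1 into R2. frac = 0.5 gives the mid-rotation used for
# base-pair and mid-step frames.
#' @noRd
rot_mid <- function(R1, R2, frac = 0.5) {
  Rel <- crossprod(R1, R2)            # R1^T R2, relative rotation
  aa <- rot_log(Rel)
  R1 %*% rot_axis(aa$axis, aa$angle * frac)
}

#' @noRd
is_rotation <- function(R, tol = 1e-6) {
  max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

# Signed angle from vector a to vector b about unit axis n (radians, (-pi, pi]).
#' @noRd
signed_angle <- function(a, b, n) {
  atan2(sum(cross3(a, b) * n), sum(a * b))
}

# Least-squares rigid superposition (Kabsch): finds R, t minimizing
# ||R %*% t(src) + t - t(dst)||. src, dst are n x 3 matrices of paired points.
# Returns list(R, t, rmsd).
#' @noRd
kabsch <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3)
  cs <- colMeans(src); cd <- colMeans(dst)
  P <- sweep(src, 2, cs); Q <- sweep(dst, 2, cd)
  H <- crossprod(P, Q)                # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cd - as.vector(R %*% cs)
  fitted <- t(R %*% t(src)) + matrix(t, nrow(src), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - dst)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

# Signed dihedral angle (degrees, (-180, 180]) for four points a-b-c-d,
# the torsion about the b-c bond.
#' @noRd
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitize(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place a fourth atom from internal coordinates: bond length to `c`, bond
# angle d-c-b (degrees) and dihedral d-c-b-a (degrees). Inverse of dihedral().
#' @noRd
place_by_internal <- function(a, b, c, length, angle, torsion) {
  th <- deg2rad(angle); ph <- deg2rad(torsion)
  bc <- unitize(c - b)
  n <- unitize(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          -length * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
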