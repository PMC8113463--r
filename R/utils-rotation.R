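# Small 3D rotation toolkit used throughout the package.  All rotation
# matrices act on column vectors (v' = R %*% v); frames are 3x3 matrices whose
# columns are the x, y, z axes expressed in lab coordinates.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `theta` degrees about the (not necessarily unit)
#' vector `axis`.
#'
#' @param axis 3-vector; direction of the rotation axis.
#' @param theta rotation angle in degrees (right-hand rule).
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about <- function(axis, theta) {
  n <- unit(axis)
  th <- theta / DEG
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis-angle decomposition of a rotation matrix
#'
#' @param R 3x3 proper rotation matrix.
#' @return list with `angle` (degrees, in \[0, 180\]) and `axis` (unit
#'   3-vector; arbitrary for the identity).
#' @export
axis_angle <- function(R) {
  tr <- sum(diag(R))
  cang <- max(-1, min(1, (tr - 1) / 2))
  ang <- acos(cang) * DEG
  if (ang < 1e-8) {
    return(list(angle = 0, axis = c(0, 0, 1)))
  }
  if (ang > 180 - 1e-6) {
    # near-pi: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    k <- which.max(ax)
    ax <- B[, k] / ax[k]
    return(list(angle = ang, axis = unit(ax)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(ax) < 1e-12) return(list(angle = 0, axis = c(0, 0, 1)))
  list(angle = ang, axis = unit(ax))
}

# Fractional power of a rotation (t = 0.5 gives the halfway rotation).
rotation_power <- function(R, t) {
  aa <- axis_angle(R)
  if (aa$angle == 0) return(diag(3))
  rotation_about(aa$axis, aa$angle * t)
}

# Signed angle (degrees) from a to b about axis n, in (-180, 180].
signed_angle <- function(a, b, n) {
  a <- unit(a); b <- unit(b); n <- unit(n)
  atan2(sum(cross3(a, b) * n), sum(a * b)) * DEG
}

# Re-orthonormalize a nearly orthonormal 3x3 matrix (closest rotation, via SVD).
orthonormalize <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

angle_between <- function(a, b) {
  acos(max(-1, min(1, sum(unit(a) * unit(b))))) * DEG
}
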