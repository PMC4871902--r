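#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (stored as a unit quaternion, so
#' repeated composition cannot drift away from the rotation group) followed by
#' a translation, `x -> R x + t`, with coordinates in Angstrom.
#'
#' @param q numeric(4) quaternion `(w, x, y, z)`; normalized on construction.
#' @param t numeric(3) translation in Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  stopifnot(length(q) == 4, length(t) == 3, all(is.finite(q)), all(is.finite(t)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion cannot represent a rotation")
  structure(list(q = q / n, t = as.numeric(t)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- 2 * acos(min(1, abs(x$q[1]))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` that leaves coordinates unchanged.
#' @export
rt_identity <- function() rigid_transform()

#' Quaternion to rotation matrix
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotation matrix to quaternion
#' @param R 3x3 proper rotation matrix.
#' @return unit quaternion `(w, x, y, z)`.
#' @export
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(max(0, R[i, i] - R[j, j] - R[k, k] + 1)) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` applies `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  Ra <- quat_to_mat(a$q)
  rigid_transform(quat_mul(a$q, b$q), as.numeric(Ra %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param a a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_invert <- function(a) {
  qi <- c(a$q[1], -a$q[2:4])
  Ri <- quat_to_mat(qi)
  rigid_transform(qi, -as.numeric(Ri %*% a$t))
}

#' Axis-angle rotation transform
#' @param axis numeric(3) rotation axis (need not be normalized).
#' @param angle rotation angle in radians.
#' @param center optional point the axis passes through (default origin).
#' @return a `rigid_transform`.
#' @export
rt_axis_angle <- function(axis, angle, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  q <- c(cos(angle / 2), sin(angle / 2) * u)
  R <- quat_to_mat(q)
  rigid_transform(q, as.numeric(center - R %*% center))
}

#' Uniform random rotation (Haar measure)
#'
#' Draws a unit quaternion from the 3-sphere by normalizing four independent
#' standard normals, which induces the uniform distribution on SO(3).
#' @return a `rigid_transform` with zero translation.
#' @export
rt_random_rotation <- function() {
  q <- stats::rnorm(4)
  rigid_transform(q)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 coordinate matrix.
#' @param rt a `rigid_transform`.
#' @return transformed n x 3 matrix.
#' @export
transform_xyz <- function(xyz, rt) {
  R <- quat_to_mat(rt$q)
  sweep(xyz %*% t(R), 2, rt$t, "+")
}
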