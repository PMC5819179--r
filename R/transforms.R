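#' Rigid transform (rotation + translation)
#'
#' Lightweight container for a pose: a 3x3 rotation matrix and a 3-vector
#' position in meters. All poses handled by the package (shoulder, elbow,
#' wrist, accelerometer) are `rigid_transform` objects.
#'
#' @param rotation 3x3 orthonormal rotation matrix, determinant +1.
#' @param position numeric 3-vector, meters.
#' @param check validate orthonormality (tolerance 1e-8)? Set `FALSE` only in
#'   tight inner loops where the rotation is a product of validated rotations.
#' @return An object of class `rigid_transform` with fields `R` and `p`.
#' @export
#' @examples
#' rigid_transform(rot_z(pi / 4), c(0.1, 0, 0.2))
rigid_transform <- function(rotation = diag(3), position = c(0, 0, 0),
                            check = TRUE) {
  rotation <- unname(as.matrix(rotation))
  position <- as.numeric(position)
  if (!all(dim(rotation) == c(3L, 3L)) || length(position) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a 3-vector position")
  if (check) assert_rotation(rotation)
  structure(list(R = rotation, p = position), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  m <- cbind(x$R, x$p)
  dimnames(m) <- list(NULL, c("", "R", "", "p [m]"))
  print(round(m, 6))
  invisible(x)
}

#' Test / assert that a matrix is a rotation
#'
#' @param R 3x3 matrix.
#' @param tol absolute tolerance on `R'R - I` and `det(R) - 1`.
#' @return `is_rotation` returns a logical; `assert_rotation` errors on
#'   failure and returns `R` invisibly.
#' @export
is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' @rdname is_rotation
#' @export
assert_rotation <- function(R, tol = 1e-8) {
  if (!is_rotation(R, tol))
    stop("matrix is not a proper rotation (orthonormal, det +1) within ", tol)
  invisible(R)
}

#' Elementary rotations about the coordinate axes
#'
#' @param angle rotation angle, radians.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' `skew(v) %*% w` equals `cross3(v, w)`.
#'
#' @param v numeric 3-vector.
#' @return 3x3 skew-symmetric matrix.
#' @export
skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3L, 3L)
}

#' Cross product of two 3-vectors
#'
#' @param a,b numeric 3-vectors.
#' @return numeric 3-vector `a x b`.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation about an arbitrary axis (Rodrigues formula)
#'
#' @param axis 3-vector, normalized internally.
#' @param angle rotation angle, radians.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_rotation <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) {
    if (abs(angle) < 1e-15) return(diag(3))
    stop("zero axis with non-zero angle")
  }
  K <- skew(axis / n)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Axis-angle vector (matrix logarithm) of a rotation
#'
#' Returns the rotation vector `theta * axis` with `theta` in `[0, pi]`.
#' Robust at both the identity and the half-turn, via the quaternion route.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric 3-vector, radians.
#' @export
rotation_log <- function(R) {
  q <- quaternion_from_rotation(R)
  nv <- sqrt(sum(q[2:4]^2))
  if (nv < 1e-15) return(c(0, 0, 0))
  theta <- 2 * atan2(nv, q[1])
  (theta / nv) * q[2:4]
}

#' Quaternion conversions
#'
#' Unit quaternions in scalar-first `(w, x, y, z)` order, as used by the
#' recording CSV format and the geometry configuration files.
#' `quaternion_from_rotation` always returns `w >= 0`.
#'
#' @param R 3x3 rotation matrix.
#' @param q numeric 4-vector `(w, x, y, z)`, normalized internally.
#' @return A 4-vector, resp. a 3x3 rotation matrix.
#' @export
quaternion_from_rotation <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' @rdname quaternion_from_rotation
#' @export
rotation_from_quaternion <- function(q) {
  q <- as.numeric(q) / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3L, 3L)
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param angle numeric vector of angles, radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(angle) {
  w <- angle %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Compose and invert rigid transforms
#'
#' @param a,b `rigid_transform` objects.
#' @return `transform_compose` returns `a * b` (apply `b` first);
#'   `transform_inverse` the inverse transform; `transform_apply` the
#'   transformed points.
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$p) + a$p, check = FALSE)
}

#' @rdname transform_compose
#' @export
transform_inverse <- function(a) {
  rigid_transform(t(a$R), as.numeric(-t(a$R) %*% a$p), check = FALSE)
}

#' @rdname transform_compose
#' @param pts 3-vector or 3-column matrix of points.
#' @export
transform_apply <- function(a, pts) {
  if (is.matrix(pts)) t(a$R %*% t(pts) + a$p) else as.numeric(a$R %*% pts) + a$p
}
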