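#' Denavit-Hartenberg table of the 7-DoF human arm
#'
#' Classical (distal) DH parameterization of the simplified upper limb:
#' a spherical shoulder (q1 abduction-adduction, q2 flexion-extension,
#' q3 internal-external rotation), elbow flexion-extension (q4), forearm
#' pronation-supination (q5), and a 2-DoF wrist (q6 ulnar-radial deviation,
#' q7 flexion-extension). The upper arm length `l_u` enters as the link
#' offset of row 3 and the forearm length `l_f` as the offset of row 5;
#' all `a` parameters are zero.
#'
#' @param l_u upper-arm length, meters.
#' @param l_f forearm length, meters.
#' @return A data frame with columns `joint`, `theta_offset`, `d`, `a`,
#'   `alpha`; joint angle `q_i` adds to `theta_offset`.
#' @export
#' @examples
#' arm_dh_table(0.31, 0.25)
arm_dh_table <- function(l_u, l_f) {
  data.frame(
    joint = 1:7,
    theta_offset = c(pi / 2, 3 * pi / 2, 0, pi / 2, pi / 2, pi / 2, pi / 2),
    d = c(0, 0, l_u, 0, l_f, 0, 0),
    a = numeric(7),
    alpha = c(pi / 2, pi / 2, -pi / 2, pi / 2, pi / 2, pi / 2, pi / 2)
  )
}

#' Single DH link transform
#'
#' Classical (distal) convention: rotation `theta` about z, translation `d`
#' along z, translation `a` along x, rotation `alpha` about x, with
#' `theta = theta_offset + q`.
#'
#' @param row one row of [arm_dh_table()] (or any list with fields
#'   `theta_offset`, `d`, `a`, `alpha`).
#' @param q joint angle added to `theta_offset`, radians.
#' @return A [rigid_transform()].
#' @export
dh_transform <- function(row, q = 0) {
  theta <- row$theta_offset + q
  ct <- cos(theta); st <- sin(theta)
  ca <- cos(row$alpha); sa <- sin(row$alpha)
  R <- matrix(c(ct, st, 0,
                -st * ca, ct * ca, sa,
                st * sa, -ct * sa, ca), 3L, 3L)
  rigid_transform(R, c(row$a * ct, row$a * st, row$d), check = FALSE)
}

# Internal FK core: cumulative rotations/origins, frames 0 (shoulder base)
# through `upto`. Returns plain lists for speed; Rs[[k+1]], ps[[k+1]] are
# frame k. `shoulder` optionally overrides the base position (moving trunk).
.fk_frames <- function(q, geom, upto = 7L, shoulder = NULL) {
  Rs <- vector("list", upto + 1L)
  ps <- vector("list", upto + 1L)
  R <- geom$shoulder_pose$R
  p <- if (is.null(shoulder)) geom$shoulder_pose$p else as.numeric(shoulder)
  Rs[[1L]] <- R; ps[[1L]] <- p
  off <- .dh_offsets; al <- .dh_alphas
  d <- c(0, 0, geom$l_u, 0, geom$l_f, 0, 0)
  for (i in seq_len(upto)) {
    theta <- off[i] + q[i]
    ct <- cos(theta); st <- sin(theta)
    ca <- al[i]  # alpha is +-pi/2 for every row: cos(alpha) = 0
    # link rotation for alpha = +-pi/2 (ca holds sin(alpha))
    A <- matrix(c(ct, st, 0, 0, 0, ca, st * ca, -ct * ca, 0), 3L, 3L)
    p <- p + R[, 3L] * d[i]
    R <- R %*% A
    Rs[[i + 1L]] <- R; ps[[i + 1L]] <- p
  }
  list(Rs = Rs, ps = ps)
}
.dh_offsets <- c(pi / 2, 3 * pi / 2, 0, pi / 2, pi / 2, pi / 2, pi / 2)
.dh_alphas <- c(1, 1, -1, 1, 1, 1, 1)  # sin(alpha); cos(alpha) = 0 throughout

#' Forward kinematics of the arm
#'
#' Cumulative poses of the seven DH frames in the robot frame, starting from
#' the shoulder base pose. The origin of frame 3 is the elbow, the origin of
#' frame 5 (= 6 = 7) is the wrist, and frame 7 is the hand pose the robot
#' end effector constrains.
#'
#' @param q numeric 7-vector of joint angles, radians.
#' @param geom an [arm_geometry()].
#' @param shoulder optional 3-vector overriding the base (shoulder) position,
#'   e.g. a per-sample shoulder measurement.
#' @return List of 7 [rigid_transform()]s; the base pose is attached as
#'   attribute `base`.
#' @export
forward_kinematics <- function(q, geom, shoulder = NULL) {
  stopifnot(length(q) == 7L, all(is.finite(q)))
  f <- .fk_frames(q, geom, 7L, shoulder)
  out <- lapply(2:8, function(k) rigid_transform(f$Rs[[k]], f$ps[[k]],
                                                 check = FALSE))
  attr(out, "base") <- rigid_transform(f$Rs[[1L]], f$ps[[1L]], check = FALSE)
  out
}

#' Shoulder, elbow and wrist points
#'
#' @inheritParams forward_kinematics
#' @return List with 3-vectors `S`, `E`, `W` (robot frame, meters).
#' @export
joint_points <- function(q, geom, shoulder = NULL) {
  f <- .fk_frames(q, geom, 5L, shoulder)
  list(S = f$ps[[1L]], E = f$ps[[4L]], W = f$ps[[6L]])
}

#' Orientation of the upper-arm accelerometer
#'
#' The sensor is modelled as rigidly mounted on the upper arm with its Y axis
#' pointing from the shoulder toward the elbow and its Z axis along the elbow
#' flexion axis, i.e. the DH elbow frame rotated by the fixed mounting
#' rotation `elbow_in_accel_ref`.
#'
#' @inheritParams forward_kinematics
#' @return 3x3 rotation matrix of the accelerometer in the robot frame.
#' @export
accel_orientation <- function(q, geom, shoulder = NULL) {
  f <- .fk_frames(q, geom, 3L, shoulder)
  f$Rs[[4L]] %*% t(geom$elbow_in_accel_ref)
}

#' Check joint angles against the anatomical soft range
#'
#' The nominal anatomical range of every joint is `[-pi/2, pi/2]`. During
#' closed-loop integration the limits are advisory (patients may slightly
#' exceed them), so this check warns rather than clamps.
#'
#' @param q numeric 7-vector or n x 7 matrix of joint angles, radians.
#' @param warn emit a warning when violated?
#' @return Logical: `TRUE` if all angles are inside the range (invisibly).
#' @export
check_joint_limits <- function(q, warn = TRUE) {
  q <- rbind(q)
  bad <- abs(q) > pi / 2 + 1e-12
  if (any(bad) && warn)
    warning(sum(bad), " joint value(s) outside the anatomical range [-pi/2, pi/2]")
  invisible(!any(bad))
}
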