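#' Arm geometry and sensor mounting
#'
#' Bundles the subject's segment lengths, the shoulder base pose in the
#' robot frame, and the accelerometer mounting rotations:
#'
#' * `mount_ref_rotation` (`rR_acc0`): orientation of the accelerometer in
#'   the robot frame at the reference posture. By default it is derived from
#'   `reference_q` through the forward kinematics, which guarantees the
#'   reference accelerometer reading is exactly `(0, 1, 0)` (gravity along
#'   the sensor Y axis, which points down the upper arm).
#' * `elbow_in_accel_ref` (`acc0R_e`): fixed rotation from the accelerometer
#'   frame to the DH elbow frame. The default half-turn about Z encodes a
#'   sensor with Y toward the elbow and Z along the elbow flexion axis.
#'
#' @param l_u upper-arm length, meters (acromion to proximal radius head).
#' @param l_f forearm length, meters (proximal radius head to radial styloid).
#' @param shoulder_pose [rigid_transform()] of the shoulder base frame in the
#'   robot frame.
#' @param reference_q joint configuration defining the reference posture used
#'   to anchor the accelerometer mounting (default: all zeros).
#' @param mount_ref_rotation optional explicit `rR_acc0`; when `NULL`
#'   (recommended) it is computed from `reference_q`.
#' @param elbow_in_accel_ref rotation `acc0R_e`; default `rot_z(pi)`.
#' @return Object of class `arm_geometry`.
#' @export
#' @examples
#' geom <- arm_geometry(0.31, 0.25)
#' reference_gravity(geom)
arm_geometry <- function(l_u, l_f,
                         shoulder_pose = rigid_transform(),
                         reference_q = rep(0, 7),
                         mount_ref_rotation = NULL,
                         elbow_in_accel_ref = rot_z(pi)) {
  if (!is.numeric(l_u) || !is.numeric(l_f) || l_u <= 0.1 || l_u >= 0.6 ||
      l_f <= 0.1 || l_f >= 0.6)
    stop("segment lengths must lie in the (0.1, 0.6) m sanity band")
  if (!inherits(shoulder_pose, "rigid_transform"))
    stop("shoulder_pose must be a rigid_transform")
  assert_rotation(shoulder_pose$R)
  assert_rotation(elbow_in_accel_ref)
  geom <- structure(list(
    l_u = l_u, l_f = l_f,
    shoulder_pose = shoulder_pose,
    reference_q = as.numeric(reference_q),
    elbow_in_accel_ref = elbow_in_accel_ref,
    mount_ref_rotation = diag(3)
  ), class = "arm_geometry")
  if (is.null(mount_ref_rotation)) {
    geom$mount_ref_rotation <- accel_orientation(geom$reference_q, geom)
  } else {
    assert_rotation(mount_ref_rotation)
    geom$mount_ref_rotation <- mount_ref_rotation
  }
  geom
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("<arm_geometry> l_u =", x$l_u, "m, l_f =", x$l_f, "m\n")
  cat("shoulder position:", paste(round(x$shoulder_pose$p, 4), collapse = ", "),
      "m\n")
  invisible(x)
}

#' Gravity direction in the robot frame
#'
#' The unit gravity direction implied by the mounting: the accelerometer
#' reads `(0, 1, 0)` at the reference posture, so gravity in the robot frame
#' is the mounting rotation applied to that reading. Used as the default
#' reference axis of the swivel plane.
#'
#' @param geom an [arm_geometry()].
#' @return Unit 3-vector.
#' @export
reference_gravity <- function(geom) {
  as.numeric(geom$mount_ref_rotation %*% c(0, 1, 0))
}

#' Default reference axis of the swivel plane
#'
#' The swivel angle needs a fixed reference axis; the convention is free
#' (targets and Jacobian use the same one) but the axis should stay well
#' away from the shoulder-wrist directions the workspace visits, where the
#' reference plane degenerates. Because the reference posture aligns the
#' upper arm with gravity, a gravity-aligned axis is the worst possible
#' choice here; the default is instead a fixed horizontal axis: the robot X
#' axis projected orthogonal to gravity (robot Z if X is near-parallel to
#' gravity). Override via `ik_config(swivel_ref_axis = )`.
#'
#' @param geom an [arm_geometry()].
#' @return Unit 3-vector in the robot frame.
#' @export
swivel_reference_axis <- function(geom) {
  g <- reference_gravity(geom)
  for (e in list(c(1, 0, 0), c(0, 0, 1))) {
    r <- e - sum(e * g) * g
    nr <- sqrt(sum(r^2))
    if (nr > 0.1) return(r / nr)
  }
  stop("cannot construct a horizontal reference axis")  # unreachable
}

#' Read / write an arm geometry configuration (JSON)
#'
#' Keys: `l_u`, `l_f` (meters), `shoulder_position` (3 floats, m),
#' `shoulder_orientation`, `mount_ref_rotation`, `elbow_in_accel_ref`
#' (unit quaternions, `(w, x, y, z)` order). Missing optional rotations fall
#' back to the [arm_geometry()] defaults; `l_u`, `l_f` and
#' `shoulder_position` are required.
#'
#' @param path file path.
#' @return `read_geometry_config` returns an [arm_geometry()];
#'   `write_geometry_config` returns `path` invisibly.
#' @export
read_geometry_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("l_u", "l_f", "shoulder_position"))
    if (is.null(cfg[[key]]))
      stop("geometry config is missing required key '", key, "'")
  rot <- function(key, default) {
    if (is.null(cfg[[key]])) default else rotation_from_quaternion(cfg[[key]])
  }
  arm_geometry(
    l_u = cfg$l_u, l_f = cfg$l_f,
    shoulder_pose = rigid_transform(rot("shoulder_orientation", diag(3)),
                                    cfg$shoulder_position),
    reference_q = if (is.null(cfg$reference_q)) rep(0, 7) else cfg$reference_q,
    mount_ref_rotation = if (is.null(cfg$mount_ref_rotation)) NULL else
      rotation_from_quaternion(cfg$mount_ref_rotation),
    elbow_in_accel_ref = rot("elbow_in_accel_ref", rot_z(pi))
  )
}

#' @rdname read_geometry_config
#' @param geom an [arm_geometry()].
#' @export
write_geometry_config <- function(geom, path) {
  cfg <- list(
    l_u = geom$l_u, l_f = geom$l_f,
    shoulder_position = geom$shoulder_pose$p,
    shoulder_orientation = quaternion_from_rotation(geom$shoulder_pose$R),
    reference_q = geom$reference_q,
    mount_ref_rotation = quaternion_from_rotation(geom$mount_ref_rotation),
    elbow_in_accel_ref = quaternion_from_rotation(geom$elbow_in_accel_ref)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
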