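#' Closed-form shoulder joint candidates
#'
#' Extracts the two `(q1, q2, q3)` branches from the rotation of the first
#' three DH frames (shoulder base to elbow frame). With the rotation written
#' with rows `n`, `o`, `a`, branch (i) is
#' `q1 = atan2(-n_y, o_y)`, `q2 = atan2(a_y, sqrt(n_y^2 + o_y^2))`,
#' `q3 = atan2(a_z, -a_x)`; branch (ii) negates the square root and shifts
#' `q1`, `q3` by a half-turn (`q1 = atan2(n_y, -o_y)`,
#' `q3 = atan2(-a_z, a_x)`). Both branches reproduce the source rotation
#' through the forward kinematics away from the gimbal condition
#' `|q2| = pi/2`, where `q1` is underdetermined and set to 0 by convention.
#'
#' @param T rotation of the elbow frame relative to the shoulder base frame:
#'   3x3 matrix or [rigid_transform()].
#' @return List of two branch solutions, each a list with `q` (3-vector,
#'   radians), `branch` (`"i"` or `"ii"`), and logical `degenerate`.
#' @export
shoulder_joint_candidates <- function(T) {
  R <- if (inherits(T, "rigid_transform")) T$R else unname(as.matrix(T))
  assert_rotation(R)
  ny <- R[1, 2]; oy <- R[2, 2]; ay <- R[3, 2]
  ax <- R[3, 1]; az <- R[3, 3]
  root <- sqrt(ny^2 + oy^2)
  degenerate <- root < 1e-9
  if (degenerate) {
    b1 <- c(0, atan2(ay, root), atan2(az, -ax))
    b2 <- c(0, atan2(ay, -root), atan2(-az, ax))
  } else {
    b1 <- c(atan2(-ny, oy), atan2(ay, root), atan2(az, -ax))
    b2 <- c(atan2(ny, -oy), atan2(ay, -root), atan2(-az, ax))
  }
  list(list(q = b1, branch = "i", degenerate = degenerate),
       list(q = b2, branch = "ii", degenerate = degenerate))
}

#' Elbow flexion from the shoulder-wrist distance
#'
#' The elbow angle is the only joint affecting the shoulder-wrist distance,
#' so it follows unequivocally from the law of cosines; in the DH
#' convention used here the closed form is
#' `q4 = arcsin((l_u^2 + l_f^2 - ||W - S||^2) / (2 l_u l_f))`,
#' with full extension at `q4 = -pi/2`. This is exactly consistent with the
#' forward kinematics (`||W - S||^2 = l_u^2 + l_f^2 - 2 l_u l_f sin(q4)`),
#' verified by roundtrip in the test suite.
#'
#' @param S,W shoulder and wrist positions (m).
#' @param l_u,l_f segment lengths (m).
#' @return `q4` in `[-pi/2, pi/2]`, radians.
#' @export
elbow_flexion_from_distance <- function(S, W, l_u, l_f) {
  d2 <- sum((W - S)^2)
  arg <- (l_u^2 + l_f^2 - d2) / (2 * l_u * l_f)
  if (abs(arg) > 1 + 1e-9)
    stop("limb lengths inconsistent with wrist-shoulder distance (",
         "arcsin argument ", format(arg, digits = 6), ")")
  asin(max(-1, min(1, arg)))
}

#' Closed-form wrist joint candidates
#'
#' Extracts the two `(q5, q6, q7)` branches from the rotation between the
#' post-elbow frame and the hand frame. Branch (iii):
#' `q5 = -atan2(n_y, o_y)`, `q6 = arcsin(a_y)`, `q7 = -atan2(a_x, a_z)`;
#' branch (iv) takes the half-turn complements (`pi` minus each), which land
#' outside the anatomical range for interior truths. Gimbal condition at
#' `|q6| = pi/2` (`q5` set to 0 by convention, flagged).
#'
#' @param T47 rotation from DH frame 4 to frame 7: 3x3 matrix or
#'   [rigid_transform()].
#' @return List of two branch solutions (fields as in
#'   [shoulder_joint_candidates()], branches `"iii"` / `"iv"`).
#' @export
wrist_joint_candidates <- function(T47) {
  R <- if (inherits(T47, "rigid_transform")) T47$R else unname(as.matrix(T47))
  assert_rotation(R)
  ny <- R[1, 2]; oy <- R[2, 2]; ay <- R[3, 2]
  ax <- R[3, 1]; az <- R[3, 3]
  if (abs(ay) > 1 + 1e-9)
    stop("invalid wrist rotation: |a_y| = ", format(abs(ay), digits = 6), " > 1")
  ay <- max(-1, min(1, ay))
  degenerate <- sqrt(ny^2 + oy^2) < 1e-9
  q5 <- if (degenerate) 0 else -atan2(ny, oy)
  q7 <- -atan2(ax, az)
  b1 <- c(q5, asin(ay), q7)
  b2 <- wrap_angle(c(pi + q5, pi - asin(ay), pi + q7))
  list(list(q = b1, branch = "iii", degenerate = degenerate),
       list(q = b2, branch = "iv", degenerate = degenerate))
}

#' Select the anatomical initial configuration
#'
#' Of the four shoulder x wrist branch combinations (elbow flexion is
#' unique), exactly one lies inside the anatomical range `[-pi/2, pi/2]`
#' for interior configurations. Boundary ties are broken by the smallest
#' total excursion `sum(|q_i|)`.
#'
#' @param shoulder_cands output of [shoulder_joint_candidates()].
#' @param q4 elbow flexion from [elbow_flexion_from_distance()].
#' @param wrist_cands output of [wrist_joint_candidates()].
#' @param tol tolerance on the range check, radians.
#' @return Joint 7-vector with attributes `shoulder_branch`, `wrist_branch`,
#'   `degenerate`.
#' @export
select_anatomical <- function(shoulder_cands, q4, wrist_cands, tol = 1e-9) {
  combos <- list()
  for (s in shoulder_cands) for (w in wrist_cands)
    combos[[length(combos) + 1L]] <- list(
      q = c(s$q, q4, w$q),
      shoulder_branch = s$branch, wrist_branch = w$branch,
      degenerate = s$degenerate || w$degenerate)
  ok <- vapply(combos, function(x) all(abs(x$q) <= pi / 2 + tol), logical(1))
  if (!any(ok)) {
    msg <- vapply(combos, function(x)
      paste0("(", x$shoulder_branch, ",", x$wrist_branch, "): ",
             paste(round(x$q, 3), collapse = " ")), character(1))
    stop("no anatomical solution among the four branch combinations:\n",
         paste(msg, collapse = "\n"))
  }
  idx <- which(ok)
  if (length(idx) > 1L) {
    tot <- vapply(combos[idx], function(x) sum(abs(x$q)), numeric(1))
    idx <- idx[which.min(tot)]
  }
  sel <- combos[[idx]]
  structure(sel$q, shoulder_branch = sel$shoulder_branch,
            wrist_branch = sel$wrist_branch, degenerate = sel$degenerate)
}

#' Initial joint configuration from the initially known poses
#'
#' Combines the closed-form branch extractions into the full initial
#' configuration, given the shoulder base pose (measured at the start of
#' the session), the elbow pose (estimated from the accelerometer) and the
#' wrist pose (the robot end effector).
#'
#' @param shoulder_pose,elbow_pose,wrist_pose [rigid_transform()]s in the
#'   robot frame.
#' @param geom an [arm_geometry()].
#' @return Joint 7-vector (see [select_anatomical()] for attributes).
#' @export
initial_pose <- function(shoulder_pose, elbow_pose, wrist_pose, geom) {
  R0 <- shoulder_pose$R
  R03 <- t(R0) %*% elbow_pose$R
  sc <- shoulder_joint_candidates(R03)
  q4 <- elbow_flexion_from_distance(shoulder_pose$p, wrist_pose$p,
                                    geom$l_u, geom$l_f)
  dh <- arm_dh_table(geom$l_u, geom$l_f)
  A4 <- dh_transform(dh[4, ], q4)
  R47 <- t(R03 %*% A4$R) %*% (t(R0) %*% wrist_pose$R)
  wc <- wrist_joint_candidates(R47)
  select_anatomical(sc, q4, wc)
}

#' Initial configuration from the first sample of a recording
#'
#' Estimates the elbow from the first accelerometer sample and applies
#' [initial_pose()]. The shoulder base orientation comes from the geometry;
#' its position from the first shoulder sample.
#'
#' @param rec a [session_recording()].
#' @param geom an [arm_geometry()].
#' @return Joint 7-vector.
#' @export
initial_pose_from_recording <- function(rec, geom) {
  S <- rec$shoulder[1L, ]
  W <- rec$poses[[1L]]
  est <- estimate_elbow(rec$accel[1L, ], S, W$p, geom, prev = NULL)
  initial_pose(rigid_transform(geom$shoulder_pose$R, S), est$pose, W, geom)
}
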