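#' Swivel angle of the arm
#'
#' The redundancy parameter of the 7-DoF arm: the signed angle, measured
#' about the shoulder-to-wrist axis, between the plane through shoulder,
#' elbow and wrist and the reference plane spanned by the shoulder-wrist
#' axis and a fixed reference axis (by default a horizontal axis, see
#' [swivel_reference_axis()]).
#'
#' @param S,E,W shoulder, elbow and wrist points, 3-vectors (m).
#' @param ref_axis fixed unit 3-vector defining the reference plane.
#' @return Swivel angle in `(-pi, pi]`, radians.
#' @export
swivel_angle <- function(S, E, W, ref_axis) {
  sw <- W - S
  nsw <- sqrt(sum(sw^2))
  if (nsw < 1e-9) stop("degenerate swivel geometry: shoulder and wrist coincide")
  n <- sw / nsw
  u <- (E - S) - sum((E - S) * n) * n
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9)
    stop("degenerate swivel geometry: shoulder, elbow and wrist are collinear")
  r <- ref_axis - sum(ref_axis * n) * n
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9)
    stop("degenerate swivel geometry: reference axis parallel to the shoulder-wrist axis")
  atan2(sum(cross3(r, u) * n), sum(r * u))
}

# swivel angle as a function of joint angles (for the finite-difference row)
.swivel_of_q <- function(q, geom, ref_axis, shoulder = NULL) {
  pts <- joint_points(q, geom, shoulder)
  swivel_angle(pts$S, pts$E, pts$W, ref_axis)
}

#' Geometric Jacobian of the hand pose
#'
#' Standard 6x7 Jacobian of the wrist/hand frame: column i is
#' `[z_{i-1} x (p_w - p_{i-1}); z_{i-1}]` for the revolute joint i, with
#' axes and origins taken from the forward kinematics.
#'
#' @inheritParams forward_kinematics
#' @return 6x7 matrix; rows 1-3 linear (m/s per rad/s), rows 4-6 angular.
#' @export
geometric_jacobian <- function(q, geom, shoulder = NULL) {
  f <- .fk_frames(q, geom, 7L, shoulder)
  .geometric_jacobian_frames(f)
}

.geometric_jacobian_frames <- function(f) {
  pw <- f$ps[[8L]]
  J <- matrix(0, 6L, 7L)
  for (i in 1:7) {
    z <- f$Rs[[i]][, 3L]
    J[1:3, i] <- cross3(z, pw - f$ps[[i]])
    J[4:6, i] <- z
  }
  J
}

#' Swivel-angle Jacobian
#'
#' Row vector of partial derivatives of the swivel angle with respect to the
#' seven joints, computed by central finite differences of the swivel angle
#' through the forward kinematics (step `1e-6` rad, differences wrapped).
#' Entries 5-7 are zero because the shoulder, elbow and wrist points depend
#' only on q1..q4.
#'
#' @inheritParams forward_kinematics
#' @param ref_axis reference axis of the swivel plane; default
#'   [swivel_reference_axis()].
#' @param step finite-difference step, radians.
#' @return 1x7 matrix.
#' @export
swivel_jacobian <- function(q, geom, ref_axis = NULL, step = 1e-6,
                            shoulder = NULL) {
  if (is.null(ref_axis)) ref_axis <- swivel_reference_axis(geom)
  J <- matrix(0, 1L, 7L)
  for (i in 1:7) {
    qp <- q; qp[i] <- q[i] + step
    qm <- q; qm[i] <- q[i] - step
    J[1L, i] <- wrap_angle(.swivel_of_q(qp, geom, ref_axis, shoulder) -
                           .swivel_of_q(qm, geom, ref_axis, shoulder)) / (2 * step)
  }
  J
}

#' Augmented Jacobian
#'
#' The 6x7 geometric Jacobian stacked with the 1x7 swivel row, yielding the
#' square 7x7 matrix that makes the redundant arm uniquely invertible for a
#' given hand pose and swivel angle.
#'
#' @inheritParams swivel_jacobian
#' @return 7x7 matrix; rows 1-6 are [geometric_jacobian()], row 7 is
#'   [swivel_jacobian()].
#' @export
augmented_jacobian <- function(q, geom, ref_axis = NULL, shoulder = NULL) {
  if (is.null(ref_axis)) ref_axis <- swivel_reference_axis(geom)
  rbind(geometric_jacobian(q, geom, shoulder),
        swivel_jacobian(q, geom, ref_axis, shoulder = shoulder))
}

#' Damped least-squares pseudoinverse
#'
#' `J' (J J' + k2 I)^-1`: bounded near singularities for `k2 > 0`; equal to
#' the exact (pseudo)inverse in the limit `k2 -> 0`.
#'
#' @param J matrix.
#' @param k2 damping factor (squared), `>= 0`.
#' @return Matrix of transposed shape.
#' @export
damped_pseudoinverse <- function(J, k2) {
  stopifnot(k2 >= 0)
  m <- nrow(J)
  t(J) %*% solve(J %*% t(J) + k2 * diag(m))
}

#' Task-space error between two poses and swivel angles
#'
#' Rows 1-3: position difference (desired minus current, m). Rows 4-6:
#' orientation error as the axis-angle vector of `R_d R_c'`. Row 7: swivel
#' difference wrapped to `(-pi, pi]`.
#'
#' @param current,desired [rigid_transform()]s of the hand.
#' @param current_alpha,desired_alpha swivel angles, radians.
#' @return Numeric 7-vector.
#' @export
pose_error <- function(current, desired, current_alpha, desired_alpha) {
  c(desired$p - current$p,
    rotation_log(desired$R %*% t(current$R)),
    wrap_angle(desired_alpha - current_alpha))
}

#' Closed-loop IK configuration
#'
#' @param gain feedback gain: scalar or 7-vector forming the diagonal gain
#'   matrix K. Default 1.5, the clinical setting.
#' @param k2 damping factor of the least-squares inverse, in the squared
#'   units of the task rows (meters). The default `5e-7` is the clinical
#'   tuning of 0.5 expressed on the SI meter scale: the original value was
#'   tuned on a millimeter-scale Jacobian, where it amounts to the same
#'   negligible *relative* damping; taking 0.5 literally against a Jacobian
#'   in meters (singular values of order 0.1-2) would bias the tracking by
#'   tens of degrees. See the methods vignette.
#' @param dt nominal sampling interval, seconds (default 0.01, i.e. 100 Hz).
#' @param swivel_ref_axis reference axis of the swivel plane, or `NULL` for
#'   the default [swivel_reference_axis()].
#' @param cond_warn condition-number threshold of the augmented Jacobian
#'   above which a diagnostic warning is emitted (never an abort).
#' @param sing_sigma,sing_k2 variable-damping (numerical filtering)
#'   parameters: when the smallest singular value of the augmented Jacobian
#'   drops below `sing_sigma`, the damping is raised smoothly up to
#'   `k2 + sing_k2` at the singularity itself, bounding the joint
#'   velocities through singular passages while leaving well-conditioned
#'   postures (smallest singular value above `sing_sigma`, which the arm
#'   workspace normally satisfies) undamped. Set `sing_k2 = 0` for plain
#'   constant damping.
#' @param qdot_max joint-velocity saturation, rad/s: when any component of
#'   the commanded velocity exceeds this, the whole vector is rescaled
#'   (direction preserved). True joint speeds in the quasi-static regime
#'   stay below 0.5 rad/s, so the default 5 rad/s is a 10x stability guard
#'   that never engages in normal operation; it prevents a single
#'   inconsistent sample (e.g. an unrecorded trunk shift) from throwing the
#'   integrated state onto a mirrored solution branch.
#' @return Object of class `ik_config`.
#' @export
ik_config <- function(gain = 1.5, k2 = 5e-7, dt = 0.01,
                      swivel_ref_axis = NULL, cond_warn = 1e6,
                      sing_sigma = 0.1, sing_k2 = 0.0025, qdot_max = 5) {
  stopifnot(all(gain >= 0), length(gain) %in% c(1L, 7L), k2 >= 0, dt > 0,
            sing_sigma >= 0, sing_k2 >= 0, qdot_max > 0)
  structure(list(gain = if (length(gain) == 1L) rep(gain, 7L) else gain,
                 k2 = k2, dt = dt, swivel_ref_axis = swivel_ref_axis,
                 cond_warn = cond_warn, sing_sigma = sing_sigma,
                 sing_k2 = sing_k2, qdot_max = qdot_max),
            class = "ik_config")
}

#' One step of the closed-loop inverse kinematics
#'
#' Computes `qdot = J*_A(q) (c(twist, alpha_rate) + K err)` with the damped
#' inverse of the augmented Jacobian and integrates one sampling interval:
#' `q_k = q_{k-1} + qdot dt`.
#'
#' @param q joint configuration at the previous sample, radians.
#' @param desired_pose target hand pose ([rigid_transform()]).
#' @param desired_alpha target swivel angle, radians.
#' @param twist feedforward hand velocity, 6-vector (m/s, rad/s).
#' @param alpha_rate feedforward swivel rate, rad/s.
#' @param cfg an [ik_config()].
#' @param geom an [arm_geometry()].
#' @param shoulder optional per-sample shoulder position (3-vector).
#' @return Updated joint 7-vector, with attributes `err` (the 7-vector task
#'   error before the step) and `cond` (condition number of the augmented
#'   Jacobian).
#' @export
ik_step <- function(q, desired_pose, desired_alpha, twist = numeric(6),
                    alpha_rate = 0, cfg = ik_config(), geom,
                    shoulder = NULL) {
  if (!all(is.finite(q), is.finite(desired_pose$p), is.finite(desired_pose$R),
           is.finite(desired_alpha), is.finite(twist), is.finite(alpha_rate)))
    stop("non-finite input to ik_step")
  ref_axis <- if (is.null(cfg$swivel_ref_axis)) swivel_reference_axis(geom) else
    cfg$swivel_ref_axis
  f <- .fk_frames(q, geom, 7L, shoulder)
  current <- rigid_transform(f$Rs[[8L]], f$ps[[8L]], check = FALSE)
  alpha <- swivel_angle(f$ps[[1L]], f$ps[[4L]], f$ps[[6L]], ref_axis)
  err <- pose_error(current, desired_pose, alpha, desired_alpha)
  JA <- rbind(.geometric_jacobian_frames(f),
              swivel_jacobian(q, geom, ref_axis, shoulder = shoulder))
  sv <- svd(JA, nu = 0, nv = 0)$d
  cond <- sv[1L] / max(sv[7L], .Machine$double.xmin)
  if (cond > cfg$cond_warn)
    warning("augmented Jacobian condition number ", format(cond, digits = 3),
            " exceeds ", cfg$cond_warn)
  k2 <- cfg$k2
  if (cfg$sing_k2 > 0 && sv[7L] < cfg$sing_sigma)  # numerical filtering
    k2 <- k2 + cfg$sing_k2 * (1 - (sv[7L] / cfg$sing_sigma)^2)
  Jstar <- damped_pseudoinverse(JA, k2)
  qdot <- as.numeric(Jstar %*% (c(twist, alpha_rate) + cfg$gain * err))
  peak <- max(abs(qdot))
  if (peak > cfg$qdot_max) qdot <- qdot * (cfg$qdot_max / peak)
  structure(q + qdot * cfg$dt, err = err, cond = cond)
}

#' Reconstruct the joint trajectory of a recorded session
#'
#' The full per-sample pipeline: estimate the elbow from the accelerometer
#' (gravity rotation, gamma plane constraint, candidate selection), derive
#' the target swivel angle from shoulder / estimated elbow / recorded wrist,
#' finite-difference the recorded hand poses into a feedforward twist, and
#' advance the closed-loop inverse kinematics one sampling interval.
#'
#' Accelerometer samples failing the quasi-static gate (`| ||v|| - 1 | >
#' 0.2` g) hold the previous gravity rotation; degenerate elbow selections
#' (near-collinear arm) fall back to the previously selected branch.
#'
#' @param rec a [session_recording()].
#' @param geom an [arm_geometry()].
#' @param cfg an [ik_config()].
#' @param q0 initial joint configuration (radians); when `NULL` it is
#'   computed from the first sample with [initial_pose_from_recording()].
#' @param on_missing `"abort"` (default) or `"skip"`: what to do with rows
#'   containing non-finite samples. Skipped rows are dropped from the output.
#' @param elbow_speed_max continuity gate on the elbow estimate, m/s: a
#'   candidate elbow moving faster than this relative to the previous raw
#'   estimate is rejected and the last accepted pose held. The true elbow
#'   moves below ~0.2 m/s in the quasi-static regime, while the estimate
#'   can jump by decimeters in one sample at postures where the gravity
#'   cone grazes the arm-plane constraint (an intrinsic observability
#'   weakness of the single-accelerometer method); 1 m/s separates the two
#'   cleanly. Comparing against the raw (not the held) estimate lets a
#'   genuine level shift through after one sample.
#' @return Object of class `arm_reconstruction`: list with `time`, joint
#'   matrix `q` (n x 7), estimated elbow positions `elbow` (n x 3), target
#'   swivel `alpha`, and a `diagnostics` data frame (task error norm,
#'   condition number, gating and branch flags).
#' @export
reconstruct_trajectory <- function(rec, geom, cfg = ik_config(), q0 = NULL,
                                   on_missing = c("abort", "skip"),
                                   elbow_speed_max = 1) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(rec, "session_recording"))
  n <- length(rec$time)
  if (n < 2L) stop("recording must contain at least two samples")
  if (any(diff(rec$time) <= 0)) stop("timestamps must be strictly increasing")
  ref_axis <- if (is.null(cfg$swivel_ref_axis)) swivel_reference_axis(geom) else
    cfg$swivel_ref_axis

  if (is.null(q0)) q0 <- initial_pose_from_recording(rec, geom)

  q_out <- matrix(NA_real_, n, 7L)
  elbow_out <- matrix(NA_real_, n, 3L)
  alpha_out <- rep(NA_real_, n)
  err_norm <- rep(NA_real_, n)
  cond_out <- rep(NA_real_, n)
  gated <- logical(n)
  branch <- rep(NA_integer_, n)
  keep <- rep(TRUE, n)

  q <- as.numeric(q0)
  prev_elbow <- NULL        # last estimate_elbow() result
  prev_raw <- NULL          # last raw elbow point (pre-gate)
  prev_used <- NULL         # last accepted elbow pose
  prev_pose <- NULL         # last recorded hand pose used
  prev_alpha <- NULL
  prev_time <- NULL
  n_limit <- 0L

  for (k in seq_len(n)) {
    pose_k <- rec$poses[[k]]
    acc_k <- rec$accel[k, ]
    sh_k <- rec$shoulder[k, ]
    if (!all(is.finite(pose_k$p), is.finite(pose_k$R), is.finite(acc_k),
             is.finite(sh_k))) {
      if (on_missing == "abort")
        stop("non-finite sample at row ", k, " (t = ", rec$time[k], " s)")
      warning("skipping non-finite sample at row ", k)
      keep[k] <- FALSE
      next
    }

    est <- estimate_elbow(acc_k, sh_k, pose_k$p, geom, prev = prev_elbow)
    raw_p <- est$pose$p
    if (!is.null(prev_raw) && !is.null(prev_time)) {
      speed <- sqrt(sum((raw_p - prev_raw)^2)) / (rec$time[k] - prev_time)
      if (speed > elbow_speed_max && !is.null(prev_used)) {
        est$pose <- prev_used   # continuity gate: hold last accepted pose
        est$gated <- TRUE
      }
    }
    prev_raw <- raw_p
    prev_used <- est$pose
    prev_elbow <- est
    alpha_k <- tryCatch(
      swivel_angle(sh_k, est$pose$p, pose_k$p, ref_axis),
      error = function(e) if (is.null(prev_alpha))
        stop("degenerate swivel geometry at the first sample: ",
             conditionMessage(e)) else prev_alpha)

    if (is.null(prev_pose)) {
      # first usable sample: output the initial pose, no integration step
      q <- as.numeric(q0)
    } else {
      dtk <- rec$time[k] - prev_time
      twist <- c((pose_k$p - prev_pose$p) / dtk,
                 rotation_log(pose_k$R %*% t(prev_pose$R)) / dtk)
      alpha_rate <- wrap_angle(alpha_k - prev_alpha) / dtk
      cfg_k <- cfg; cfg_k$dt <- dtk
      q <- ik_step(q, pose_k, alpha_k, twist, alpha_rate, cfg_k, geom,
                   shoulder = sh_k)
      err_norm[k] <- sqrt(sum(attr(q, "err")^2))
      cond_out[k] <- attr(q, "cond")
      q <- as.numeric(q)
    }
    if (any(abs(q) > pi / 2 + 1e-12)) n_limit <- n_limit + 1L

    q_out[k, ] <- q
    elbow_out[k, ] <- est$pose$p
    alpha_out[k] <- alpha_k
    gated[k] <- est$gated
    branch[k] <- est$index
    prev_pose <- pose_k
    prev_alpha <- alpha_k
    prev_time <- rec$time[k]
  }

  if (n_limit > 0L)
    warning(n_limit, " sample(s) exceeded the anatomical joint range ",
            "[-pi/2, pi/2] (soft limit, not clamped)")

  structure(list(
    time = rec$time[keep],
    q = q_out[keep, , drop = FALSE],
    elbow = elbow_out[keep, , drop = FALSE],
    alpha = alpha_out[keep],
    q0 = as.numeric(q0),
    config = cfg,
    diagnostics = data.frame(
      time = rec$time[keep],
      err_norm = err_norm[keep],
      cond = cond_out[keep],
      gated = gated[keep],
      elbow_branch = branch[keep])
  ), class = "arm_reconstruction")
}

#' @export
print.arm_reconstruction <- function(x, ...) {
  cat("<arm_reconstruction>", nrow(x$q), "samples,",
      round(diff(range(x$time)), 2), "s\n")
  cat("median task error norm:",
      format(stats::median(x$diagnostics$err_norm, na.rm = TRUE), digits = 3),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.arm_reconstruction <- function(x, ...) {
  d <- data.frame(time_s = x$time)
  q <- x$q; colnames(q) <- paste0("q", 1:7, "_rad")
  cbind(d, q)
}
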