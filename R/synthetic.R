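#' Smooth synthetic joint trajectories
#'
#' Generates ground-truth joint time series emulating slow point-to-point
#' reaching therapy: each joint is a sum of low-frequency sinusoids around a
#' random working posture (within +-0.35 rad of the reference), with a
#' per-joint range of motion drawn between roughly 9 and 40 degrees -- the
#' scale observed in end-effector therapy sessions. The series is rescaled
#' so that the trajectory stays inside `(-pi/2 + 0.1, pi/2 - 0.1)` and the
#' joint speed never exceeds 0.5 rad/s (the quasi-static regime the
#' accelerometer model assumes). Deterministic given `seed`.
#'
#' @param duration_s session length, seconds.
#' @param dt_s sampling interval, seconds (default 0.01 = 100 Hz).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param amplitude_scale scales the whole excursion around the reference
#'   posture; 0 gives a constant reference posture, 1 (default) the full
#'   calibrated excursion. Values above 1 may violate the construction
#'   bounds and are rejected.
#' @param n_harmonics sinusoids per joint.
#' @return Object of class `joint_trajectory`: list with `time` (seconds)
#'   and `q` (n x 7 matrix, radians).
#' @export
generate_joint_trajectory <- function(duration_s, dt_s = 0.01, seed = NULL,
                                      amplitude_scale = 1, n_harmonics = 3) {
  stopifnot(duration_s > 0, dt_s > 0, amplitude_scale >= 0,
            amplitude_scale <= 1)
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, duration_s, by = dt_s)
  n <- length(time)
  q <- matrix(0, n, 7L)
  margin <- pi / 2 - 0.1
  vmax <- 0.5
  for (j in 1:7) {
    centre <- stats::runif(1, -0.35, 0.35)
    freq <- stats::runif(n_harmonics, 0.05, 0.2)           # Hz
    amp <- stats::runif(n_harmonics, 0.2, 1)
    phase <- stats::runif(n_harmonics, 0, 2 * pi)
    rom_target <- stats::runif(1, 0.15, 0.7)               # rad, peak to peak
    amp <- amp / sum(amp) * rom_target / 2
    # enforce range confinement and the quasi-static speed bound
    s_range <- (margin - abs(centre)) / sum(amp)
    s_speed <- vmax / sum(amp * 2 * pi * freq)
    amp <- amp * min(1, 0.95 * s_range, 0.95 * s_speed)
    qt <- centre
    for (h in seq_len(n_harmonics))
      qt <- qt + amp[h] * sin(2 * pi * freq[h] * time + phase[h])
    q[, j] <- amplitude_scale * qt
  }
  structure(list(time = time, q = q), class = "joint_trajectory")
}

#' Sensor noise and disturbance specification
#'
#' @param accel_sigma Gaussian noise on each accelerometer component,
#'   g units.
#' @param pose_sigma_pos Gaussian noise on the end-effector position, m.
#' @param pose_sigma_rot end-effector orientation noise: rotation by a
#'   Gaussian angle (rad) about a random axis.
#' @param shoulder_drift_amplitude amplitude of a slow sinusoidal shoulder
#'   displacement (m) emulating trunk compensation. The displacement is
#'   real: the arm base moves with it, the end-effector poses follow, and
#'   the shoulder stream records it (shoulder motion is measured during a
#'   session, so the reconstruction is expected to compensate it). For an
#'   unrecorded, inconsistent disturbance use [inject_shoulder_steps()].
#' @param drift_freq_hz frequency of the shoulder drift.
#' @param seed integer seed used by [simulate_recording()].
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(accel_sigma = 0, pose_sigma_pos = 0,
                       pose_sigma_rot = 0, shoulder_drift_amplitude = 0,
                       drift_freq_hz = 0.1, seed = NULL) {
  stopifnot(accel_sigma >= 0, pose_sigma_pos >= 0, pose_sigma_rot >= 0,
            shoulder_drift_amplitude >= 0, drift_freq_hz >= 0)
  structure(list(accel_sigma = accel_sigma, pose_sigma_pos = pose_sigma_pos,
                 pose_sigma_rot = pose_sigma_rot,
                 shoulder_drift_amplitude = shoulder_drift_amplitude,
                 drift_freq_hz = drift_freq_hz, seed = seed),
            class = "noise_spec")
}

#' Session recording container
#'
#' Synchronized time series of everything the reconstruction consumes:
#' robot end-effector poses, accelerometer samples, shoulder positions, and
#' (for synthetic sessions) the ground-truth joints.
#'
#' @param time numeric vector of timestamps, seconds, strictly increasing.
#' @param poses list of hand [rigid_transform()]s.
#' @param accel n x 3 matrix of accelerometer samples, g units.
#' @param shoulder n x 3 matrix of shoulder positions, m.
#' @param q_true optional n x 7 matrix of ground-truth joints, radians.
#' @return Object of class `session_recording`.
#' @export
session_recording <- function(time, poses, accel, shoulder, q_true = NULL) {
  n <- length(time)
  accel <- as.matrix(accel); shoulder <- as.matrix(shoulder)
  if (length(poses) != n || nrow(accel) != n || nrow(shoulder) != n)
    stop("recording streams must have equal length")
  if (!is.null(q_true) && nrow(as.matrix(q_true)) != n)
    stop("ground-truth joints must match the recording length")
  if (n > 1L) {
    dts <- diff(time)
    if (any(dts <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(dts / stats::median(dts) - 1)) > 0.01)
      warning("sampling interval varies by more than 1% of nominal")
  }
  structure(list(time = as.numeric(time), poses = poses, accel = accel,
                 shoulder = shoulder, q_true = q_true),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording>", length(x$time), "samples,",
      round(diff(range(x$time)), 2), "s",
      if (!is.null(x$q_true)) "(with ground truth)" else "", "\n")
  invisible(x)
}

#' Simulate the sensor streams of a joint trajectory
#'
#' Forward-simulates what the robot and the accelerometer would record while
#' the arm follows `traj`: the end-effector pose is the forward-kinematic
#' hand pose; the accelerometer reads the gravity direction rotated into the
#' current sensor frame (static model -- dynamic acceleration is left to the
#' noise term); the shoulder stream is the nominal shoulder position plus
#' the optional drift disturbance. Gravity in the robot frame is derived
#' from the mounting ([reference_gravity()]), so the reference posture
#' reproduces the reference reading `(0, 1, 0)` exactly.
#'
#' @param traj a [generate_joint_trajectory()] result (or compatible list).
#' @param geom an [arm_geometry()].
#' @param noise a [noise_spec()].
#' @return A [session_recording()] with ground truth retained.
#' @export
simulate_recording <- function(traj, geom, noise = noise_spec()) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  time <- traj$time
  n <- length(time)
  ghat <- reference_gravity(geom)
  poses <- vector("list", n)
  accel <- matrix(0, n, 3L)
  shoulder <- matrix(rep(geom$shoulder_pose$p, each = n), n, 3L)
  drift_dir <- c(1, 0, 0); drift_phase <- 0
  if (noise$shoulder_drift_amplitude > 0) {
    v <- stats::rnorm(3)
    drift_dir <- v / sqrt(sum(v^2))
    drift_phase <- stats::runif(1, 0, 2 * pi)
  }
  for (k in seq_len(n)) {
    q <- traj$q[k, ]
    if (noise$shoulder_drift_amplitude > 0)
      shoulder[k, ] <- shoulder[k, ] + drift_dir *
        noise$shoulder_drift_amplitude *
        sin(2 * pi * noise$drift_freq_hz * time[k] + drift_phase)
    f <- .fk_frames(q, geom, 7L, shoulder = shoulder[k, ])
    p <- f$ps[[8L]]; R <- f$Rs[[8L]]
    if (noise$pose_sigma_pos > 0)
      p <- p + stats::rnorm(3, 0, noise$pose_sigma_pos)
    if (noise$pose_sigma_rot > 0) {
      ax <- stats::rnorm(3)
      R <- axis_angle_rotation(ax, stats::rnorm(1, 0, noise$pose_sigma_rot)) %*% R
    }
    poses[[k]] <- rigid_transform(R, p, check = FALSE)
    Racc <- f$Rs[[4L]] %*% t(geom$elbow_in_accel_ref)
    a <- as.numeric(t(Racc) %*% ghat)
    if (noise$accel_sigma > 0) a <- a + stats::rnorm(3, 0, noise$accel_sigma)
    accel[k, ] <- a
  }
  session_recording(time, poses, accel, shoulder, q_true = traj$q)
}

#' Inject step displacements into the shoulder stream
#'
#' Emulates abrupt trunk compensation: from each time in `times` onward the
#' reported shoulder positions are shifted by the corresponding step vector
#' (steps accumulate). End-effector poses are untouched (robot frame).
#'
#' @param rec a [session_recording()].
#' @param steps 3-vector, or k x 3 matrix of per-event steps, meters; each
#'   component within +-0.1 m.
#' @param times numeric vector of onset times, seconds.
#' @return The modified [session_recording()].
#' @export
inject_shoulder_steps <- function(rec, steps, times) {
  steps <- if (is.matrix(steps)) steps else
    matrix(steps, nrow = length(times), ncol = 3L, byrow = TRUE)
  stopifnot(nrow(steps) == length(times), all(abs(steps) <= 0.1))
  for (j in seq_along(times)) {
    idx <- rec$time >= times[j]
    rec$shoulder[idx, ] <- rec$shoulder[idx, ] +
      matrix(steps[j, ], sum(idx), 3L, byrow = TRUE)
  }
  rec
}
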