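#' Read / write a session recording as CSV files
#'
#' Plain comma-separated files with a header row and `.` decimal marks:
#'
#' * poses: `time_s,px,py,pz,qw,qx,qy,qz` (position m, unit quaternion);
#' * accel: `time_s,ax_g,ay_g,az_g` (g units, sensor frame);
#' * shoulder: `time_s,sx,sy,sz` (m, robot frame);
#' * joints (optional ground truth): `time_s,q1_rad,...,q7_rad`.
#'
#' @param poses_csv,accel_csv,shoulder_csv,joints_csv file paths;
#'   `joints_csv` may be `NULL`.
#' @return A [session_recording()].
#' @export
read_recording <- function(poses_csv, accel_csv, shoulder_csv,
                           joints_csv = NULL) {
  po <- utils::read.csv(poses_csv)
  ac <- utils::read.csv(accel_csv)
  sh <- utils::read.csv(shoulder_csv)
  need <- function(d, cols, path) {
    miss <- setdiff(cols, names(d))
    if (length(miss))
      stop("file '", path, "' is missing column(s): ",
           paste(miss, collapse = ", "))
  }
  need(po, c("time_s", "px", "py", "pz", "qw", "qx", "qy", "qz"), poses_csv)
  need(ac, c("time_s", "ax_g", "ay_g", "az_g"), accel_csv)
  need(sh, c("time_s", "sx", "sy", "sz"), shoulder_csv)
  if (nrow(po) != nrow(ac) || nrow(po) != nrow(sh))
    stop("recording CSV files differ in length")
  if (max(abs(po$time_s - ac$time_s), abs(po$time_s - sh$time_s)) > 1e-9)
    stop("recording CSV files are not synchronized")
  poses <- lapply(seq_len(nrow(po)), function(k) {
    quat <- as.numeric(po[k, c("qw", "qx", "qy", "qz")])
    if (all(is.finite(quat))) {
      rigid_transform(rotation_from_quaternion(quat),
                      as.numeric(po[k, c("px", "py", "pz")]), check = FALSE)
    } else {
      rigid_transform(diag(3) * NA_real_,
                      as.numeric(po[k, c("px", "py", "pz")]), check = FALSE)
    }
  })
  q_true <- NULL
  if (!is.null(joints_csv)) {
    jt <- utils::read.csv(joints_csv)
    need(jt, c("time_s", paste0("q", 1:7, "_rad")), joints_csv)
    q_true <- as.matrix(jt[, paste0("q", 1:7, "_rad")])
  }
  session_recording(po$time_s, poses,
                    as.matrix(ac[, c("ax_g", "ay_g", "az_g")]),
                    as.matrix(sh[, c("sx", "sy", "sz")]), q_true)
}

#' @rdname read_recording
#' @param rec a [session_recording()].
#' @param prefix path prefix; writes `<prefix>_poses.csv`,
#'   `<prefix>_accel.csv`, `<prefix>_shoulder.csv` and, when ground truth is
#'   present, `<prefix>_joints.csv`.
#' @return `write_recording` returns the written paths invisibly.
#' @export
write_recording <- function(rec, prefix) {
  quats <- t(vapply(rec$poses, function(p) quaternion_from_rotation(p$R),
                    numeric(4)))
  pos <- t(vapply(rec$poses, function(p) p$p, numeric(3)))
  paths <- c(poses = paste0(prefix, "_poses.csv"),
             accel = paste0(prefix, "_accel.csv"),
             shoulder = paste0(prefix, "_shoulder.csv"))
  utils::write.csv(
    data.frame(time_s = rec$time, px = pos[, 1], py = pos[, 2], pz = pos[, 3],
               qw = quats[, 1], qx = quats[, 2], qy = quats[, 3],
               qz = quats[, 4]),
    paths["poses"], row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = rec$time, ax_g = rec$accel[, 1],
               ay_g = rec$accel[, 2], az_g = rec$accel[, 3]),
    paths["accel"], row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = rec$time, sx = rec$shoulder[, 1],
               sy = rec$shoulder[, 2], sz = rec$shoulder[, 3]),
    paths["shoulder"], row.names = FALSE)
  if (!is.null(rec$q_true)) {
    jt <- data.frame(time_s = rec$time, rec$q_true)
    names(jt) <- c("time_s", paste0("q", 1:7, "_rad"))
    paths["joints"] <- paste0(prefix, "_joints.csv")
    utils::write.csv(jt, paths["joints"], row.names = FALSE)
  }
  invisible(paths)
}

#' Run a full reconstruction session from files
#'
#' Orchestrates the pipeline on recorded (or simulated) files: read the
#' recording and geometry, compute the initial pose from the first sample,
#' reconstruct the joint trajectory, and -- when ground truth is available --
#' evaluate the accuracy metrics. Optionally writes the joint trajectory
#' (CSV, with diagnostics columns) and the metrics (JSON).
#'
#' @param poses_csv,accel_csv,shoulder_csv recording files
#'   (see [read_recording()]).
#' @param geometry path to a geometry JSON ([read_geometry_config()]) or an
#'   [arm_geometry()] object.
#' @param joints_csv optional ground-truth joints CSV.
#' @param cfg an [ik_config()].
#' @param out_dir optional output directory; writes `joints_estimated.csv`
#'   and `metrics.json` there.
#' @param on_missing `"skip"` (default) or `"abort"` for non-finite rows.
#' @return List with the `reconstruction`, the `metrics` (or `NULL`), and
#'   the output paths written.
#' @export
run_session <- function(poses_csv, accel_csv, shoulder_csv, geometry,
                        joints_csv = NULL, cfg = ik_config(),
                        out_dir = NULL, on_missing = c("skip", "abort")) {
  on_missing <- match.arg(on_missing)
  geom <- if (inherits(geometry, "arm_geometry")) geometry else
    read_geometry_config(geometry)
  rec <- read_recording(poses_csv, accel_csv, shoulder_csv, joints_csv)
  recon <- reconstruct_trajectory(rec, geom, cfg, on_missing = on_missing)
  metrics <- if (!is.null(rec$q_true)) joint_metrics(recon, rec, geom)
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jp <- file.path(out_dir, "joints_estimated.csv")
    out <- cbind(as.data.frame(recon),
                 recon$diagnostics[c("err_norm", "cond", "gated",
                                     "elbow_branch")])
    utils::write.csv(out, jp, row.names = FALSE)
    paths <- c(joints = jp)
    if (!is.null(metrics)) {
      mp <- file.path(out_dir, "metrics.json")
      jsonlite::write_json(metrics, mp, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
      paths["metrics"] <- mp
    }
  }
  list(reconstruction = recon, metrics = metrics, paths = paths)
}
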