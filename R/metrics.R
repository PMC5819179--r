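#' RMSE and SD of an estimate against a reference
#'
#' Column-wise root-mean-square error and standard deviation of the error
#' series. Angular series are compared on differences wrapped to
#' `(-pi, pi]`. The SD uses the sample convention (`n - 1` denominator).
#'
#' @param estimated,reference numeric vectors or matrices of equal shape.
#' @param angular wrap differences as angles?
#' @return List with numeric vectors `rmse` and `sd` (one entry per column).
#' @export
rmse_sd <- function(estimated, reference, angular = TRUE) {
  estimated <- as.matrix(estimated); reference <- as.matrix(reference)
  if (!all(dim(estimated) == dim(reference)))
    stop("estimated and reference series differ in length")
  if (nrow(estimated) < 2L) stop("need at least two samples")
  d <- estimated - reference
  if (angular) d <- wrap_angle(d)
  list(rmse = sqrt(colMeans(d^2)), sd = apply(d, 2L, stats::sd))
}

#' Pearson correlation of an estimate against a reference
#'
#' @param estimated,reference numeric vectors or matrices of equal shape;
#'   both must be non-constant.
#' @return Numeric vector of product-moment correlations per column.
#' @export
pearson_r <- function(estimated, reference) {
  estimated <- as.matrix(estimated); reference <- as.matrix(reference)
  if (!all(dim(estimated) == dim(reference)))
    stop("estimated and reference series differ in length")
  sds <- c(apply(estimated, 2L, stats::sd), apply(reference, 2L, stats::sd))
  if (any(sds == 0))
    stop("correlation undefined for a constant series")
  vapply(seq_len(ncol(estimated)),
         function(j) stats::cor(estimated[, j], reference[, j]), numeric(1))
}

#' Range of motion
#'
#' Per-joint max minus min over the session, reported in degrees -- the
#' clinical assessment quantity.
#'
#' @param q numeric vector or n x 7 matrix of joint angles, radians.
#' @return Named numeric vector of ROM values, degrees.
#' @export
rom <- function(q) {
  q <- as.matrix(q)
  if (nrow(q) == 0L) stop("empty series")
  out <- (apply(q, 2L, max) - apply(q, 2L, min)) * 180 / pi
  names(out) <- paste0("q", seq_len(ncol(q)))
  out
}

#' Session metrics against ground truth
#'
#' Builds the per-joint accuracy table (RMSE and SD in degrees, Pearson R)
#' plus elbow and wrist position RMSE in centimeters. The estimated elbow
#' is the accelerometer-based series the algorithm used; the estimated
#' wrist is the recorded end-effector position; both are compared with the
#' ground-truth forward kinematics.
#'
#' @param recon an [reconstruct_trajectory()] result.
#' @param rec the [session_recording()] it was computed from; must carry
#'   `q_true`.
#' @param geom an [arm_geometry()].
#' @return List with data frame `joints` (rmse_deg, sd_deg, r per joint),
#'   scalars `elbow_rmse_cm`, `wrist_rmse_cm`, and data frame `rom_deg`
#'   (estimated and true ROM per joint).
#' @export
joint_metrics <- function(recon, rec, geom) {
  if (is.null(rec$q_true)) stop("recording carries no ground-truth joints")
  idx <- match(recon$time, rec$time)
  q_true <- rec$q_true[idx, , drop = FALSE]
  ja <- rmse_sd(recon$q, q_true, angular = TRUE)
  r <- pearson_r(recon$q, q_true)
  true_pts <- vapply(seq_len(nrow(q_true)), function(k) {
    pts <- joint_points(q_true[k, ], geom, shoulder = rec$shoulder[idx[k], ])
    c(pts$E, pts$W)
  }, numeric(6))
  elbow_err <- recon$elbow - t(true_pts[1:3, , drop = FALSE])
  wrist_rec <- t(vapply(idx, function(k) rec$poses[[k]]$p, numeric(3)))
  wrist_err <- wrist_rec - t(true_pts[4:6, , drop = FALSE])
  list(
    joints = data.frame(
      joint = paste0("q", 1:7),
      rmse_deg = ja$rmse * 180 / pi,
      sd_deg = ja$sd * 180 / pi,
      r = r),
    elbow_rmse_cm = sqrt(mean(rowSums(elbow_err^2))) * 100,
    wrist_rmse_cm = sqrt(mean(rowSums(wrist_err^2))) * 100,
    rom_deg = data.frame(joint = paste0("q", 1:7),
                         estimated = unname(rom(recon$q)),
                         true = unname(rom(q_true)))
  )
}
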