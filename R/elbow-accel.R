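#' Gravity rotation from one accelerometer sample
#'
#' Under the quasi-static assumption the accelerometer reads the gravity
#' direction in its own frame. Given the reference reading `(0, 1, 0)`, this
#' returns one rotation `R` consistent with the measurement, i.e. satisfying
#' `sample = R^-1 (0, 1, 0)` to machine precision. All other consistent
#' rotations differ by a rotation about the gravity axis (see
#' [solve_gamma()]).
#'
#' The construction follows the cross-product Rodrigues form; antiparallel
#' samples (`sample ~ (0, -1, 0)`) are handled by an explicit half-turn
#' about the sensor X axis, and near-zero rotations return the identity.
#'
#' @param sample accelerometer 3-vector in g units; its norm must be within
#'   `[0.8, 1.2]` (quasi-static band); renormalized internally.
#' @return Object of class `gravity_rotation`: list with the rotation `R`,
#'   the rotation angle `theta`, and the (unnormalized) cross-product axis
#'   `V = (0,1,0) x sample`.
#' @export
#' @examples
#' gravity_rotation(c(0, 1, 0))$theta   # reference reading: no rotation
gravity_rotation <- function(sample) {
  v <- as.numeric(sample)
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv < 0.8 || nv > 1.2)
    stop("accelerometer sample norm ", format(nv, digits = 3),
         " outside the quasi-static band [0.8, 1.2] g")
  v <- v / nv
  g0 <- c(0, 1, 0)
  V <- cross3(g0, v)
  st <- sqrt(sum(V^2))
  ct <- sum(g0 * v)
  if (st < 1e-8) {
    R <- if (ct > 0) diag(3) else rot_x(pi)
  } else {
    M <- skew(V)
    # printed construction maps (0,1,0) onto the sample; the measurement
    # contract sample = R^-1 (0,1,0) requires its transpose
    R <- t(diag(3) + M + M %*% M * ((1 - ct) / st^2))
  }
  structure(list(R = R, theta = atan2(st, ct), V = V),
            class = "gravity_rotation")
}

#' Solve the gamma plane constraint
#'
#' The gravity rotation leaves one degree of freedom: a rotation by `gamma`
#' about the gravity direction (expressed in the accelerometer reference
#' frame, axis `(0, 1, 0)`). The physical arm requires the sensor XY plane
#' to contain the shoulder-to-wrist segment, i.e. the sensor Z axis to be
#' orthogonal to `W - S`. Written out, that is a harmonic equation
#' `a cos(gamma) + b sin(gamma) + c = 0` with two roots.
#'
#' @param rot a [gravity_rotation()].
#' @param S,W shoulder and wrist positions, robot frame (m).
#' @param geom an [arm_geometry()].
#' @return Numeric 2-vector of gamma roots, wrapped to `(-pi, pi]`.
#' @export
solve_gamma <- function(rot, S, W, geom) {
  sw <- W - S
  if (sqrt(sum(sw^2)) < 1e-9) stop("shoulder and wrist coincide")
  g0 <- c(0, 1, 0)
  u <- rot$R[, 3L]                                  # candidate Z, acc0 frame
  w <- as.numeric(t(geom$mount_ref_rotation) %*% sw) # W - S, acc0 frame
  a <- sum(u * w) - sum(g0 * u) * sum(g0 * w)
  b <- sum(cross3(g0, u) * w)
  cc <- sum(g0 * u) * sum(g0 * w)
  rho <- sqrt(a^2 + b^2)
  if (abs(cc) > rho * (1 + 1e-9))
    stop("no real gamma: accelerometer reading inconsistent with the ",
         "shoulder-wrist segment")
  delta <- acos(max(-1, min(1, -cc / rho)))
  phi <- atan2(b, a)
  wrap_angle(c(phi + delta, phi - delta))
}

#' Candidate elbow poses for the two gamma roots
#'
#' Each root gives an accelerometer orientation whose Z axis is one of the
#' two normals of the arm plane; the elbow lies at `l_u` along the sensor Y
#' axis from the shoulder.
#'
#' @param gammas 2-vector from [solve_gamma()].
#' @param rot the [gravity_rotation()] used to solve for `gammas`.
#' @param S shoulder position, robot frame (m).
#' @param geom an [arm_geometry()].
#' @return Object of class `elbow_candidates`: list with `gammas`, `poses`
#'   (two accelerometer [rigid_transform()]s, origin at the shoulder) and
#'   `elbows` (2 x 3 matrix of elbow points).
#' @export
elbow_candidates <- function(gammas, rot, S, geom) {
  g0 <- c(0, 1, 0)
  poses <- lapply(gammas, function(g) {
    Racc <- geom$mount_ref_rotation %*% axis_angle_rotation(g0, g) %*% rot$R
    rigid_transform(Racc, S, check = FALSE)
  })
  elbows <- t(vapply(poses, function(p) p$p + geom$l_u * p$R[, 2L],
                     numeric(3)))
  structure(list(gammas = gammas, poses = poses, elbows = elbows),
            class = "elbow_candidates")
}

#' Select the anatomically correct elbow candidate
#'
#' The true candidate's Z axis (the elbow flexion axis) points along
#' `(W - E) x (S - E)`, so its dot product with that cross product is
#' positive for any elbow flexion in the interior of the range. The two
#' candidate Z axes are in general *not* antiparallel (they are the two
#' intersections of the gravity cone with the plane orthogonal to the
#' shoulder-wrist axis), so the sign test alone does not always single out
#' one candidate. When the geometry is supplied, forearm-length consistency
#' `| ||W - E|| - l_f |` -- which the spurious candidate violates grossly --
#' picks the candidate first and the sign test then validates it. Near full
#' extension (collinear S, E, W) the flexion axis is unobservable, the dot
#' product vanishes and an error is raised; callers fall back to the
#' previously selected branch.
#'
#' @param cands an [elbow_candidates()].
#' @param S,W shoulder and wrist positions (m).
#' @param geom an [arm_geometry()] enabling the forearm-length
#'   disambiguation; `NULL` falls back to the pure sign rule (valid only
#'   where that rule is well defined).
#' @param tol relative degeneracy tolerance on the selection dot product.
#' @return Index (1 or 2) of the selected candidate.
#' @export
select_elbow <- function(cands, S, W, geom = NULL, tol = 1e-9) {
  d <- vapply(1:2, function(i) {
    E <- cands$elbows[i, ]
    sum(cands$poses[[i]]$R[, 3L] * cross3(W - E, S - E))
  }, numeric(1))
  scale <- max(sqrt(sum((W - S)^2)), 1e-12)
  if (is.null(geom)) {
    # pure sign rule (assumes it is well defined: exactly one positive)
    if (max(abs(d)) < tol * scale)
      stop("degenerate elbow selection: shoulder, elbow and wrist are collinear")
    return(which.max(d))
  }
  lf_err <- vapply(1:2, function(i)
    abs(sqrt(sum((W - cands$elbows[i, ])^2)) - geom$l_f), numeric(1))
  i <- if (abs(lf_err[1L] - lf_err[2L]) > tol * geom$l_f)
    which.min(lf_err) else which.max(d)
  if (d[i] < tol * scale)
    stop("degenerate elbow selection: shoulder, elbow and wrist are collinear")
  i
}

#' Homogeneous elbow pose of a selected candidate
#'
#' Composes the accelerometer orientation with the fixed accelerometer-to-
#' elbow mounting rotation; the position is the candidate elbow point.
#'
#' @param cands an [elbow_candidates()].
#' @param index candidate index from [select_elbow()].
#' @param geom an [arm_geometry()].
#' @return [rigid_transform()] of the elbow (DH elbow frame) in the robot
#'   frame.
#' @export
elbow_pose <- function(cands, index, geom) {
  rigid_transform(cands$poses[[index]]$R %*% geom$elbow_in_accel_ref,
                  cands$elbows[index, ], check = FALSE)
}

#' One-sample elbow estimation with quasi-static gating
#'
#' Wrapper chaining [gravity_rotation()], [solve_gamma()],
#' [elbow_candidates()] and [select_elbow()]. Samples outside the
#' quasi-static norm band hold the previous gravity rotation; a degenerate
#' (collinear) selection falls back to the previously selected branch.
#'
#' @param sample accelerometer 3-vector, g units.
#' @param S,W shoulder and wrist positions (m).
#' @param geom an [arm_geometry()].
#' @param prev previous return value of this function (or `NULL` at the
#'   first sample).
#' @return List with the selected elbow `pose`, branch `index`, logical
#'   `gated`, and the `rot` ([gravity_rotation()]) used.
#' @export
estimate_elbow <- function(sample, S, W, geom, prev = NULL) {
  nv <- sqrt(sum(as.numeric(sample)^2))
  gated <- !is.finite(nv) || abs(nv - 1) > 0.2
  if (gated) {
    if (is.null(prev))
      stop("first accelerometer sample fails the quasi-static gate ",
           "(norm ", format(nv, digits = 3), " g)")
    rot <- prev$rot
  } else {
    rot <- gravity_rotation(sample)
  }
  gammas <- tryCatch(solve_gamma(rot, S, W, geom), error = function(e) {
    if (is.null(prev)) stop(e)
    NULL
  })
  if (is.null(gammas))  # inconsistent sample: hold the previous estimate
    return(list(pose = prev$pose, index = prev$index, gated = TRUE,
                rot = prev$rot))
  cands <- elbow_candidates(gammas, rot, S, geom)
  index <- tryCatch(select_elbow(cands, S, W, geom), error = function(e) {
    if (is.null(prev)) stop(e)
    prev$index
  })
  list(pose = elbow_pose(cands, index, geom), index = index, gated = gated,
       rot = rot)
}
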